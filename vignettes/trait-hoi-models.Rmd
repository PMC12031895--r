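---
title: "Models and methods: trait-mediated pairwise and higher-order competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: trait-mediated pairwise and higher-order competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The modelling framework

`hoisim` simulates communities of $S$ competing species whose individuals
carry a single quantitative trait $z$.  Under the standard
quantitative-genetic limit (many loci of small additive effect), each
species' trait distribution is normal, $p_i = N(u_i, \sigma_i^2)$, with a
mean $u_i$ that evolves and a variance $\sigma_i^2$ that stays constant
through time.  The per-capita growth rate of a phenotype $z$ combines an
intrinsic rate, pairwise competition against all phenotypes present, and a
three-way (higher-order) term in which a third phenotype modulates a
pairwise interaction:

$$
r(z) = r_0(z)
 - \sum_j N_j \int a(z, z')\, p_j(z')\, dz'
 - \sum_{j,k} N_j N_k \iint W(z, z', z'')\, p_j(z') p_k(z'')\, dz'\, dz''.
$$

Averaging $r(z)$ over $p_i$ gives the density dynamics
$dN_i/dt = N_i \bar r_i$, and weighting it by $(z - u_i)$ gives the
mean-trait dynamics $du_i/dt = h_i^2 \int (z - u_i) r(z) p_i(z)\, dz$,
with $h_i^2$ the trait's heritability.  In the small-variance limit the
trait equation reduces to the familiar selection-gradient form
$h^2 \sigma^2\, \partial \bar r / \partial u$; the integral form used here
remains valid for large $\sigma_i$.

Four model variants arise from the choice of kernels:

| model     | $a(z, z')$ | $W(z, z', z'')$ | $r_0(z)$ |
|-----------|------------|------------------|----------|
| `evo`     | $e^{-(z-z')^2/\omega^2}$ | $0$ | box: 1 on $[-\theta,\theta]$ |
| `evoHOI`  | as `evo`   | $\kappa C(\omega)\, e^{-[(z-z')^2+(z'-z'')^2+(z''-z)^2]/(3\omega^2/2)}$ | as `evo` |
| `hier`    | $\tfrac12[\mathrm{erf}((z-z')/\omega)+1]$ | $0$ | $1 - e^{-z/\theta}$ |
| `hierHOI` | as `hier`  | $\tfrac{\kappa}{2}[\mathrm{erf}((z_0 + z - \tfrac{z'+z''}{2})/\Omega)+1]$ | as `hier` |

The `evo` family models resource-overlap (distance-decay) competition: the
closer two phenotypes, the harder they compete, and the three-way term
grows with the triple overlap in resource use.  The `hier` family models a
competitive hierarchy (e.g. height competition for light): lower trait
values dominate, while the intrinsic rate rewards high trait values,
creating a competition-growth trade-off; its three-way term evaluates the
focal phenotype's rank against the *average* of the other two.

Both higher-order kernels are built so that the triple-self term
$W(z,z,z)$ is a constant independent of $z$.  A $z$-dependent $W(z,z,z)$
would smuggle phenotype-dependent self-regulation into the model and could
spuriously promote coexistence; a constant merely adds a uniform
density-dependent self-limitation.  This constancy is asserted exactly in
the test suite, and is also the reason the interaction sums run over *all*
species pairs including the focal species itself.

## The Gaussian three-way prefactor

The `evoHOI` kernel's printed normalisation constant is read literally as
$C(\omega) = 4/(3\pi\omega)$.  Since $C(\omega)$ multiplies $\kappa$, any
alternative normalisation only rescales the higher-order magnitude, so the
constant is exposed as the `hoi_prefactor` argument of `model_params()`
for sensitivity checks, and the package default states the literal value.

# Species-level reductions: closed forms and their oracle

All simulation work happens at the species level, using the coefficients
$\bar r_{0,i}$, $\alpha_{ij}$ and $\epsilon_{ijk}$ obtained by integrating
the phenotype kernels against one, two or three normal trait
distributions.  Every one of these integrals has a closed form:

* Gaussian kernels integrate by the standard convolution identity, e.g.
  $\alpha_{ij} = \omega/\sqrt{V}\, e^{-(u_i-u_j)^2/V}$ with
  $V = \omega^2 + 2\sigma_i^2 + 2\sigma_j^2$ — individual variation always
  broadens (and flattens) the effective kernel.
* erf kernels use $E[\mathrm{erf}(Y/\omega)] =
  \mathrm{erf}(\mu_Y/\sqrt{\omega^2 + 2\sigma_Y^2})$ for normal $Y$.
* The Gaussian three-way coefficient follows from the quadratic-form
  identity $E[e^{-\beta X^\top A X}] = \det(I + 2\beta\Sigma A)^{-1/2}
  e^{-\beta\, \mu^\top A (I + 2\beta\Sigma A)^{-1} \mu}$, which reduces to
  the explicit scalar expression documented in `eff_epsilon()`.
* The selection integrals follow from Stein's identity for normal
  distributions, $E[(Z - u) f(Z)] = \sigma^2\, \partial E[f(Z)] /
  \partial u$, applied to each closed form.

Closed forms are the production path; an independent tensor-product
Gauss–Hermite / adaptive quadrature evaluator (`quad_oracle()`) exists
solely to validate them.  `validate_kernels()` runs that comparison over
random parameter draws and is also exposed as the CLI `validate`
subcommand.  Two numerical caveats dictated the oracle's design:

* the box-shaped intrinsic growth is discontinuous, so its 1-D integrals
  use adaptive quadrature split at the known breakpoints rather than
  Gauss–Hermite;
* the `hierHOI` sigmoid at its default width $\Omega = 0.01$ is too sharp
  for tensor quadrature at any reasonable node count, so random-draw
  validation samples $\Omega$ on a resolvable scale ($0.05$–$0.2$), while
  the sharp default is checked against an exact 1-D reduction (the kernel
  depends on phenotypes only through $z_0 + z - (z'+z'')/2$, which is
  itself normal).

# Integration to equilibrium

The coupled $2S$ system is integrated with `deSolve::lsoda` (stiff-capable)
at `rtol = 1e-9`, `atol = 1e-12`, in geometrically growing time chunks
(from 50 up to $10^6$ time units).  After each chunk, species below the
extinction threshold ($N_i < 10^{-6}$, far below any equilibrium density
in these models yet above solver noise) are removed: their density is set
to zero and their trait frozen at its value at the time of extinction —
selection acting through a vanished population is not meaningful, and
freezing avoids spurious re-entry.  Removing extinct species from the
active system also shrinks the $O(S^3)$ higher-order contraction, which is
the computational hot spot (implemented in compiled code; the R closed
forms remain the tested reference).

Equilibrium is declared when both

1. $\max_i\left(|dN_i/dt| / \max(N_i, 1),\ |du_i/dt|\right) < 10^{-8}$
   (`eq_tol`), and
2. $\max_i |\bar r_i| < 10^{-6}$ (`r_tol`) over the remaining species.

The second condition matters: a species declining exponentially at low
density satisfies the first criterion long before it crosses the
extinction threshold (its $|dN/dt| = N |\bar r|$ is small *because* $N$
is), yet it is not part of any equilibrium.  Requiring near-zero
per-capita growth keeps the integrator running until such species are
actually excluded.  This is how, for instance, the wide-kernel
high-variation Gaussian cell ends at exactly two survivors instead of two
survivors plus a moribund straggler.  The value $10^{-6}$ balances that
against the opposite failure mode: near-degenerate species pairs whose
mutual exclusion slows to per-capita rates below any fixed threshold, and
which a stricter criterion would chase into numerically stiff territory
for astronomically long transients.

The time horizon is capped at $t_{\max} = 10^8$.  Under low individual
variation ($\sigma \sim 0.006$, $h^2 \sim 0.12$) trait evolution moves at
rates of order $h^2\sigma^2 \sim 10^{-5}$ per unit time, so
eco-evolutionary equilibria are only reached around $t \sim 10^6$–$10^7$;
a much shorter horizon would terminate mid-transient and report spuriously
rich, unconverged communities.  Because chunk lengths grow geometrically
and the dynamics slow exponentially near equilibrium, the large horizon
costs little wall time.

# Outcome metrics

* **Diversity** — inverse Simpson index $D = 1/\sum_i p_i^2$ over
  surviving relative abundances: an effective species number.
* **Trait spacing** — the coefficient of variation of adjacent gaps
  between sorted survivor trait means (sample standard deviation over
  mean; the convention cancels out of the null comparison as long as it
  is applied uniformly).  With fewer than three survivors there are not
  two gaps and the metric is reported as `NA`.
* **Clustering p-value** — observed traits are min–max rescaled to
  $[0,1]$ and their gap CV is compared against 1000 communities of equal
  richness drawn uniformly on $[0,1]$; the p-value is the fraction of
  null CVs *strictly* below the observed one (ties have probability zero
  for continuous draws).  Values near 0 indicate overdispersion (even
  spacing), near 1 clustering.  Both the observed rescaling and the CV
  are affine-invariant, so the comparison is well-posed.
* **Robustness** — the community matrix $J_{ij} = \partial(N_i \bar
  r_i)/\partial N_j$ (traits held fixed) is evaluated over survivors at
  equilibrium, and robustness is the geometric mean of its eigenvalue
  magnitudes, computed as $|\det J|^{1/S}$; the eigenvalue route is kept
  as an identity check.  It measures average return rates after density
  perturbations.
* **Effective kernel** — the diagnostic $\alpha_{\mathrm{eff}}(u, u') =
  \alpha(u, u') + \sum_k N_k \epsilon(u, u', u_k)$ that reduces an HOI
  model to an approximate pairwise one.  The probe phenotypes need a trait
  sd; the default is the median survivor sd, exposed as an option since
  the construction is explicitly a heuristic: the summed HOI term has no
  position-independent width, so the curve guides intuition about species
  spacing rather than making quantitative predictions.

# The simulation campaign

The full design crosses the four models with kernel widths $\omega \in
\{0.1, 0.2, 0.5\}$ and three intraspecific-variation levels ($\sigma_i$
uniform in $(0.003, 0.009)$, $(0.01, 0.03)$ or $(0.05, 0.1)$): 36 cells,
by default 40 replicates each.  Every replicate starts with 40 species at
density 1, trait means uniform on $(-0.5, 0.5)$ (`evo` family) or
$(0, 2)$ (`hier` family), and heritabilities uniform on $(0.1, 0.15)$.

Matched replicates are central to the design: the comparison "what does
adding HOIs do?" is made replicate-by-replicate, so replicate $r$ must
start identically in `evo` and `evoHOI` (and in `hier` vs `hierHOI`), and
the per-species $\sigma_i$, $h_i^2$ draws must agree across all cells
sharing a replicate index.  The seed scheme therefore derives the RNG seed
from (base seed, replicate) only, draws raw uniforms in a fixed order
(trait means, then sds, then heritabilities), and maps them to
model-family and variation-level ranges afterwards.  The clustering null
draws use a separate per-(cell, replicate) seed so they cannot perturb
this matching.  A campaign is fully reproducible from its configuration
and base seed, independent of execution order or parallelism.

## Problem sizes used in the shipped checks

The packaged test-suite and the acceptance script re-run the campaign at
10 replicates per cell over the 11 design cells that carry the qualitative
conclusions (the diversity gradients and the matched model contrasts);
unit tests use 6–12-species communities.  These sizes were chosen so the
full verification run completes comfortably on a single core while leaving
the medians far from their decision boundaries; the full 36-cell,
40-replicate campaign is available through `run_ensemble()` or the CLI
`run` subcommand.

# What the generator does and does not emulate

The synthetic communities implement the study conditions exactly: random
initial placements along the trait axis, fixed normal intraspecific
variation, heritable mean-trait evolution, and strictly competitive
kernels.  They do not emulate demographic stochasticity, environmental
fluctuation, mutation-driven variance dynamics, multiple traits, or
non-competitive (e.g. trophic) interactions — passing tests therefore
speak to the deterministic trait-based theory, not to noisy field data.
Within the models, forward integration always reached fixed-point
equilibria (no cycles or chaos were observed), matching the behaviour the
theory predicts for these kernel choices.

# Known limitations

* The `evoHOI` three-way closed form and its compiled contraction assume
  normal trait distributions; skewed or bounded distributions would
  require the quadrature path throughout.
* Robustness is computed on the survivor submatrix only; extinct species
  contribute structurally zero rows and are excluded.
* The effective-kernel diagnostic depends on a probe-sd convention
  (median survivor sd by default) and is a heuristic, not an estimator.
* The random-coefficient variant in which intraspecific HOI effects
  exceed interspecific ones is out of scope, as are multi-trait HOIs and
  non-competitive kernel extensions.
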