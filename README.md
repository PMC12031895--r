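# hoisim

Eco-evolutionary community dynamics with trait-mediated pairwise and
higher-order competition.

## What this package is for

A long-standing question in community ecology is when higher-order
interactions (HOIs) — cases where a third species modulates the
competition between two others — help or hinder species coexistence.
Most theory draws HOI coefficients at random; `hoisim` instead implements
*structured, low-dimensional* HOIs in which all interactions derive from a
single quantitative trait $z$, and couples them to quantitative-genetic
trait evolution.  It is aimed at theoretical ecologists who want to
simulate and dissect these models: how diversity, trait spacing and the
robustness of coexistence respond to the width of competition kernels,
the level of heritable intraspecific variation, and the presence of
trait-based HOIs.

Species $i$ has a normal trait distribution $p_i = N(u_i, \sigma_i^2)$
(mean evolving, variance fixed).  A phenotype $z$ grows at

$$
r(z) = r_0(z) - \sum_j N_j \!\int\! a(z,z')\,p_j(z')\,dz'
 - \sum_{j,k} N_j N_k \!\iint\! W(z,z',z'')\,p_j(z')\,p_k(z'')\,dz'dz'' ,
$$

and the community evolves by $dN_i/dt = N_i \int r(z) p_i(z)\,dz$ and
$du_i/dt = h_i^2 \int (z-u_i)\, r(z)\, p_i(z)\,dz$.  Four kernel choices
give four models:

* **evo** — Gaussian distance-decay competition
  $a = e^{-(z-z')^2/\omega^2}$, no HOIs, box-shaped intrinsic growth;
* **evoHOI** — evo plus a Gaussian three-way kernel
  $W = \kappa C(\omega)\,e^{-[(z-z')^2+(z'-z'')^2+(z''-z)^2]/(3\omega^2/2)}$;
* **hier** — hierarchical competition
  $a = \frac12[\mathrm{erf}((z-z')/\omega)+1]$ (lower trait wins),
  intrinsic growth $1-e^{-z/\theta}$ rewarding high traits;
* **hierHOI** — hier plus a sigmoid three-way kernel
  $W = \frac{\kappa}{2}[\mathrm{erf}((z_0+z-\frac{z'+z''}{2})/\Omega)+1]$.

All species-level coefficients (two- and three-way integrals over the
trait distributions, and their selection-gradient counterparts) are
closed-form, validated against an independent Gauss–Hermite/adaptive
quadrature oracle (`quad_oracle()`, `validate_kernels()`).  Communities
are integrated to eco-evolutionary equilibrium with extinction handling,
then summarised by inverse Simpson diversity, an adjacent-gap
trait-clustering null model, and community-matrix robustness
($|\det J|^{1/S}$); the effective-kernel diagnostic
$\alpha_\mathrm{eff}(u,u') = \alpha(u,u') + \sum_k N_k\,\epsilon(u,u',u_k)$
reduces an HOI model to an approximate pairwise one for interpretation.
The methods vignette (`vignettes/trait-hoi-models.Rmd`) documents the
models, the numerical choices and their rationale.

## Worked example

Run one replicate of the Gaussian-HOI model at kernel width
$\omega = 0.1$ under low intraspecific variation, starting from 40
species at density 1:

```r
library(hoisim)

grid <- build_grid(models = "evoHOI", omega = 0.1, variation = "low",
                   replicates = 1, base_seed = 1)
res <- run_replicate(grid[1, ], replicate = 1)
print(res)
#> <replicate_result> evoHOI_w0.1_low replicate 1 (seed 7920)
#> <equilibrium_result>
#>   converged: TRUE at t = 5.63835e+06 (residual 6.87e-10)
#>   survivors: 11 of 40
#> <metrics_record>
#>   richness      11
#>   D             10.3769
#>   gap_cv        0.2028
#>   clustering_p  0
#>   robustness    0.8109
```

Of the 40 founding species, 11 coexist at equilibrium, with an effective
(inverse Simpson) diversity of 10.4 — nearly even abundances.  The
clustering p-value of 0 says the survivors' trait means are far more
evenly spaced than uniform-random placement (limiting similarity), and
the robustness 0.81 is the geometric-mean return rate after density
perturbations.  Running the matched pairwise replicate (`models = "evo"`,
same seed) starts from the same initial trait means and ends at a nearly
identical diversity (D = 10.20) but a 40-fold lower robustness (0.020
vs 0.811) — the HOI term acts as extra self-limitation that makes species
dynamically more independent of one another.  The effective kernel behind
this comparison is available via `effective_kernel(res$eq, res$params)`.

The full 36-cell factorial campaign of the study (4 models × ω ∈ {0.1,
0.2, 0.5} × low/medium/high variation, 40 replicates each, matched across
models) is `run_ensemble(build_grid(base_seed = 1))`, or from the shell:

```sh
Rscript inst/scripts/hoisim.R run --replicates 40 --seed 1 --out campaign.csv
```

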