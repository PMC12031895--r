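## Phenotype-level kernels and their species-level (trait-distribution
## averaged) reductions.  All functions are vectorised elementwise and accept
## conformable arrays, which the dynamics module exploits to build S x S
## matrices and S x S x S tensors without loops.

#' Pairwise interaction kernel at the phenotype level
#'
#' Competitive effect of phenotype `z_prime` on phenotype `z`.  For the
#' `evo` family this is the Gaussian distance-decay kernel
#' \eqn{a(z, z') = \exp(-(z - z')^2/\omega^2)}; for the `hier` family it is
#' the sigmoid hierarchy \eqn{a(z, z') = \frac{1}{2}[\mathrm{erf}((z -
#' z')/\omega) + 1]}, so that phenotypes lower on the trait axis are
#' competitively superior.  Values lie in \eqn{[0, 1]}.
#'
#' @param z,z_prime Phenotype values (trait units); vectorised.
#' @param params A [model_params()] object.
#' @return Interaction strength(s) in \eqn{[0, 1]}.
#' @export
phen_pairwise <- function(z, z_prime, params) {
  .check_params(params)
  d <- z - z_prime
  if (params$model %in% c("evo", "evoHOI")) {
    exp(-d^2 / params$omega^2)
  } else {
    0.5 * (erf(d / params$omega) + 1)
  }
}

#' Higher-order interaction kernel at the phenotype level
#'
#' Modification of the pairwise interaction between `z` and `z_prime` by a
#' third phenotype `z_dprime`.  Identically zero for the pairwise models.
#' For `evoHOI` it is the symmetric Gaussian three-way overlap
#' \deqn{W(z, z', z'') = \kappa C(\omega) \exp\{-[(z-z')^2 + (z'-z'')^2 +
#' (z''-z)^2] / (3\omega^2/2)\}}
#' with \eqn{C(\omega)} the normalising prefactor stored in `params`.  For
#' `hierHOI` it is
#' \deqn{W(z, z', z'') = \frac{\kappa}{2}\left[\mathrm{erf}\left(\frac{z_0 +
#' z - (z' + z'')/2}{\Omega}\right) + 1\right],}
#' i.e. the competitive superiority of `z` is assessed against the average
#' of the other two phenotypes.  Both kernels satisfy the consistency
#' requirement that \eqn{W(z, z, z)} is a z-independent constant, so the
#' self-terms amount to a uniform extra self-limitation rather than a hidden
#' phenotype-dependent self-regulation.
#'
#' @inheritParams phen_pairwise
#' @param z_dprime Third phenotype (trait units); vectorised.
#' @return Non-negative interaction strength(s).
#' @export
phen_hoi <- function(z, z_prime, z_dprime, params) {
  .check_params(params)
  switch(params$model,
    evo = ,
    hier = 0 * (z + z_prime + z_dprime),
    evoHOI = {
      q <- (z - z_prime)^2 + (z_prime - z_dprime)^2 + (z_dprime - z)^2
      params$kappa * params$hoi_prefactor * exp(-q / (1.5 * params$omega^2))
    },
    hierHOI = {
      arg <- (params$z0 + z - (z_prime + z_dprime) / 2) / params$Omega
      (params$kappa / 2) * (erf(arg) + 1)
    }
  )
}

#' Intrinsic growth rate at the phenotype level
#'
#' For the `evo` family, growth is 1 inside the box \eqn{|z| \le \theta}
#' and 0 outside (the boundary counts as inside).  For the `hier` family,
#' \eqn{r_0(z) = 1 - e^{-z/\theta}}: positive growth requires \eqn{z > 0}
#' and larger traits grow faster, trading off against their lower rank in
#' the competitive hierarchy.
#'
#' @inheritParams phen_pairwise
#' @return Intrinsic growth rate(s).
#' @export
phen_intrinsic <- function(z, params) {
  .check_params(params)
  if (params$model %in% c("evo", "evoHOI")) {
    (abs(z) <= params$theta) + 0 * z
  } else {
    1 - exp(-z / params$theta)
  }
}

.check_sigma <- function(...) {
  for (s in list(...))
    if (any(s < 0)) stop("trait standard deviations must be >= 0", call. = FALSE)
}

.check_sigma_pos <- function(s) {
  if (any(s <= 0))
    stop("selection integrals require sigma > 0", call. = FALSE)
}

#' Species-level pairwise competition coefficient
#'
#' Expectation of [phen_pairwise()] over the normal trait distributions of
#' the two species, \eqn{\alpha_{ij} = \iint a(z, z') p_i(z) p_j(z')\,dz\,
#' dz'} with \eqn{p_i = N(u_i, \sigma_i^2)}.  Closed forms: for `evo`,
#' \eqn{\omega/\sqrt{V}\,e^{-(u_i-u_j)^2/V}} and for `hier`
#' \eqn{\frac12[\mathrm{erf}((u_i-u_j)/\sqrt{V}) + 1]}, where
#' \eqn{V = \omega^2 + 2\sigma_i^2 + 2\sigma_j^2}.  Individual variation
#' thus broadens (and for `evo` flattens) the kernel.
#'
#' @param u_i,u_j Mean traits of the focal (affected) and partner species.
#' @param sigma_i,sigma_j Trait standard deviations, \eqn{\ge 0} (0 denotes
#'   a point phenotype).
#' @param params A [model_params()] object.
#' @return Non-negative coefficient(s); vectorised.
#' @export
eff_alpha <- function(u_i, sigma_i, u_j, sigma_j, params) {
  .check_params(params)
  .check_sigma(sigma_i, sigma_j)
  V <- params$omega^2 + 2 * sigma_i^2 + 2 * sigma_j^2
  d <- u_i - u_j
  if (params$model %in% c("evo", "evoHOI")) {
    params$omega / sqrt(V) * exp(-d^2 / V)
  } else {
    0.5 * (erf(d / sqrt(V)) + 1)
  }
}

#' Species-level higher-order competition coefficient
#'
#' Expectation of [phen_hoi()] over the trait distributions of the three
#' species involved, \eqn{\epsilon_{ijk} = \iiint W(z, z', z'') p_i(z)
#' p_j(z') p_k(z'')}.  Zero for the pairwise models.  For `evoHOI` the
#' Gaussian quadratic-form identity gives, with \eqn{t = 4/(3\omega^2)},
#' variances \eqn{(a, b, c) = (\sigma_i^2, \sigma_j^2, \sigma_k^2)} and
#' squared trait differences \eqn{d^2_{\cdot\cdot}},
#' \deqn{\epsilon = \kappa C(\omega) D^{-1/2} e^{-tQ/2}, \quad
#'  D = 1 + 2t(a+b+c) + 3t^2(ab+ac+bc),}
#' \deqn{Q = [d_{ij}^2 + d_{jk}^2 + d_{ki}^2 +
#'  3t(a\,d_{jk}^2 + b\,d_{ki}^2 + c\,d_{ij}^2)]/D.}
#' For `hierHOI` the erf-Gaussian convolution identity gives
#' \eqn{\frac{\kappa}{2}[\mathrm{erf}(m/\sqrt{v}) + 1]} with
#' \eqn{m = z_0 + u_i - (u_j + u_k)/2} and \eqn{v = \Omega^2 +
#' 2\sigma_i^2 + (\sigma_j^2 + \sigma_k^2)/2}.  Both forms are symmetric
#' under exchange of the two partner species \eqn{j \leftrightarrow k} and
#' agree with the quadrature oracle [quad_oracle()].
#'
#' @inheritParams eff_alpha
#' @param u_k,sigma_k Mean trait and trait sd of the third species.
#' @return Non-negative coefficient(s); vectorised.
#' @export
eff_epsilon <- function(u_i, sigma_i, u_j, sigma_j, u_k, sigma_k, params) {
  .check_params(params)
  .check_sigma(sigma_i, sigma_j, sigma_k)
  if (!params$has_hoi || params$kappa == 0)
    return(0 * (u_i + u_j + u_k))
  if (params$model == "evoHOI") {
    t2 <- 4 / (3 * params$omega^2)   # = 2 * beta
    a <- sigma_i^2; b <- sigma_j^2; c <- sigma_k^2
    dij2 <- (u_i - u_j)^2; djk2 <- (u_j - u_k)^2; dki2 <- (u_k - u_i)^2
    D <- 1 + 2 * t2 * (a + b + c) + 3 * t2^2 * (a * b + a * c + b * c)
    Q <- (dij2 + djk2 + dki2 + 3 * t2 * (a * djk2 + b * dki2 + c * dij2)) / D
    params$kappa * params$hoi_prefactor / sqrt(D) * exp(-0.5 * t2 * Q)
  } else {
    m <- params$z0 + u_i - (u_j + u_k) / 2
    v <- params$Omega^2 + 2 * sigma_i^2 + (sigma_j^2 + sigma_k^2) / 2
    (params$kappa / 2) * (erf(m / sqrt(v)) + 1)
  }
}

#' Species-level intrinsic growth rate
#'
#' Expectation of [phen_intrinsic()] over the focal species' trait
#' distribution, \eqn{\bar r_{0,i} = \int r_0(z) p_i(z)\,dz}.  Closed
#' forms: for `evo`,
#' \eqn{\frac12[\mathrm{erf}((\theta-u)/(\sigma\sqrt2)) +
#' \mathrm{erf}((\theta+u)/(\sigma\sqrt2))]}; for `hier`,
#' \eqn{1 - e^{-u/\theta + \sigma^2/(2\theta^2)}}.
#'
#' @param u_i Mean trait of the focal species; vectorised.
#' @param sigma_i Trait standard deviation, \eqn{\ge 0}.
#' @inheritParams eff_alpha
#' @return Growth rate(s).
#' @export
eff_r0 <- function(u_i, sigma_i, params) {
  .check_params(params)
  .check_sigma(sigma_i)
  if (params$model %in% c("evo", "evoHOI")) {
    th <- params$theta
    u <- u_i + 0 * sigma_i
    s <- sigma_i + 0 * u_i
    out <- (abs(u) <= th) + 0 * u            # sigma = 0: box indicator
    pos <- s > 0
    if (any(pos)) {
      up <- u[pos]; sp <- s[pos]
      out[pos] <- 0.5 * (erf((th - up) / (sp * sqrt(2))) +
                         erf((th + up) / (sp * sqrt(2))))
    }
    out
  } else {
    1 - exp(-u_i / params$theta + sigma_i^2 / (2 * params$theta^2))
  }
}

#' Selection integrals of the growth-rate components
#'
#' Trait-weighted analogues of [eff_r0()], [eff_alpha()] and
#' [eff_epsilon()]: each is \eqn{\int (z - u_i)\,[\mathrm{term}](z)\,
#' p_i(z)\,dz} with the partner phenotypes already averaged over their own
#' trait distributions.  These are the building blocks of the mean-trait
#' dynamics; by Stein's identity for normal distributions each equals
#' \eqn{\sigma_i^2 \, \partial/\partial u_i} of the corresponding
#' expectation, which is how the closed forms below are obtained.  The
#' returned values are the raw integrals; the dynamics subtracts the
#' competitive terms.
#'
#' @inheritParams eff_epsilon
#' @return Selection integral(s); vectorised.  `sigma_i` must be strictly
#'   positive (the integrals vanish identically at \eqn{\sigma_i = 0}, and
#'   a point phenotype cannot respond to selection).
#' @export
sel_r0 <- function(u_i, sigma_i, params) {
  .check_params(params)
  .check_sigma_pos(sigma_i)
  if (params$model %in% c("evo", "evoHOI")) {
    th <- params$theta
    sigma_i / sqrt(2 * pi) *
      (exp(-(th + u_i)^2 / (2 * sigma_i^2)) -
       exp(-(th - u_i)^2 / (2 * sigma_i^2)))
  } else {
    sigma_i^2 / params$theta *
      exp(-u_i / params$theta + sigma_i^2 / (2 * params$theta^2))
  }
}

#' @rdname sel_r0
#' @export
sel_alpha <- function(u_i, sigma_i, u_j, sigma_j, params) {
  .check_params(params)
  .check_sigma_pos(sigma_i)
  .check_sigma(sigma_j)
  V <- params$omega^2 + 2 * sigma_i^2 + 2 * sigma_j^2
  d <- u_i - u_j
  if (params$model %in% c("evo", "evoHOI")) {
    sigma_i^2 * (-2 * d / V) * params$omega / sqrt(V) * exp(-d^2 / V)
  } else {
    sigma_i^2 / sqrt(pi * V) * exp(-d^2 / V)
  }
}

#' @rdname sel_r0
#' @export
sel_epsilon <- function(u_i, sigma_i, u_j, sigma_j, u_k, sigma_k, params) {
  .check_params(params)
  .check_sigma_pos(sigma_i)
  .check_sigma(sigma_j, sigma_k)
  if (!params$has_hoi || params$kappa == 0)
    return(0 * (u_i + u_j + u_k))
  if (params$model == "evoHOI") {
    t2 <- 4 / (3 * params$omega^2)
    a <- sigma_i^2; b <- sigma_j^2; c <- sigma_k^2
    dij2 <- (u_i - u_j)^2; djk2 <- (u_j - u_k)^2; dki2 <- (u_k - u_i)^2
    D <- 1 + 2 * t2 * (a + b + c) + 3 * t2^2 * (a * b + a * c + b * c)
    Q <- (dij2 + djk2 + dki2 + 3 * t2 * (a * djk2 + b * dki2 + c * dij2)) / D
    eff <- params$kappa * params$hoi_prefactor / sqrt(D) * exp(-0.5 * t2 * Q)
    dQ <- (6 * t2 * (b * (u_i - u_k) + c * (u_i - u_j)) +
           2 * (2 * u_i - u_j - u_k)) / D
    a * eff * (-0.5 * t2 * dQ)
  } else {
    m <- params$z0 + u_i - (u_j + u_k) / 2
    v <- params$Omega^2 + 2 * sigma_i^2 + (sigma_j^2 + sigma_k^2) / 2
    params$kappa * sigma_i^2 / sqrt(pi * v) * exp(-m^2 / v)
  }
}

#' Gauss-Hermite quadrature oracle for species-level integrals
#'
#' Evaluates \eqn{E[f(Z_1, \ldots, Z_d)]} for independent normal variables
#' \eqn{Z_m \sim N(\mathrm{mean}_m, \mathrm{sd}_m^2)} by tensor-product
#' Gauss-Hermite quadrature.  This is the reference evaluator against which
#' every closed-form species-level coefficient is tested; it is deliberately
#' independent of those closed forms.  Dimensions with `sd = 0` collapse to
#' a point evaluation.
#'
#' @param f Integrand: a function taking a numeric matrix with `d` columns
#'   (one row per quadrature node) and returning a numeric vector.
#' @param mean,sd Numeric vectors of length `d` (1, 2 or 3): the means and
#'   standard deviations of the integration variables.
#' @param nodes Number of Gauss-Hermite nodes per axis.
#' @param check If `TRUE`, re-evaluate with `nodes + 8` nodes per axis and
#'   flag non-convergence.
#' @param tol Relative tolerance for the convergence check.
#' @param method `"gauss_hermite"` (tensor product), `"adaptive"`
#'   (`stats::integrate`, 1-D only; robust to discontinuous integrands
#'   such as the box-shaped intrinsic growth) or `"auto"` (adaptive for
#'   1-D, Gauss-Hermite otherwise).
#' @param breaks Optional known discontinuity locations of a 1-D
#'   integrand; the adaptive path integrates piecewise between them.
#' @return The integral value, with attribute `"converged"` when
#'   `check = TRUE`.  A warning is raised if the two node counts disagree
#'   beyond `tol`.
#' @examples
#' p <- model_params("evo", omega = 0.1)
#' quad_oracle(function(x) phen_pairwise(x[, 1], x[, 2], p),
#'             mean = c(0, 0.05), sd = c(0.02, 0.02))
#' @export
quad_oracle <- function(f, mean, sd, nodes = 48, check = FALSE, tol = 1e-8,
                        method = c("auto", "gauss_hermite", "adaptive"),
                        breaks = NULL) {
  method <- match.arg(method)
  d <- length(mean)
  if (!d %in% 1:3 || length(sd) != d)
    stop("'mean' and 'sd' must have equal length 1, 2 or 3", call. = FALSE)
  .check_sigma(sd)
  if (method == "auto") method <- if (d == 1L) "adaptive" else "gauss_hermite"
  if (method == "adaptive") {
    if (d != 1L) stop("adaptive quadrature is 1-D only", call. = FALSE)
    if (sd == 0) return(f(matrix(mean, 1L)))
    lo <- mean - 12 * sd; hi <- mean + 12 * sd
    pts <- sort(unique(c(lo, breaks[breaks > lo & breaks < hi], hi)))
    val <- 0
    for (i in seq_len(length(pts) - 1L))
      val <- val + stats::integrate(function(z) f(matrix(z, ncol = 1L)) *
                                      dnorm(z, mean, sd),
                                    lower = pts[i], upper = pts[i + 1L],
                                    subdivisions = 2000L,
                                    rel.tol = 1e-11, abs.tol = 1e-13)$value
    if (check) attr(val, "converged") <- TRUE
    return(val)
  }
  eval_n <- function(n) {
    gh <- pracma::gaussHermite(n)
    pts <- vector("list", d)
    wts <- vector("list", d)
    for (m in seq_len(d)) {
      if (sd[m] > 0) {
        pts[[m]] <- mean[m] + sqrt(2) * sd[m] * gh$x
        wts[[m]] <- gh$w / sqrt(pi)
      } else {
        pts[[m]] <- mean[m]
        wts[[m]] <- 1
      }
    }
    grid <- as.matrix(expand.grid(pts, KEEP.OUT.ATTRS = FALSE))
    wgrid <- as.matrix(expand.grid(wts, KEEP.OUT.ATTRS = FALSE))
    sum(f(grid) * apply(wgrid, 1L, prod))
  }
  val <- eval_n(nodes)
  if (check) {
    val2 <- eval_n(nodes + 8L)
    rel <- abs(val - val2) / max(abs(val2), .Machine$double.eps)
    if (rel > tol)
      warning(sprintf("quadrature oracle not converged (rel. change %.3g)", rel))
    attr(val, "converged") <- rel <= tol
  }
  val
}
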