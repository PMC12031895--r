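#' Inverse Simpson diversity
#'
#' Effective number of species \eqn{D = 1/\sum_i p_i^2} with
#' \eqn{p_i = N_i/\sum_j N_j} over the species with positive density.
#' Scale-invariant; equals the richness when all abundances are equal.
#'
#' @param N Density vector (non-negative, at least one positive entry).
#' @return Diversity \eqn{D \in [1, \mathrm{richness}]}.
#' @examples
#' inverse_simpson(c(0.5, 0.5))  # 2
#' @export
inverse_simpson <- function(N) {
  if (any(N < 0)) stop("densities must be non-negative", call. = FALSE)
  N <- N[N > 0]
  if (length(N) == 0L) stop("all densities are zero", call. = FALSE)
  p <- N / sum(N)
  1 / sum(p^2)
}

## sd/mean of consecutive gaps of a sorted trait vector (sample sd)
.gap_cv <- function(u_sorted) {
  g <- diff(u_sorted)
  sd(g) / mean(g)
}

#' Coefficient of variation of adjacent trait gaps
#'
#' Sorts the survivor mean traits, takes consecutive differences and
#' returns their sample-sd / mean.  Zero for perfectly evenly spaced
#' communities; larger values indicate clustering.  Undefined (`NA`) with
#' fewer than 3 species, since at least two gaps are needed.
#'
#' @param u Mean traits of the surviving species.
#' @return The gap CV, or `NA_real_` if fewer than 3 species.
#' @export
adjacent_gap_cv <- function(u) {
  if (length(u) < 3L) return(NA_real_)
  .gap_cv(sort(u))
}

#' Trait-clustering p-value against a uniform null
#'
#' Rescales the observed survivor traits to \eqn{[0, 1]} by the min-max
#' transform, computes their adjacent-gap CV, and compares it with the gap
#' CVs of `n_null` communities of the same richness drawn from the uniform
#' distribution on \eqn{[0, 1]}.  The returned p-value is the fraction of
#' null CVs strictly lower than the observed one: values near 0 mean the
#' community is more evenly spaced than expected by chance, values near 1
#' that it is more clustered.
#'
#' @param u Mean traits of the surviving species (at least 3, not all
#'   equal; otherwise `NA_real_` is returned).
#' @param n_null Number of null communities (default 1000).
#' @param seed Optional integer seed for the null draws; the caller's RNG
#'   state is restored afterwards.
#' @return p-value in \eqn{[0, 1]}, or `NA_real_` if undefined.
#' @export
clustering_pvalue <- function(u, n_null = 1000, seed = NULL) {
  k <- length(u)
  if (k < 3L) return(NA_real_)
  rng <- diff(range(u))
  if (rng == 0) return(NA_real_)
  u01 <- (u - min(u)) / rng
  cv_obs <- .gap_cv(sort(u01))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  m <- matrix(runif(n_null * k), nrow = n_null)
  ms <- matrix(m[order(row(m), m)], nrow = n_null, byrow = TRUE)
  gaps <- ms[, -1L, drop = FALSE] - ms[, -k, drop = FALSE]
  gm <- rowMeans(gaps)
  gs <- sqrt(rowSums((gaps - gm)^2) / (k - 2L))
  sum(gs / gm < cv_obs) / n_null
}

#' Community matrix at an eco-evolutionary equilibrium
#'
#' Jacobian of the ecological part of the dynamics — \eqn{\partial(N_i \bar
#' r_i)/\partial N_j} with mean traits held fixed — restricted to the
#' surviving species:
#' \deqn{J_{ij} = -N_i\left[\alpha_{ij} + \sum_k N_k(\epsilon_{ijk} +
#' \epsilon_{ikj})\right] + \delta_{ij}\,\bar r_i,}
#' where the \eqn{\bar r_i} term vanishes at an exact equilibrium but is
#' retained so the finite-residual state is differentiated consistently.
#' Its eigenvalues set the return rates after density perturbations.
#'
#' @param eq A converged [integrate_to_equilibrium()] result.
#' @param params A [model_params()] object.
#' @return A square matrix over the surviving species.
#' @export
community_jacobian <- function(eq, params) {
  .check_params(params)
  if (!inherits(eq, "equilibrium_result"))
    stop("'eq' must be an equilibrium_result", call. = FALSE)
  if (!isTRUE(eq$converged))
    stop("community matrix requires a converged equilibrium", call. = FALSE)
  st <- .survivor_state(eq)
  if (st$S == 0L) stop("no surviving species", call. = FALSE)
  A <- .alpha_matrix(st$u, st$sigma, params)
  M <- A
  if (params$has_hoi && params$kappa > 0) {
    eps <- .eps_tensor(st$u, st$sigma, params)
    Nk3 <- .expand3(st$N, 3L)
    ## sum_k N_k (eps[i,j,k] + eps[i,k,j])
    M <- M + rowSums(eps * Nk3, dims = 2L) +
      apply(eps * .expand3(st$N, 2L), c(1L, 3L), sum)
  }
  J <- -M * st$N                 # row i scaled by N_i (column recycling)
  diag(J) <- diag(J) + species_growth(st, params)
  J
}

#' Robustness of coexistence
#'
#' Geometric mean of the magnitudes of the community-matrix eigenvalues,
#' \eqn{(\prod_i |\lambda_i|)^{1/S} = |\det J|^{1/S}}.  It measures the
#' geometric-average return rate to equilibrium after density perturbations
#' and the community's sensitivity to parameter perturbations.  Larger is
#' more robust.
#'
#' @param J Community matrix (square, finite).
#' @param method `"det"` (default) uses the determinant identity;
#'   `"eigen"` multiplies eigenvalue magnitudes.  The two agree to
#'   numerical precision.
#' @return Positive scalar; 0 (with a warning) for a singular matrix.
#' @export
robustness <- function(J, method = c("det", "eigen")) {
  method <- match.arg(method)
  if (!is.matrix(J) || nrow(J) != ncol(J) || any(!is.finite(J)))
    stop("'J' must be a finite square matrix", call. = FALSE)
  S <- nrow(J)
  if (method == "det") {
    ld <- determinant(J, logarithm = TRUE)
    if (!is.finite(ld$modulus)) {
      warning("singular community matrix; robustness is 0")
      return(0)
    }
    exp(as.numeric(ld$modulus) / S)
  } else {
    ev <- eigen(J, only.values = TRUE)$values
    if (any(ev == 0)) {
      warning("singular community matrix; robustness is 0")
      return(0)
    }
    exp(mean(log(abs(ev))))
  }
}

#' Effective interaction kernel of an HOI community
#'
#' The diagnostic that reduces a higher-order model to an approximate
#' pairwise one: \deqn{\alpha_{\mathrm{eff}}(u, u') = \alpha(u, u') +
#' \sum_k N_k\, \epsilon(u, u', u_k),} i.e. the species-level pairwise
#' kernel plus the higher-order effects summed over all third participants
#' at their equilibrium densities.  The probe phenotypes at `u` and `u'`
#' are given a representative trait sd (`probe_sigma`, default the median
#' survivor sd).  The width of this effective kernel, rather than of the
#' bare pairwise kernel, is what governs species spacing in HOI models.
#'
#' @param eq A converged [integrate_to_equilibrium()] result with at least
#'   one survivor.
#' @param params A [model_params()] object.
#' @param u Focal probe traits (default: 101 points spanning the survivor
#'   trait range, extended by one kernel width on each side).
#' @param u_prime Partner probe trait(s) (default: median survivor trait).
#'   The grid is the cross product of `u` and `u_prime`.
#' @param probe_sigma Trait sd assigned to both probe phenotypes.
#' @return A data frame with columns `u`, `u_prime`, `alpha` (pairwise
#'   part), `hoi` (summed higher-order part) and `alpha_eff = alpha + hoi`.
#' @export
effective_kernel <- function(eq, params, u = NULL, u_prime = NULL,
                             probe_sigma = NULL) {
  .check_params(params)
  if (!inherits(eq, "equilibrium_result"))
    stop("'eq' must be an equilibrium_result", call. = FALSE)
  st <- .survivor_state(eq)
  if (st$S == 0L) stop("no surviving species", call. = FALSE)
  if (is.null(probe_sigma)) probe_sigma <- median(st$sigma)
  if (is.null(u_prime)) u_prime <- median(st$u)
  if (is.null(u)) {
    r <- range(st$u)
    u <- seq(r[1] - params$omega, r[2] + params$omega, length.out = 101L)
  }
  g <- expand.grid(u = u, u_prime = u_prime, KEEP.OUT.ATTRS = FALSE)
  alpha <- eff_alpha(g$u, probe_sigma, g$u_prime, probe_sigma, params)
  hoi <- numeric(nrow(g))
  if (params$has_hoi && params$kappa > 0) {
    for (k in seq_len(st$S))
      hoi <- hoi + st$N[k] *
        eff_epsilon(g$u, probe_sigma, g$u_prime, probe_sigma,
                    st$u[k], st$sigma[k], params)
  }
  data.frame(u = g$u, u_prime = g$u_prime, alpha = alpha, hoi = hoi,
             alpha_eff = alpha + hoi)
}

#' Summary metrics of one equilibrium community
#'
#' Convenience wrapper computing the per-replicate outcome statistics:
#' inverse Simpson diversity, survivor richness, adjacent-gap CV,
#' trait-clustering p-value and robustness.  Metrics that are undefined for
#' the community at hand (fewer than 3 survivors for the clustering
#' statistics; non-converged equilibria for robustness) are reported as
#' `NA`.
#'
#' @param eq An [integrate_to_equilibrium()] result.
#' @param params A [model_params()] object.
#' @param n_null,null_seed Passed to [clustering_pvalue()].
#' @return A list of class `"metrics_record"` with fields `D`, `richness`,
#'   `gap_cv`, `clustering_p`, `robustness`.
#' @export
metrics_record <- function(eq, params, n_null = 1000, null_seed = NULL) {
  keep <- eq$survivors
  N <- eq$state$N[keep]; u <- eq$state$u[keep]
  rec <- list(
    D = if (length(N)) inverse_simpson(N) else NA_real_,
    richness = length(N),
    gap_cv = adjacent_gap_cv(u),
    clustering_p = clustering_pvalue(u, n_null = n_null, seed = null_seed),
    robustness = NA_real_
  )
  if (isTRUE(eq$converged) && length(N) > 0L)
    rec$robustness <- robustness(community_jacobian(eq, params))
  class(rec) <- "metrics_record"
  rec
}

#' @export
print.metrics_record <- function(x, ...) {
  cat("<metrics_record>\n")
  cat(sprintf("  richness      %d\n", x$richness))
  cat(sprintf("  D             %.4f\n", x$D))
  cat(sprintf("  gap_cv        %s\n", format(x$gap_cv, digits = 4)))
  cat(sprintf("  clustering_p  %s\n", format(x$clustering_p, digits = 4)))
  cat(sprintf("  robustness    %s\n", format(x$robustness, digits = 4)))
  invisible(x)
}
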