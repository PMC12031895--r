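#' A community of competing species on a one-dimensional trait axis
#'
#' Bundles the per-species state and fixed attributes: density `N`, mean
#' trait `u`, trait standard deviation `sigma` (constant in time, as under
#' the quantitative-genetic limit of many small-effect loci) and
#' heritability `h2` (constant, scales the rate of mean-trait evolution).
#'
#' @param N Non-negative densities.
#' @param u Mean trait values (trait units).
#' @param sigma Trait standard deviations; must be strictly positive for
#'   eco-evolutionary integration (zero is allowed for ecology-only use of
#'   point phenotypes).
#' @param h2 Heritabilities in \eqn{[0, 1]}.
#' @return An object of class `"species_ensemble"` with fields `S`, `N`,
#'   `u`, `sigma`, `h2`.
#' @examples
#' species_ensemble(N = c(1, 1), u = c(-0.1, 0.1), sigma = c(0.02, 0.02),
#'                  h2 = c(0.12, 0.12))
#' @export
species_ensemble <- function(N, u, sigma, h2) {
  S <- length(N)
  if (length(u) != S || length(sigma) != S || length(h2) != S)
    stop("N, u, sigma, h2 must have equal length", call. = FALSE)
  if (any(!is.finite(N)) || any(!is.finite(u)) ||
      any(!is.finite(sigma)) || any(!is.finite(h2)))
    stop("species_ensemble fields must be finite", call. = FALSE)
  if (any(N < 0)) stop("densities must be non-negative", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]", call. = FALSE)
  structure(list(S = S, N = as.numeric(N), u = as.numeric(u),
                 sigma = as.numeric(sigma), h2 = as.numeric(h2)),
            class = "species_ensemble")
}

#' @export
print.species_ensemble <- function(x, ...) {
  cat("<species_ensemble> S =", x$S, "\n")
  print(data.frame(N = x$N, u = x$u, sigma = x$sigma, h2 = x$h2), ...)
  invisible(x)
}

## expand a length-S vector into an S x S x S array varying along dim `along`
.expand3 <- function(x, along) {
  S <- length(x)
  switch(along,
         array(x, c(S, S, S)),
         array(rep(x, each = S), c(S, S, S)),
         array(rep(x, each = S * S), c(S, S, S)))
}

## S x S matrix of pairwise coefficients; rows = affected species i
.alpha_matrix <- function(u, sigma, params) {
  S <- length(u)
  Ui <- matrix(u, S, S); Si <- matrix(sigma, S, S)
  eff_alpha(Ui, Si, t(Ui), t(Si), params)
}

## focal sigma (rows) may differ from partner sigma (columns): the
## selection integrals require sigma_i > 0 but tolerate sigma_j = 0
.sel_alpha_matrix <- function(u, sigma_focal, sigma_partner, params) {
  S <- length(u)
  Ui <- matrix(u, S, S)
  sel_alpha(Ui, matrix(sigma_focal, S, S),
            t(Ui), t(matrix(sigma_partner, S, S)), params)
}

## S x S x S tensors eps[i, j, k] of higher-order coefficients
.eps_tensor <- function(u, sigma, params, fun = eff_epsilon,
                        sigma_focal = sigma) {
  fun(.expand3(u, 1L), .expand3(sigma_focal, 1L),
      .expand3(u, 2L), .expand3(sigma, 2L),
      .expand3(u, 3L), .expand3(sigma, 3L), params)
}

## quadratic HOI load per focal species: G_i = sum_jk N_j N_k eps[i,j,k]
.hoi_load <- function(eps, N) {
  S <- length(N)
  NN <- .expand3(N, 2L) * .expand3(N, 3L)
  rowSums(eps * NN, dims = 1L)
}

## dispatch the compiled triple-sum contractions; returns list(G, H)
.hoi_loads <- function(u, sigma, sigma_focal, N, params, want_sel = FALSE) {
  s2 <- sigma^2
  s2f <- sigma_focal^2
  if (params$model == "evoHOI") {
    hoi_loads_gauss(u, s2, s2f, N, params$kappa * params$hoi_prefactor,
                    4 / (3 * params$omega^2), want_sel)
  } else {
    hoi_loads_hier(u, s2, s2f, N, params$kappa, params$Omega, params$z0,
                   want_sel)
  }
}

#' Per-capita species-level growth rates
#'
#' Assembles \eqn{\bar r_i = \bar r_{0,i} - \sum_j N_j \alpha_{ij} -
#' \sum_{j,k} N_j N_k \epsilon_{ijk}} from the closed-form species-level
#' coefficients.  Sums run over all species including the focal one: the
#' kernels are built so that self- and triple-self terms represent ordinary
#' (phenotype-independent) self-limitation.
#'
#' @param state A [species_ensemble()].
#' @param params A [model_params()] object.
#' @return Numeric vector of per-capita growth rates \eqn{\bar r_i}.
#' @export
species_growth <- function(state, params) {
  .check_params(params)
  r <- eff_r0(state$u, state$sigma, params) -
    drop(.alpha_matrix(state$u, state$sigma, params) %*% state$N)
  if (params$has_hoi && params$kappa > 0)
    r <- r - .hoi_loads(state$u, state$sigma, state$sigma, state$N,
                        params)$G
  if (any(!is.finite(r)))
    stop("non-finite growth rate for species ",
         paste(which(!is.finite(r)), collapse = ", "), call. = FALSE)
  r
}

#' Rate of change of mean traits
#'
#' The mean-trait dynamics \eqn{du_i/dt = h_i^2 [\,\mathrm{sel}_{r_0}(i) -
#' \sum_j N_j\, \mathrm{sel}_\alpha(i,j) - \sum_{j,k} N_j N_k\,
#' \mathrm{sel}_\epsilon(i,j,k)\,]}, i.e. the trait-weighted growth-rate
#' integral scaled by heritability.  In the small-variance limit this
#' reduces to the classic \eqn{h^2 \sigma^2 \,\partial \bar r/\partial u}
#' selection-gradient dynamics.
#'
#' @inheritParams species_growth
#' @return Numeric vector \eqn{du_i/dt}.  Requires `sigma > 0` for all
#'   species.
#' @export
trait_velocity <- function(state, params) {
  .check_params(params)
  .check_sigma_pos(state$sigma)
  .trait_velocity_impl(state, params)
}

## like trait_velocity() but tolerates sigma = 0 (those traits are frozen)
.trait_velocity_impl <- function(state, params) {
  evolving <- state$sigma > 0
  du <- numeric(state$S)
  if (!any(evolving)) return(du)
  sigf <- state$sigma
  sigf[!evolving] <- 1   # focal-role placeholder; those rows are discarded
  g <- sel_r0(state$u, sigf, params) -
    drop(.sel_alpha_matrix(state$u, sigf, state$sigma, params) %*% state$N)
  if (params$has_hoi && params$kappa > 0)
    g <- g - .hoi_loads(state$u, state$sigma, sigf, state$N, params,
                        want_sel = TRUE)$H
  du[evolving] <- (state$h2 * g)[evolving]
  if (any(!is.finite(du)))
    stop("non-finite trait velocity for species ",
         paste(which(!is.finite(du)), collapse = ", "), call. = FALSE)
  du
}

## derivative function on the active subsystem, for deSolve; assembles
## growth and selection in one pass so the HOI tensor is contracted once
.rhs_factory <- function(sigma, h2, params) {
  S <- length(sigma)
  evolving <- sigma > 0
  sigf <- sigma
  sigf[!evolving] <- 1
  hoi <- params$has_hoi && params$kappa > 0
  function(t, y, p) {
    N <- pmax(y[seq_len(S)], 0)
    u <- y[S + seq_len(S)]
    r <- eff_r0(u, sigma, params) -
      drop(.alpha_matrix(u, sigma, params) %*% N)
    g <- sel_r0(u, sigf, params) -
      drop(.sel_alpha_matrix(u, sigf, sigma, params) %*% N)
    if (hoi) {
      loads <- .hoi_loads(u, sigma, sigf, N, params, want_sel = TRUE)
      r <- r - loads$G
      g <- g - loads$H
    }
    du <- h2 * g
    du[!evolving] <- 0
    list(c(N * r, du))
  }
}

#' Integrate a community to eco-evolutionary equilibrium
#'
#' Integrates the coupled density and mean-trait dynamics with a
#' stiff-capable solver (deSolve's `lsoda`) in geometrically growing time
#' chunks.  After each chunk, species whose density has fallen below
#' `extinction_threshold` are declared extinct: their density is set to 0
#' and their trait frozen, and they are removed from the active subsystem
#' (which also shrinks the \eqn{O(S^3)} higher-order tensor).  Convergence
#' is declared when \eqn{\max_i(|dN_i/dt| / \max(N_i, 1),\, |du_i/dt|) <
#' \mathtt{eq\_tol}} over the active species *and* every remaining
#' species has per-capita growth below `r_tol` in magnitude; otherwise
#' integration stops at `t_max` with `converged = FALSE`.  The second
#' condition prevents a low-density species that is still deterministically
#' dying (whose \eqn{dN/dt = N \bar r} is small only because \eqn{N} is)
#' from being declared part of an equilibrium.
#'
#' If the solver stalls inside a chunk (step-count ceiling in a stiff,
#' near-degenerate configuration), the progress made so far is kept and
#' the chunk length is reduced before retrying; integration only aborts
#' if no progress at all can be made.
#'
#' @param state0 Initial [species_ensemble()].
#' @param params A [model_params()] object.
#' @param eq_tol Residual tolerance for declaring equilibrium.
#' @param r_tol Per-capita growth-rate tolerance for survivors at
#'   equilibrium.
#' @param t_max Maximum model time.
#' @param extinction_threshold Density below which a species is removed.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param method deSolve integration method (stiff-capable by default).
#' @param keep_trajectory If `TRUE`, store sampled states along the way.
#' @param chunk0 Length of the first integration chunk (doubles up to
#'   `chunk_max` as the dynamics slow down).
#' @param chunk_max Upper bound on the chunk length.
#' @return An object of class `"equilibrium_result"`: list with `state`
#'   (full-size ensemble; extinct species at `N = 0` with frozen traits),
#'   `converged`, `residual`, `t_final`, `survivors` (logical mask) and
#'   optionally `trajectory` (matrix with columns `t`, `N1..NS`, `u1..uS`).
#' @export
integrate_to_equilibrium <- function(state0, params,
                                     eq_tol = 1e-8,
                                     r_tol = 1e-6,
                                     t_max = 1e8,
                                     extinction_threshold = 1e-6,
                                     rtol = 1e-9, atol = 1e-12,
                                     method = "lsoda",
                                     keep_trajectory = FALSE,
                                     chunk0 = 50, chunk_max = 1e6) {
  .check_params(params)
  stopifnot(inherits(state0, "species_ensemble"))
  S <- state0$S
  N <- state0$N; u <- state0$u
  active <- N > extinction_threshold
  t_now <- 0; dt <- chunk0
  converged <- FALSE; residual <- NA_real_
  traj <- if (keep_trajectory) list(c(t = 0, N = N, u = u)) else NULL

  while (t_now < t_max && any(active)) {
    idx <- which(active)
    rhs <- .rhs_factory(state0$sigma[idx], state0$h2[idx], params)
    dt <- min(dt, t_max - t_now)
    times <- if (keep_trajectory) seq(0, dt, length.out = 6L) else c(0, dt)
    sol <- suppressWarnings(
      deSolve::ode(y = c(N[idx], u[idx]), times = times, func = rhs,
                   parms = NULL, method = method,
                   rtol = rtol, atol = atol, maxsteps = 100000))
    k <- length(idx)
    stalled <- attr(sol, "istate")[1L] < 0
    if (stalled) {
      ## keep whatever progress was made, then retry with a shorter chunk
      t_reached <- sol[nrow(sol), 1L]
      if (t_reached <= 0) {
        if (dt <= chunk0) stop(sprintf(
          "solver failure at t = %g (model %s)", t_now, params$model),
          call. = FALSE)
        dt <- max(chunk0, dt / 8)
        next
      }
      dt_done <- t_reached
    } else {
      dt_done <- dt
    }
    if (keep_trajectory && nrow(sol) > 1L) {
      for (r in 2:nrow(sol)) {
        Nfull <- N; ufull <- u
        Nfull[idx] <- pmax(sol[r, 1L + seq_len(k)], 0)
        ufull[idx] <- sol[r, 1L + k + seq_len(k)]
        traj[[length(traj) + 1L]] <- c(t = t_now + sol[r, 1L],
                                       N = Nfull, u = ufull)
      }
    }
    yend <- sol[nrow(sol), -1L]
    N[idx] <- pmax(yend[seq_len(k)], 0)
    u[idx] <- yend[k + seq_len(k)]
    t_now <- t_now + dt_done

    ## cull extinctions, freeze their traits at time of death
    dead <- idx[N[idx] < extinction_threshold]
    if (length(dead)) {
      N[dead] <- 0
      active[dead] <- FALSE
    }

    if (any(active)) {
      idx <- which(active)
      st <- species_ensemble(N[idx], u[idx], state0$sigma[idx],
                             state0$h2[idx])
      r <- species_growth(st, params)
      du <- .trait_velocity_impl(st, params)
      residual <- max(abs(st$N * r) / pmax(st$N, 1), abs(du))
      ## a low-density species can satisfy the density residual while
      ## still deterministically dying (dN = N r small because N is);
      ## equilibrium additionally requires near-zero per-capita growth
      if (residual < eq_tol && max(abs(r)) < r_tol) {
        converged <- TRUE; break
      }
    } else {
      residual <- 0; converged <- TRUE; break
    }
    dt <- min(if (stalled) dt else dt * 2, chunk_max)
  }

  res <- list(
    state = species_ensemble(N, u, state0$sigma, state0$h2),
    converged = converged,
    residual = residual,
    t_final = t_now,
    survivors = N > extinction_threshold
  )
  if (keep_trajectory) res$trajectory <- do.call(rbind, traj)
  class(res) <- "equilibrium_result"
  res
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("<equilibrium_result>\n")
  cat(sprintf("  converged: %s at t = %g (residual %.3g)\n",
              x$converged, x$t_final, x$residual))
  cat(sprintf("  survivors: %d of %d\n", sum(x$survivors), x$state$S))
  invisible(x)
}

## survivor-only sub-ensemble of an equilibrium result
.survivor_state <- function(eq) {
  keep <- eq$survivors
  species_ensemble(eq$state$N[keep], eq$state$u[keep],
                   eq$state$sigma[keep], eq$state$h2[keep])
}
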