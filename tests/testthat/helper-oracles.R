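# Shared numerical oracles and small fixtures, built in code.

# central-difference Jacobian of the density dynamics f_i(N) = N_i * rbar_i
# at fixed traits, over the surviving species of an equilibrium
fd_jacobian <- function(eq, params, h = 1e-6) {
  st <- hoisim:::.survivor_state(eq)
  S <- st$S
  f <- function(N) {
    s2 <- st
    s2$N <- N
    N * species_growth(s2, params)
  }
  J <- matrix(0, S, S)
  for (j in seq_len(S)) {
    Np <- st$N; Nm <- st$N
    Np[j] <- Np[j] + h
    Nm[j] <- Nm[j] - h
    J[, j] <- (f(Np) - f(Nm)) / (2 * h)
  }
  J
}

# a small random community for a given model, integrated to equilibrium
small_equilibrium <- function(model, omega = 0.2, S = 8, seed = 1,
                              variation = c(0.02, 0.05), ...) {
  set.seed(seed)
  params <- model_params(model, omega = omega)
  u0 <- if (model %in% c("evo", "evoHOI")) runif(S, -0.5, 0.5)
        else runif(S, 0, 2)
  st <- species_ensemble(N = rep(1, S), u = u0,
                         sigma = runif(S, variation[1], variation[2]),
                         h2 = runif(S, 0.1, 0.15))
  list(params = params,
       eq = integrate_to_equilibrium(st, params, ...))
}
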