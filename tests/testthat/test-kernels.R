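erf <- hoisim:::erf

test_that("phenotype-level pairwise kernels take their defining values", {
  evo <- model_params("evo", omega = 0.1)
  hier <- model_params("hier", omega = 0.1)
  expect_equal(phen_pairwise(0.3, 0.3, evo), 1)
  expect_equal(phen_pairwise(0.3, 0.3, hier), 0.5)
  expect_equal(phen_pairwise(0.2, 0.1, evo), exp(-1))
  set.seed(1)
  z <- runif(200, -2, 2); zp <- runif(200, -2, 2)
  for (p in list(evo, hier)) {
    v <- phen_pairwise(z, zp, p)
    expect_true(all(v >= 0 & v <= 1))
  }
  # hierarchy: lower phenotype exerts competition, receives little
  expect_gt(phen_pairwise(1, 0, hier), 0.99)
  expect_lt(phen_pairwise(0, 1, hier), 0.01)
})

test_that("W(z,z,z) is a z-independent constant for both HOI models", {
  set.seed(42)
  z <- runif(1000, -3, 3)
  for (m in c("evoHOI", "hierHOI")) {
    p <- model_params(m, omega = 0.17)
    w <- phen_hoi(z, z, z, p)
    expect_equal(max(w) - min(w), 0)       # exact, to machine precision
    expect_true(all(w > 0))
  }
  # and the constants are the analytic ones
  pe <- model_params("evoHOI", omega = 0.17)
  expect_equal(phen_hoi(1.3, 1.3, 1.3, pe), pe$kappa * pe$hoi_prefactor)
  ph <- model_params("hierHOI")
  expect_equal(phen_hoi(0.4, 0.4, 0.4, ph),
               (ph$kappa / 2) * (erf(ph$z0 / ph$Omega) + 1))
  expect_equal(phen_hoi(0.4, 0.4, 0.4, ph), 5, tolerance = 1e-12)
})

test_that("HOI kernels vanish for pairwise models and respect their bounds", {
  evo <- model_params("evo", omega = 0.1)
  expect_equal(phen_hoi(0.1, 0.2, 0.3, evo), 0)
  expect_equal(phen_hoi(0.1, 0.2, 0.3, model_params("hier")), 0)
  set.seed(7)
  z <- matrix(runif(600, -1, 2), ncol = 3)
  pe <- model_params("evoHOI", omega = 0.1)
  we <- phen_hoi(z[, 1], z[, 2], z[, 3], pe)
  expect_true(all(we >= 0 & we <= pe$kappa * pe$hoi_prefactor))
  ph <- model_params("hierHOI")
  wh <- phen_hoi(z[, 1], z[, 2], z[, 3], ph)
  expect_true(all(wh >= 0 & wh <= ph$kappa))
})

test_that("intrinsic growth: box for evo, saturating exponential for hier", {
  evo <- model_params("evo")
  hier <- model_params("hier")
  expect_equal(phen_intrinsic(0, evo), 1)
  expect_equal(phen_intrinsic(0.6, evo), 0)
  expect_equal(phen_intrinsic(0.5, evo), 1)   # boundary counts as inside
  expect_equal(phen_intrinsic(0, hier), 0)
  expect_lt(phen_intrinsic(-0.5, hier), 0)    # negative growth below 0
  # theta enters hier as the rate scale 1/theta
  h2 <- model_params("hier", theta = 2)
  expect_equal(phen_intrinsic(1, h2), 1 - exp(-0.5))
})

test_that("species-level coefficients reduce to phenotype kernels at sigma = 0", {
  set.seed(11)
  for (m in c("evo", "evoHOI", "hier", "hierHOI")) {
    p <- model_params(m, omega = 0.15)
    u <- runif(3, -0.4, 1.4)
    expect_equal(eff_alpha(u[1], 0, u[2], 0, p),
                 phen_pairwise(u[1], u[2], p))
    expect_equal(eff_epsilon(u[1], 0, u[2], 0, u[3], 0, p),
                 phen_hoi(u[1], u[2], u[3], p))
    expect_equal(eff_r0(u[1], 0, p), phen_intrinsic(u[1], p))
  }
})

test_that("small-variance limit converges to the point-phenotype formulas", {
  set.seed(12)
  s <- 1e-6
  for (m in c("evo", "evoHOI", "hier", "hierHOI")) {
    p <- model_params(m, omega = 0.15)
    u <- c(0.12, 0.31, 0.44)   # away from the box discontinuity
    expect_equal(eff_alpha(u[1], s, u[2], s, p),
                 phen_pairwise(u[1], u[2], p), tolerance = 1e-4)
    expect_equal(eff_epsilon(u[1], s, u[2], s, u[3], s, p),
                 phen_hoi(u[1], u[2], u[3], p), tolerance = 1e-4)
    expect_equal(eff_r0(u[1], s, p), phen_intrinsic(u[1], p),
                 tolerance = 1e-4)
  }
})

test_that("known closed-form special cases hold", {
  p <- model_params("evo", omega = 0.1)
  # same means, equal variances: broadened self-overlap
  expect_equal(eff_alpha(0.2, 0.05, 0.2, 0.05, p),
               0.1 / sqrt(0.1^2 + 4 * 0.05^2))
  ph <- model_params("hier", omega = 0.1)
  expect_equal(eff_alpha(0.7, 0, 0.7, 0, ph), 0.5)
  # hierHOI triple-self with sharp sigmoid
  phh <- model_params("hierHOI")
  expect_equal(eff_epsilon(0.4, 0, 0.4, 0, 0.4, 0, phh), 5,
               tolerance = 1e-12)
})

test_that("individual variation broadens the evo kernel", {
  # the kernel's shape flattens as sigma grows: relative to its height at
  # zero trait distance, the value at distance omega increases strictly
  # (the peak height itself shrinks, so the raw value is not monotone)
  p <- model_params("evo", omega = 0.1)
  sig <- c(0, 0.01, 0.03, 0.05, 0.1)
  rel <- sapply(sig, function(s)
    eff_alpha(0, s, 0.1, s, p) / eff_alpha(0, s, 0, s, p))
  expect_true(all(diff(rel) > 0))
  # raw value also increases over the design's sigma range (up to ~omega/2)
  raw <- sapply(c(0, 0.01, 0.03, 0.05), function(s) eff_alpha(0, s, 0.1, s, p))
  expect_true(all(diff(raw) > 0))
})

test_that("eff_epsilon is exactly symmetric in the two partner species", {
  set.seed(5)
  for (m in c("evoHOI", "hierHOI")) {
    p <- model_params(m, omega = 0.12)
    for (i in 1:20) {
      u <- runif(3, -0.5, 1.5); s <- runif(3, 0, 0.1)
      expect_equal(eff_epsilon(u[1], s[1], u[2], s[2], u[3], s[3], p),
                   eff_epsilon(u[1], s[1], u[3], s[3], u[2], s[2], p),
                   tolerance = 1e-14)
    }
  }
})

test_that("kappa = 0 collapses HOI coefficients onto the pairwise model", {
  set.seed(6)
  u <- runif(3); s <- runif(3, 0.01, 0.1)
  e0 <- model_params("evo", omega = 0.2)
  eh <- model_params("evoHOI", omega = 0.2, kappa = 0)
  expect_identical(eff_alpha(u[1], s[1], u[2], s[2], e0),
                   eff_alpha(u[1], s[1], u[2], s[2], eh))
  expect_identical(eff_epsilon(u[1], s[1], u[2], s[2], u[3], s[3], eh), 0)
  expect_identical(sel_epsilon(u[1], s[1], u[2], s[2], u[3], s[3], eh), 0)
})

test_that("selection at equal trait means reflects each kernel's symmetry", {
  # the Gaussian kernel is even in z - z', so the integrand is odd and
  # pairwise selection vanishes between species with equal means ...
  for (m in c("evo", "evoHOI")) {
    p <- model_params(m, omega = 0.15)
    expect_equal(sel_alpha(0.3, 0.04, 0.3, 0.04, p), 0)
  }
  # ... but the hierarchical sigmoid is asymmetric: even at equal means
  # there is directional selection toward competitive superiority (lower
  # trait), confirmed against the quadrature oracle
  for (m in c("hier", "hierHOI")) {
    p <- model_params(m, omega = 0.15)
    got <- sel_alpha(0.3, 0.04, 0.3, 0.04, p)
    expect_gt(got, 0)
    want <- quad_oracle(function(x) (x[, 1] - 0.3) *
                          phen_pairwise(x[, 1], x[, 2], p),
                        mean = c(0.3, 0.3), sd = c(0.04, 0.04), nodes = 60)
    expect_equal(got, want, tolerance = 1e-8)
  }
  p <- model_params("evo")
  expect_equal(sel_r0(0, 0.07, p), 0)   # box symmetric about 0
  expect_error(sel_r0(0, 0, p), "sigma")
  expect_error(sel_alpha(0, -0.1, 0, 0.1, p), "sigma|selection")
})

test_that("closed forms agree with the quadrature oracle on random draws", {
  # the full 100-draw sweep runs in the acceptance suite; spot-check here
  v <- validate_kernels(n_draws = 10, tol = 1e-6, seed = 99, verbose = FALSE)
  expect_true(as.logical(v))
})

test_that("selection closed form matches a direct quadrature of the gradient", {
  p <- model_params("evo", omega = 0.1)
  got <- sel_alpha(0.1, 0.05, 0, 0.05, p)
  want <- quad_oracle(function(x) (x[, 1] - 0.1) *
                        phen_pairwise(x[, 1], x[, 2], p),
                      mean = c(0.1, 0), sd = c(0.05, 0.05), nodes = 60)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("sharp hierHOI sigmoid agrees with the exact 1-D reduction", {
  # W depends on phenotypes only through y = z0 + z - (z' + z'')/2, which is
  # normal with known mean and variance; integrate that 1-D density directly
  p <- model_params("hierHOI", omega = 0.2)   # Omega = 0.01, very sharp
  u <- c(0.9, 0.7, 1.1); s <- c(0.06, 0.03, 0.08)
  m <- u[1] - (u[2] + u[3]) / 2
  sy <- sqrt(s[1]^2 + (s[2]^2 + s[3]^2) / 4)
  want <- quad_oracle(function(x) phen_hoi(x[, 1], 0, 0, p),
                      mean = m, sd = sy, method = "adaptive")
  expect_equal(eff_epsilon(u[1], s[1], u[2], s[2], u[3], s[3], p), want,
               tolerance = 1e-8)
})

test_that("quadrature oracle normalises and reports convergence", {
  one <- function(x) rep(1, nrow(x))
  expect_equal(quad_oracle(one, 0, 0.3, method = "gauss_hermite"), 1)
  expect_equal(quad_oracle(one, c(0, 1), c(0.3, 0.1)), 1)
  expect_equal(quad_oracle(one, c(0, 1, 2), c(0.3, 0.1, 0.2), nodes = 12), 1)
  v <- quad_oracle(one, c(0, 0), c(0.1, 0.1), check = TRUE)
  expect_true(attr(v, "converged"))
  expect_error(quad_oracle(one, c(0, 0), 0.1), "length")
  expect_error(quad_oracle(one, 0, -1), "sigma|>= 0")
})
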