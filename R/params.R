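#' Model parameters for a trait-based competition model
#'
#' Constructs and validates the parameter set of one of the four community
#' models:
#'
#' * `"evo"` — Gaussian distance-decay pairwise competition, no higher-order
#'   interactions (HOIs); box-shaped intrinsic growth on \eqn{[-\theta, \theta]}.
#' * `"evoHOI"` — as `"evo"`, plus a Gaussian three-way kernel whose strength
#'   grows with the three-way overlap of resource utilisation.
#' * `"hier"` — hierarchical (error-function sigmoid) pairwise competition:
#'   phenotypes lower on the trait axis are competitively superior; intrinsic
#'   growth \eqn{1 - e^{-z/\theta}} rewards large trait values.
#' * `"hierHOI"` — as `"hier"`, plus a sigmoid three-way kernel in which the
#'   competitive superiority of the focal phenotype is assessed against the
#'   average of the other two.
#'
#' Defaults follow the study design: \eqn{\theta = 0.5} for the `evo` family
#' and \eqn{\theta = 1} for the `hier` family; \eqn{\kappa = 10} for
#' `evoHOI`, \eqn{\kappa = 5} for `hierHOI` and 0 for the pairwise models;
#' \eqn{\Omega = 0.01} and \eqn{z_0 = 0.15} for `hierHOI`.
#'
#' @param model One of `"evo"`, `"evoHOI"`, `"hier"`, `"hierHOI"`.
#' @param omega Width of the pairwise competition kernel (trait units), > 0.
#' @param theta Width of the intrinsic growth curve (trait units), > 0.
#'   Defaults to 0.5 (`evo`/`evoHOI`) or 1 (`hier`/`hierHOI`).
#' @param kappa Dimensionless magnitude of the higher-order terms, >= 0.
#'   Defaults to 10 (`evoHOI`), 5 (`hierHOI`), 0 otherwise.  Setting
#'   `kappa = 0` reduces each HOI model exactly to its pairwise twin.
#' @param Omega Width of the `hierHOI` sigmoid kernel (trait units), > 0.
#' @param z0 Shift of the `hierHOI` sigmoid kernel (trait units).
#' @param hoi_prefactor Normalising constant \eqn{C(\omega)} multiplying
#'   \eqn{\kappa} in the `evoHOI` kernel.  `"default"` uses
#'   \eqn{4/(3\pi\omega)}; alternatively supply a positive number to probe
#'   other normalisations (the constant only rescales \eqn{\kappa}).
#'
#' @return An object of class `"model_params"`: a list with elements
#'   `model`, `omega`, `theta`, `kappa`, `Omega`, `z0`, `hoi_prefactor`
#'   (the resolved numeric constant) and `has_hoi`.
#' @examples
#' model_params("evo", omega = 0.1)
#' model_params("hierHOI", omega = 0.5)
#' @export
model_params <- function(model = c("evo", "evoHOI", "hier", "hierHOI"),
                         omega = 0.1,
                         theta = NULL,
                         kappa = NULL,
                         Omega = 0.01,
                         z0 = 0.15,
                         hoi_prefactor = "default") {
  if (length(model) != 1L && !identical(model, c("evo", "evoHOI", "hier", "hierHOI")))
    stop("'model' must be a single model identifier", call. = FALSE)
  model <- match.arg(model)
  hier_family <- model %in% c("hier", "hierHOI")
  has_hoi <- model %in% c("evoHOI", "hierHOI")
  if (is.null(theta)) theta <- if (hier_family) 1 else 0.5
  if (is.null(kappa)) kappa <- switch(model, evoHOI = 10, hierHOI = 5, 0)
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega),
            is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(kappa), length(kappa) == 1L, is.finite(kappa),
            is.numeric(Omega), length(Omega) == 1L, is.finite(Omega),
            is.numeric(z0), length(z0) == 1L, is.finite(z0))
  if (omega <= 0) stop("'omega' must be positive", call. = FALSE)
  if (theta <= 0) stop("'theta' must be positive", call. = FALSE)
  if (Omega <= 0) stop("'Omega' must be positive", call. = FALSE)
  if (kappa < 0) stop("'kappa' must be non-negative", call. = FALSE)
  if (identical(hoi_prefactor, "default")) {
    pref <- 4 / (3 * pi * omega)
  } else {
    stopifnot(is.numeric(hoi_prefactor), length(hoi_prefactor) == 1L,
              is.finite(hoi_prefactor), hoi_prefactor > 0)
    pref <- hoi_prefactor
  }
  structure(
    list(model = model, omega = omega, theta = theta, kappa = kappa,
         Omega = Omega, z0 = z0, hoi_prefactor = pref, has_hoi = has_hoi),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>", x$model, "\n")
  cat("  omega =", x$omega, " theta =", x$theta, "\n")
  if (x$has_hoi) {
    cat("  kappa =", x$kappa)
    if (x$model == "evoHOI")
      cat("  C(omega) =", format(x$hoi_prefactor, digits = 6))
    if (x$model == "hierHOI")
      cat("  Omega =", x$Omega, " z0 =", x$z0)
    cat("\n")
  }
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "model_params"))
    stop("'params' must be created by model_params()", call. = FALSE)
  params
}
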