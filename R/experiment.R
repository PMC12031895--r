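## The replicated simulation campaign: a full factorial over model,
## pairwise kernel width and intraspecific-variation level, with a seed
## scheme that keeps replicates matched across design cells.

.variation_levels <- list(low = c(0.003, 0.009),
                          medium = c(0.01, 0.03),
                          high = c(0.05, 0.1))
.all_models <- c("evo", "evoHOI", "hier", "hierHOI")

## per-replicate seed: shared by every cell so that initial conditions are
## matched across models and variation levels
.replicate_seed <- function(base_seed, replicate) {
  as.integer((as.numeric(base_seed) + 7919 * replicate) %% 2147483647)
}

## per-(cell, replicate) seed for the clustering null draws
.null_seed <- function(base_seed, cell_id, replicate) {
  h <- sum(utf8ToInt(cell_id) * seq_along(utf8ToInt(cell_id)))
  as.integer((as.numeric(base_seed) + 104729 * replicate + 131 * h) %%
               2147483647)
}

#' Build the factorial simulation design
#'
#' Crosses the requested models, pairwise kernel widths and
#' intraspecific-variation levels into a table of design cells, ordered by
#' (model, omega, variation).  The default design is the full 4 x 3 x 3
#' factorial of 36 cells: models `evo`, `evoHOI`, `hier`, `hierHOI`;
#' \eqn{\omega \in \{0.1, 0.2, 0.5\}}; variation levels `low`
#' (\eqn{\sigma \sim U(0.003, 0.009)}), `medium` (\eqn{U(0.01, 0.03)}) and
#' `high` (\eqn{U(0.05, 0.1)}).
#'
#' @param models Subset of `"evo"`, `"evoHOI"`, `"hier"`, `"hierHOI"`.
#' @param omega Pairwise kernel widths (positive, distinct).
#' @param variation Subset of `"low"`, `"medium"`, `"high"`.
#' @param replicates Replicates per cell (default 40).
#' @param base_seed Base seed of the campaign.
#' @return A data frame of design cells with columns `cell_id`, `model`,
#'   `omega`, `variation`, `replicates`, `base_seed`.
#' @examples
#' nrow(build_grid())  # 36
#' @export
build_grid <- function(models = .all_models,
                       omega = c(0.1, 0.2, 0.5),
                       variation = names(.variation_levels),
                       replicates = 40, base_seed = 1) {
  if (!all(models %in% .all_models))
    stop("unknown model: ", paste(setdiff(models, .all_models),
                                  collapse = ", "), call. = FALSE)
  if (!all(variation %in% names(.variation_levels)))
    stop("unknown variation level: ",
         paste(setdiff(variation, names(.variation_levels)),
               collapse = ", "), call. = FALSE)
  if (any(omega <= 0)) stop("'omega' must be positive", call. = FALSE)
  if (anyDuplicated(models) || anyDuplicated(omega) ||
      anyDuplicated(variation))
    stop("duplicate cell specification", call. = FALSE)
  g <- expand.grid(variation = variation, omega = omega, model = models,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("model", "omega", "variation")]
  g <- g[order(match(g$model, .all_models), g$omega,
               match(g$variation, names(.variation_levels))), ]
  rownames(g) <- NULL
  g$cell_id <- sprintf("%s_w%g_%s", g$model, g$omega, g$variation)
  g$replicates <- replicates
  g$base_seed <- base_seed
  g[, c("cell_id", "model", "omega", "variation", "replicates", "base_seed")]
}

#' Draw the initial community of a design cell
#'
#' Generates the starting [species_ensemble()] for one replicate: `S`
#' species at density 1; initial mean traits uniform on \eqn{(-0.5, 0.5)}
#' for the `evo` family and \eqn{(0, 2)} for the `hier` family; trait sds
#' uniform within the cell's variation level; heritabilities uniform on
#' \eqn{(0.1, 0.15)}.
#'
#' The seed is a function of the base seed and the replicate index only,
#' and the underlying uniform draws are mapped to each range afterwards.
#' Consequently a given replicate index yields the *same* initial trait
#' means across models sharing a trait range (evo vs evoHOI, hier vs
#' hierHOI) and the same per-species \eqn{\sigma} and \eqn{h^2} draws
#' across all cells, so that matched replicates are directly comparable.
#'
#' @param cell One row of a [build_grid()] table (data frame or list with
#'   `model`, `variation`, `base_seed`).
#' @param replicate Replicate index (1-based).
#' @param n_species Number of species (default 40).
#' @return A [species_ensemble()].
#' @export
draw_initial_conditions <- function(cell, replicate, n_species = 40) {
  model <- as.character(cell$model)
  if (!model %in% .all_models) stop("unknown model: ", model, call. = FALSE)
  lev <- .variation_levels[[as.character(cell$variation)]]
  if (is.null(lev))
    stop("unknown variation level: ", cell$variation, call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(.replicate_seed(cell$base_seed, replicate))
  u_raw <- runif(n_species)
  s_raw <- runif(n_species)
  h_raw <- runif(n_species)
  u0 <- if (model %in% c("evo", "evoHOI")) u_raw - 0.5 else 2 * u_raw
  species_ensemble(
    N = rep(1, n_species),
    u = u0,
    sigma = lev[1] + (lev[2] - lev[1]) * s_raw,
    h2 = 0.1 + 0.05 * h_raw
  )
}

#' Run one replicate of a design cell
#'
#' Draws the initial community, integrates it to eco-evolutionary
#' equilibrium and computes the outcome metrics.
#'
#' @inheritParams draw_initial_conditions
#' @param n_null Null communities for the clustering p-value.
#' @param hoi_prefactor Passed to [model_params()].
#' @param ... Further arguments to [integrate_to_equilibrium()]
#'   (`eq_tol`, `t_max`, `extinction_threshold`, ...).
#' @return A list of class `"replicate_result"` with fields `cell_id`,
#'   `model`, `omega`, `variation`, `replicate`, `seed`, `eq`
#'   (the [integrate_to_equilibrium()] result) and `metrics`
#'   (a [metrics_record()]).
#' @export
run_replicate <- function(cell, replicate, n_species = 40, n_null = 1000,
                          hoi_prefactor = "default", ...) {
  params <- model_params(as.character(cell$model), omega = cell$omega,
                         hoi_prefactor = hoi_prefactor)
  ic <- draw_initial_conditions(cell, replicate, n_species = n_species)
  eq <- integrate_to_equilibrium(ic, params, ...)
  met <- metrics_record(eq, params, n_null = n_null,
                        null_seed = .null_seed(cell$base_seed,
                                               as.character(cell$cell_id),
                                               replicate))
  structure(list(cell_id = as.character(cell$cell_id),
                 model = params$model, omega = cell$omega,
                 variation = as.character(cell$variation),
                 replicate = replicate,
                 seed = .replicate_seed(cell$base_seed, replicate),
                 params = params, eq = eq, metrics = met),
            class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("<replicate_result> %s replicate %d (seed %d)\n",
              x$cell_id, x$replicate, x$seed))
  print(x$eq)
  print(x$metrics)
  invisible(x)
}

.replicate_row <- function(r) {
  keep <- r$eq$survivors
  data.frame(
    cell_id = r$cell_id, model = r$model, omega = r$omega,
    variation = r$variation, replicate = r$replicate, seed = r$seed,
    converged = r$eq$converged, t_final = r$eq$t_final,
    richness = r$metrics$richness, D = r$metrics$D,
    gap_cv = r$metrics$gap_cv, clustering_p = r$metrics$clustering_p,
    robustness = r$metrics$robustness,
    survivor_u = as.character(jsonlite::toJSON(r$eq$state$u[keep],
                                               digits = NA)),
    survivor_N = as.character(jsonlite::toJSON(r$eq$state$N[keep],
                                               digits = NA)),
    failed = FALSE, error = NA_character_,
    stringsAsFactors = FALSE
  )
}

.failed_row <- function(cell, replicate, msg) {
  data.frame(
    cell_id = as.character(cell$cell_id), model = as.character(cell$model),
    omega = cell$omega, variation = as.character(cell$variation),
    replicate = replicate,
    seed = .replicate_seed(cell$base_seed, replicate),
    converged = NA, t_final = NA_real_, richness = NA_integer_,
    D = NA_real_, gap_cv = NA_real_, clustering_p = NA_real_,
    robustness = NA_real_, survivor_u = NA_character_,
    survivor_N = NA_character_, failed = TRUE, error = msg,
    stringsAsFactors = FALSE
  )
}

#' Run a replicated simulation campaign
#'
#' Executes every (cell, replicate) combination of the design and returns
#' one tidy row per replicate.  Replicates are independent, so any
#' execution order (including parallel execution) yields identical rows;
#' integration failures are recorded in the `failed`/`error` columns
#' rather than aborting the campaign.
#'
#' @param grid A [build_grid()] table (or subset of its rows).
#' @param replicates Optional override of the per-cell replicate count.
#' @param n_species,n_null,hoi_prefactor,... Passed to [run_replicate()].
#' @param cores Number of worker processes (forked via the parallel
#'   package when > 1).
#' @param keep_results If `TRUE`, attach the full list of
#'   `replicate_result` objects as attribute `"results"` (useful for
#'   follow-up diagnostics such as [effective_kernel()]).
#' @return A data frame with columns `cell_id`, `model`, `omega`,
#'   `variation`, `replicate`, `seed`, `converged`, `t_final`, `richness`,
#'   `D`, `gap_cv`, `clustering_p`, `robustness`, plus survivor trait and
#'   density vectors as JSON list columns and failure diagnostics.
#' @export
run_ensemble <- function(grid, replicates = NULL, n_species = 40,
                         n_null = 1000, hoi_prefactor = "default",
                         cores = 1L, keep_results = FALSE, ...) {
  jobs <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    reps <- if (is.null(replicates)) cell$replicates else replicates
    for (r in seq_len(reps))
      jobs[[length(jobs) + 1L]] <- list(cell = cell, replicate = r)
  }
  worker <- function(job) {
    tryCatch({
      res <- run_replicate(job$cell, job$replicate, n_species = n_species,
                           n_null = n_null, hoi_prefactor = hoi_prefactor,
                           ...)
      list(row = .replicate_row(res), res = res)
    }, error = function(e) {
      list(row = .failed_row(job$cell, job$replicate, conditionMessage(e)),
           res = NULL)
    })
  }
  out <- if (cores > 1L) {
    parallel::mclapply(jobs, worker, mc.cores = cores)
  } else {
    lapply(jobs, worker)
  }
  tab <- do.call(rbind, lapply(out, `[[`, "row"))
  rownames(tab) <- NULL
  if (keep_results) attr(tab, "results") <- lapply(out, `[[`, "res")
  tab
}

#' Write campaign outputs
#'
#' Writes the tidy replicate table as a UTF-8 CSV with a deterministic
#' column order, plus a JSON sidecar echoing the design, the seeds and the
#' package version.
#'
#' @param tab A [run_ensemble()] table.
#' @param path CSV output path; the sidecar is written next to it with
#'   extension `.json`.
#' @param config Optional list echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(tab, path, config = NULL) {
  write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  sidecar <- list(
    package = "hoisim",
    version = as.character(utils::packageVersion("hoisim")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    cells = unique(tab$cell_id),
    base_seeds = unique(tab$seed)
  )
  jsonlite::write_json(sidecar,
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
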