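#' Plan for a full Monte Carlo experiment
#'
#' Describes the scenario grid (the cross of sample sizes and group counts),
#' the number of replicates per cell, the master seed and the fitting
#' policies. Defaults reproduce the study grid: N in \{30, 60, 120\} crossed
#' with \{3, 5, 10\} group levels, 10,000 replicates per cell.
#'
#' @param n_obs Integer vector of sample sizes.
#' @param n_levels Integer vector of grouping-factor level counts.
#' @param n_reps Replicates per cell (>= 1).
#' @param seed Master seed; per-cell and per-replicate child streams are
#'   derived from it, so results do not depend on cell execution order.
#' @param alpha Interval miscoverage (default 0.05).
#' @param singular_tol Singularity threshold on theta (default 1e-4).
#' @param ci_method LMM interval policy, `"z"` or `"t"` (see [fit_lmm()]).
#' @param ... Generating parameters passed on to [scenario_config()]
#'   (`beta0`, `beta1`, `beta2`, `sigma2_site`, `sigma2_resid`, `var_x`).
#' @return An object of class `experiment_plan` with a `cells` list of
#'   [scenario_config()]s (row-major over `n_obs` x `n_levels`).
#' @export
experiment_plan <- function(n_obs = c(30L, 60L, 120L),
                            n_levels = c(3L, 5L, 10L),
                            n_reps = 10000L, seed = 1L,
                            alpha = 0.05, singular_tol = 1e-4,
                            ci_method = c("z", "t"), ...) {
  ci_method <- match.arg(ci_method)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) {
    stop("`n_reps` must be a positive integer", call. = FALSE)
  }
  grid <- expand.grid(n_levels = as.integer(n_levels),
                      n_obs = as.integer(n_obs))[, c("n_obs", "n_levels")]
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    scenario_config(grid$n_obs[i], grid$n_levels[i], ...)
  })
  structure(
    list(cells = cells, n_reps = n_reps, seed = as.integer(seed),
         alpha = alpha, singular_tol = singular_tol, ci_method = ci_method),
    class = "experiment_plan"
  )
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat("Experiment plan:", length(x$cells), "cells x", x$n_reps,
      "replicates (seed", paste0(x$seed, ")"), "\n")
  for (cfg in x$cells) {
    cat(sprintf("  N = %3d, levels = %2d\n", cfg$n_obs, cfg$n_levels))
  }
  invisible(x)
}

# Lightweight per-dataset checksum used to verify that the LM and LMM rows
# of a replicate were fit to the same data.
dataset_checksum <- function(dataset) {
  signif(sum(dataset$y) + 2 * sum(dataset$x1) + 3 * sum(dataset$x2) +
           sum(dataset$group) / length(dataset$group), 15)
}

#' Run all replicates of one scenario cell
#'
#' For each replicate: draw one dataset, fit both the dummy-coded LM and the
#' random-intercept LMM to the *same* data, and emit long-format records —
#' the two slope estimates for each model plus the intercept and the
#' random-effect variance estimate for the LMM (6 rows per replicate). A
#' replicate whose fit fails is kept as a row with `converged = FALSE` and
#' `NA` estimates rather than silently redrawn, which would bias the Monte
#' Carlo distribution.
#'
#' @param config A [scenario_config()].
#' @param n_reps Number of replicates.
#' @param stream An L'Ecuyer-CMRG cell stream (internal; when `NULL`, one is
#'   derived from `seed`).
#' @param seed Convenience master seed used when `stream` is `NULL`.
#' @param alpha,singular_tol,ci_method Fitting policies, see [fit_lmm()].
#' @return Long-format data frame: columns `n_obs`, `n_levels`, `rep`,
#'   `model` (`"LM"`/`"LMM"`), `parameter` (`beta1`, `beta2`, `intercept`,
#'   `sigma2_site`), `estimate`, `ci_low`, `ci_high`, `truth`, `singular`,
#'   `converged`, `checksum`.
#' @export
run_cell <- function(config, n_reps, stream = NULL, seed = 1L,
                     alpha = 0.05, singular_tol = 1e-4, ci_method = "z") {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 1L)
  if (is.null(stream)) stream <- cell_stream(master_stream(seed), 1L)
  n_reps <- as.integer(n_reps)
  k <- 6L  # rows per replicate
  nr <- n_reps * k
  rep_idx <- rep(seq_len(n_reps), each = k)
  model <- character(nr); parameter <- character(nr)
  estimate <- rep(NA_real_, nr); ci_low <- rep(NA_real_, nr)
  ci_high <- rep(NA_real_, nr); truth <- rep(NA_real_, nr)
  singular <- rep(FALSE, nr); converged <- rep(TRUE, nr)
  checksum <- rep(NA_real_, nr)

  old_seed <- get0(".Random.seed", envir = globalenv())
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  s <- stream
  for (r in seq_len(n_reps)) {
    s <- parallel::nextRNGSubStream(s)
    assign(".Random.seed", s, envir = globalenv())
    rows <- (r - 1L) * k + seq_len(k)
    model[rows] <- c("LM", "LM", "LMM", "LMM", "LMM", "LMM")
    parameter[rows] <- c("beta1", "beta2", "beta1", "beta2",
                         "intercept", "sigma2_site")
    truth[rows] <- c(config$beta1, config$beta2, config$beta1, config$beta2,
                     config$beta0, config$sigma2_site)
    res <- tryCatch({
      d <- gen_dataset(config)
      lmf <- fit_lm(d, alpha = alpha)
      mmf <- fit_lmm(d, alpha = alpha, singular_tol = singular_tol,
                     ci_method = ci_method)
      list(d = d, lmf = lmf, mmf = mmf)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      converged[rows] <- FALSE
      next
    }
    est_rows <- rbind(res$lmf$slopes, res$mmf$slopes, res$mmf$intercept)
    estimate[rows] <- c(est_rows$estimate, res$mmf$sigma2_site_hat)
    ci_low[rows] <- c(est_rows$ci_low, NA_real_)
    ci_high[rows] <- c(est_rows$ci_high, NA_real_)
    singular[rows] <- c(FALSE, FALSE, rep(res$mmf$singular, 4L))
    converged[rows] <- c(TRUE, TRUE, rep(res$mmf$converged, 4L))
    checksum[rows] <- dataset_checksum(res$d)
  }
  data.frame(
    n_obs = config$n_obs, n_levels = config$n_levels, rep = rep_idx,
    model = model, parameter = parameter, estimate = estimate,
    ci_low = ci_low, ci_high = ci_high, truth = truth,
    singular = singular, converged = converged, checksum = checksum,
    stringsAsFactors = FALSE
  )
}

#' Run the full Monte Carlo experiment
#'
#' Executes every cell of the plan with its pre-assigned random stream (so
#' results are identical however cells are ordered or parallelized), stacks
#' the per-replicate records, and computes both unstratified and
#' singularity-stratified summaries. Optionally persists everything as CSV
#' plus a JSON metadata sidecar.
#'
#' @param plan An [experiment_plan()].
#' @param out_dir Output directory; when non-`NULL`, writes
#'   `replicates.csv`, `summary.csv`, `summary_by_singular.csv` and
#'   `metadata.json` there (created if needed).
#' @param verbose Print per-cell progress?
#' @return List with `records` (long data frame), `summary`,
#'   `summary_by_singular`, and `plan`.
#' @export
run_experiment <- function(plan, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    probe <- file.path(out_dir, ".write_probe")
    ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
    if (!isTRUE(ok)) {
      stop("output directory is not writable: ", out_dir, call. = FALSE)
    }
    unlink(probe)
  }
  master <- master_stream(plan$seed)
  records <- vector("list", length(plan$cells))
  for (i in seq_along(plan$cells)) {
    cfg <- plan$cells[[i]]
    if (verbose) {
      message(sprintf("cell %d/%d: N = %d, levels = %d (%d reps)",
                      i, length(plan$cells), cfg$n_obs, cfg$n_levels,
                      plan$n_reps))
    }
    t0 <- proc.time()[["elapsed"]]
    records[[i]] <- run_cell(cfg, plan$n_reps,
                             stream = cell_stream(master, i),
                             alpha = plan$alpha,
                             singular_tol = plan$singular_tol,
                             ci_method = plan$ci_method)
    if (verbose) {
      message(sprintf("  done in %.1f s", proc.time()[["elapsed"]] - t0))
    }
  }
  records <- do.call(rbind, records)
  summary <- summarize_records(records)
  lmm_rec <- records[records$model == "LMM", , drop = FALSE]
  summary_strat <- summarize_records(lmm_rec, stratify_by_singular = TRUE)
  result <- list(records = records, summary = summary,
                 summary_by_singular = summary_strat, plan = plan)
  if (!is.null(out_dir)) {
    utils::write.csv(records, file.path(out_dir, "replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_strat,
                     file.path(out_dir, "summary_by_singular.csv"),
                     row.names = FALSE)
    meta <- list(
      package = "fewlevels",
      version = as.character(utils::packageVersion("fewlevels")),
      seed = plan$seed, n_reps = plan$n_reps,
      alpha = plan$alpha, singular_tol = plan$singular_tol,
      interval_policy = list(lm = "t", lmm = plan$ci_method),
      quantile_type = 7,
      cells = lapply(plan$cells, function(c) {
        list(n_obs = c$n_obs, n_levels = c$n_levels)
      }),
      generator = plan$cells[[1]][c("beta0", "beta1", "beta2", "sigma2_site",
                                    "sigma2_resid", "var_x")]
    )
    jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}
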