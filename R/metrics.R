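#' @title Monte Carlo evaluation metrics
#' @description Functions that turn per-replicate fit records (long format:
#'   one row per scenario x replicate x model x parameter) into the study's
#'   evaluation quantities: coverage probability of 95\% confidence
#'   intervals, relative RMSE, bias, mean variance-component estimates with
#'   empirical 95\% quantile intervals, and singular-fit proportions, with
#'   optional stratification by singular-fit status.
#' @name metrics
NULL

check_records <- function(records) {
  needed <- c("estimate", "ci_low", "ci_high", "truth")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("`records` must be a data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("metric undefined on an empty set of records", call. = FALSE)
  }
  invisible(records)
}

#' Coverage probability of confidence intervals
#'
#' Fraction of replicate records whose interval contains the true generating
#' value; interval endpoints count as covered (an event of probability zero
#' under the continuous model, fixed for determinism).
#'
#' @param records Data frame with columns `ci_low`, `ci_high`, `truth`
#'   (records for a single scenario cell, model and parameter).
#' @return Proportion in \[0, 1\].
#' @export
coverage <- function(records) {
  check_records(records)
  mean(records$ci_low <= records$truth & records$truth <= records$ci_high)
}

#' Relative root-mean-square error of the point estimates
#'
#' RMSE normalized by the absolute true value, so panels for slopes of
#' different magnitude (2 and 0.2) are on comparable scales:
#' `sqrt(mean((estimate - truth)^2)) / |truth|`.
#'
#' @inheritParams coverage
#' @return Nonnegative scalar.
#' @export
relative_rmse <- function(records) {
  check_records(records)
  truth <- unique(records$truth)
  if (any(truth == 0)) {
    stop("relative RMSE is undefined for truth = 0; use an absolute RMSE",
         call. = FALSE)
  }
  sqrt(mean((records$estimate - records$truth)^2)) / abs(records$truth[1L])
}

#' Mean estimate and bias
#'
#' @inheritParams coverage
#' @return Named list with `mean_estimate` and `bias`
#'   (`mean_estimate - truth`).
#' @export
bias_and_mean <- function(records) {
  check_records(records)
  m <- mean(records$estimate)
  list(mean_estimate = m, bias = m - records$truth[1L])
}

#' Empirical quantile interval
#'
#' Quantiles by linear interpolation of order statistics (R's default
#' type 7 definition).
#'
#' @param values Numeric vector of point estimates.
#' @param lo,hi Probabilities, `0 <= lo < hi <= 1` (defaults 0.025, 0.975).
#' @return Numeric vector `c(q_lo, q_hi)`.
#' @examples
#' quantile_interval(1:100)  # c(3.475, 97.525)
#' @export
quantile_interval <- function(values, lo = 0.025, hi = 0.975) {
  stopifnot(is.numeric(values), length(values) > 0,
            lo >= 0, hi <= 1, lo < hi)
  unname(stats::quantile(values, c(lo, hi), type = 7))
}

#' Proportion of singular mixed-model fits
#'
#' @param records Data frame of LMM records with a logical `singular` column.
#' @return Proportion in \[0, 1\].
#' @export
singular_proportion <- function(records) {
  if (!is.data.frame(records) || !"singular" %in% names(records)) {
    stop("`records` must be a data frame with a `singular` column",
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("metric undefined on an empty set of records", call. = FALSE)
  }
  mean(records$singular)
}

#' Summarize replicate records into per-scenario metrics
#'
#' Aggregates a long-format record table into one row per combination of
#' scenario cell (`n_obs`, `n_levels`), model, parameter and — if
#' `stratify_by_singular = TRUE` — singular-fit status. Non-converged fits
#' are excluded from the metrics and counted in the `n_excluded` column.
#' Strata with zero usable records are omitted; strata with exactly one
#' record are flagged (`flagged = TRUE`) since a single replicate cannot
#' represent a Monte Carlo mean. Coverage is reported as `NA` for
#' parameters without intervals (the random-effect variance); relative RMSE
#' is `NA` when the truth is zero.
#'
#' @param records Long-format data frame as produced by [run_cell()].
#' @param stratify_by_singular Split each cell into singular and
#'   non-singular LMM strata (Figs.-style stratified summaries)?
#' @return Data frame of class `scenario_summary` with columns `n_obs`,
#'   `n_levels`, `model`, `parameter` (optionally `singular`), `n_reps`,
#'   `n_excluded`, `coverage`, `relative_rmse`, `bias`, `mean_estimate`,
#'   `q025`, `q975`, `singular_proportion`, `flagged`.
#' @export
summarize_records <- function(records, stratify_by_singular = FALSE) {
  needed <- c("n_obs", "n_levels", "model", "parameter", "estimate",
              "ci_low", "ci_high", "truth", "singular", "converged")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("`records` must be a long-format record table with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  keys <- c("n_obs", "n_levels", "model", "parameter",
            if (stratify_by_singular) "singular")
  key_df <- records[keys]
  groups <- split(seq_len(nrow(records)), key_df, drop = TRUE)
  rows <- lapply(groups, function(idx) {
    block <- records[idx, , drop = FALSE]
    used <- block[block$converged & is.finite(block$estimate), , drop = FALSE]
    n_excluded <- nrow(block) - nrow(used)
    if (nrow(used) == 0L) return(NULL)
    truth <- used$truth[1L]
    cov <- if (anyNA(used$ci_low)) NA_real_ else coverage(used)
    rrmse <- if (truth != 0) relative_rmse(used) else NA_real_
    bm <- bias_and_mean(used)
    qi <- quantile_interval(used$estimate)
    out <- used[1L, keys, drop = FALSE]
    out$n_reps <- nrow(used)
    out$n_excluded <- n_excluded
    out$coverage <- cov
    out$relative_rmse <- rrmse
    out$bias <- bm$bias
    out$mean_estimate <- bm$mean_estimate
    out$q025 <- qi[1L]
    out$q975 <- qi[2L]
    out$singular_proportion <-
      if (used$model[1L] == "LMM") mean(used$singular) else NA_real_
    out$flagged <- nrow(used) == 1L
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$n_obs, out$n_levels, out$model, out$parameter), ,
             drop = FALSE]
  class(out) <- c("scenario_summary", "data.frame")
  out
}
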