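#' Allocate observations to group levels, rejecting balanced designs
#'
#' Builds an unbalanced allocation of `n_obs` observations to `n_levels`
#' levels of a grouping factor: one observation is first placed in every
#' level, the remaining `n_obs - n_levels` observations are assigned
#' uniformly at random (with replacement) across levels, and any allocation
#' in which every level ends up with the same count is discarded and redrawn
#' from scratch. Balanced designs are excluded because in that special case
#' the fixed-effects estimators are independent of the random effects, which
#' would blur the comparison the simulations are designed to make.
#'
#' Uses the current state of R's random number generator; seed control is
#' the caller's responsibility (see [run_cell()] for the stream scheme).
#'
#' @param n_obs Total number of observations; must exceed `n_levels`.
#' @param n_levels Number of group levels.
#' @return Integer vector of length `n_obs` with values in `1:n_levels`;
#'   every level present, counts not all equal. The first `n_levels`
#'   elements are the guaranteed one-per-level placements.
#' @examples
#' set.seed(1)
#' table(allocate_groups(30, 3))
#' @export
allocate_groups <- function(n_obs, n_levels) {
  n_obs <- as.integer(n_obs)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) {
    stop("`n_levels` must be >= 2: with a single level every allocation is ",
         "balanced and rejection cannot terminate", call. = FALSE)
  }
  if (n_obs <= n_levels) {
    stop("invalid configuration: `n_obs` (", n_obs, ") must exceed `n_levels` (",
         n_levels, "); rejection of balanced allocations could not terminate",
         call. = FALSE)
  }
  n_extra <- n_obs - n_levels
  repeat {
    extra <- sample.int(n_levels, n_extra, replace = TRUE)
    labels <- c(seq_len(n_levels), extra)
    counts <- tabulate(labels, nbins = n_levels)
    if (length(unique(counts)) > 1L) {
      return(labels)
    }
    # balanced by chance: discard the whole allocation and redraw
  }
}

#' Generate one grouped Gaussian dataset
#'
#' Draws a dataset from the generating model
#' `y_i = beta0 + Site_j(i) + beta1 * x1_i + beta2 * x2_i + e_i`
#' with `Site_j ~ N(0, sigma2_site)`, `e_i ~ N(0, sigma2_resid)` and
#' predictors `x1, x2 ~ N(0, var_x)`, on an unbalanced allocation from
#' [allocate_groups()]. The drawn site effects are retained so downstream
#' scoring can compare estimates against the generating truth.
#'
#' @param config A [scenario_config()].
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called
#'   first. Otherwise the current RNG state is used.
#' @return An object of class `sim_dataset`: a list with vectors `y`, `x1`,
#'   `x2`, integer `group` (labels `1:n_levels`), `true_site_effects`
#'   (length `n_levels`) and the `config`.
#' @examples
#' d <- gen_dataset(scenario_config(30, 3), seed = 42)
#' table(d$group)
#' @export
gen_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  group <- allocate_groups(config$n_obs, config$n_levels)
  site <- stats::rnorm(config$n_levels, 0, sqrt(config$sigma2_site))
  x1 <- stats::rnorm(config$n_obs, 0, sqrt(config$var_x))
  x2 <- stats::rnorm(config$n_obs, 0, sqrt(config$var_x))
  eps <- stats::rnorm(config$n_obs, 0, sqrt(config$sigma2_resid))
  y <- config$beta0 + site[group] + config$beta1 * x1 + config$beta2 * x2 + eps
  structure(
    list(y = y, x1 = x1, x2 = x2, group = group,
         true_site_effects = site, config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", x$config$n_obs, "observations in",
      x$config$n_levels, "groups\n")
  cat("  group counts:", paste(tabulate(x$group, x$config$n_levels),
                               collapse = " "), "\n")
  invisible(x)
}

#' Write a simulated dataset to CSV
#'
#' Columns `y`, `x1`, `x2`, `group` with a header row; "." decimal separator.
#'
#' @param dataset A `sim_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "sim_dataset"))
  utils::write.csv(
    data.frame(y = dataset$y, x1 = dataset$x1, x2 = dataset$x2,
               group = dataset$group),
    path, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
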