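#' Scenario configuration for the grouped-Gaussian generator
#'
#' Bundles all data-generating parameters for one simulation cell: the total
#' number of observations, the number of levels of the grouping factor
#' (sites, individuals, populations, ...), the fixed-effect coefficients and
#' the variance components. Defaults reproduce the study conditions: an
#' overall intercept of 73, a strong slope of 2 and a weak slope of 0.2 on
#' two standard-normal-like predictors (mean 0, variance 0.5), site effects
#' drawn from Normal(0, 1) and residual noise Normal(0, 1).
#'
#' @param n_obs Total number of observations (30, 60 or 120 in the study grid).
#' @param n_levels Number of levels of the grouping factor (3, 5 or 10 in the
#'   study grid). Must be strictly less than `n_obs` so that an unbalanced
#'   allocation exists.
#' @param beta0 Overall intercept (grand mean across groups).
#' @param beta1 Slope of the first (stronger) predictor.
#' @param beta2 Slope of the second (weaker) predictor.
#' @param sigma2_site Variance of the group-level random intercepts.
#' @param sigma2_resid Residual (observation-level) variance.
#' @param var_x Variance of each predictor.
#' @return An object of class `scenario_config` (a validated list).
#' @examples
#' cfg <- scenario_config(n_obs = 30, n_levels = 3)
#' cfg$beta1
#' @export
scenario_config <- function(n_obs, n_levels,
                            beta0 = 73, beta1 = 2, beta2 = 0.2,
                            sigma2_site = 1, sigma2_resid = 1,
                            var_x = 0.5) {
  n_obs <- as.integer(n_obs)
  n_levels <- as.integer(n_levels)
  if (length(n_obs) != 1L || is.na(n_obs) || n_obs < 1L) {
    stop("`n_obs` must be a single positive integer", call. = FALSE)
  }
  if (length(n_levels) != 1L || is.na(n_levels) || n_levels < 2L) {
    stop("`n_levels` must be a single integer >= 2 (with a single level no ",
         "unbalanced allocation exists)", call. = FALSE)
  }
  if (n_obs <= n_levels) {
    stop("invalid configuration: `n_obs` (", n_obs, ") must exceed `n_levels` (",
         n_levels, "); otherwise only the balanced allocation exists and ",
         "rejection of balanced designs cannot terminate", call. = FALSE)
  }
  for (nm in c("beta0", "beta1", "beta2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  for (nm in c("sigma2_site", "sigma2_resid", "var_x")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single nonnegative number", call. = FALSE)
    }
  }
  structure(
    list(n_obs = n_obs, n_levels = n_levels,
         beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
         beta2 = as.numeric(beta2),
         sigma2_site = as.numeric(sigma2_site),
         sigma2_resid = as.numeric(sigma2_resid),
         var_x = as.numeric(var_x)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario: N =", x$n_obs, "observations,", x$n_levels, "group levels\n")
  cat(sprintf("  y = %g + Site + %g*x1 + %g*x2 + e\n", x$beta0, x$beta1, x$beta2))
  cat(sprintf("  Site ~ N(0, %g), e ~ N(0, %g), x1, x2 ~ N(0, %g)\n",
              x$sigma2_site, x$sigma2_resid, x$var_x))
  invisible(x)
}
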