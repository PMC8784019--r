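#' @title Model fitting for the simulation study
#' @description Two competing fits to the same dataset: an ordinary linear
#'   model with the grouping factor dummy-coded as fixed effects, and a
#'   random-intercept linear mixed model estimated by restricted maximum
#'   likelihood (REML), profiled over the ratio of the random-intercept
#'   standard deviation to the residual standard deviation.
#' @name estimators
NULL

# Design matrix for the dummy-coded LM: intercept, x1, x2, treatment-coded
# group dummies (levels 2..J). Column names kept for rank-deficiency reports.
lm_design <- function(dataset) {
  J <- dataset$config$n_levels
  n <- dataset$config$n_obs
  X <- matrix(0, n, 2L + J)
  X[, 1L] <- 1
  X[, 2L] <- dataset$x1
  X[, 3L] <- dataset$x2
  if (J > 1L) {
    for (j in 2:J) X[dataset$group == j, 2L + j] <- 1
  }
  colnames(X) <- c("(Intercept)", "x1", "x2",
                   if (J > 1L) paste0("group", 2:J))
  X
}

# Relative-tolerance rank check on the singular values of a design matrix;
# errors naming the offending column.
check_full_rank <- function(X, tol = 1e-10) {
  d <- svd(X, nu = 0, nv = 0)$d
  if (d[length(d)] < tol * d[1L]) {
    qr_x <- qr(X, tol = tol)
    bad <- setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])
    stop("design matrix is rank deficient; offending column(s): ",
         paste(colnames(X)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

fe_row <- function(name, estimate, se, crit) {
  data.frame(name = name, estimate = estimate, se = se,
             ci_low = estimate - crit * se,
             ci_high = estimate + crit * se,
             stringsAsFactors = FALSE)
}

#' Fit the dummy-coded linear model
#'
#' Ordinary least squares of `y` on an intercept, the two predictors and
#' treatment-coded dummies for the grouping factor, so that an independent
#' intercept term is estimated for each group level (no pooling). Slope
#' confidence intervals use t quantiles with `n - n_levels - 2` residual
#' degrees of freedom.
#'
#' @param dataset A `sim_dataset` from [gen_dataset()].
#' @param alpha Two-sided interval miscoverage; intervals have nominal level
#'   `1 - alpha` (default 0.05 for 95\% CIs).
#' @return An object of class `lm_fit`: list with `slopes` (data frame of
#'   the two slope estimates with SEs and CIs), `group_effects` (per-level
#'   intercepts, grand intercept plus dummy contrasts), `sigma2_resid_hat`
#'   (RSS / df) and `df_resid`.
#' @examples
#' d <- gen_dataset(scenario_config(60, 5), seed = 7)
#' fit_lm(d)$slopes
#' @export
fit_lm <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "sim_dataset"),
            is.numeric(alpha), alpha > 0, alpha < 1)
  X <- lm_design(dataset)
  check_full_rank(X)
  n <- nrow(X)
  p <- ncol(X)
  fit <- stats::lm.fit(X, dataset$y)
  coefs <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df_resid <- n - p  # = n_obs - (n_levels + 2)
  sigma2 <- rss / df_resid
  XtX_inv <- chol2inv(chol(crossprod(X)))
  ses <- sqrt(sigma2 * diag(XtX_inv))
  crit <- stats::qt(1 - alpha / 2, df_resid)
  slopes <- rbind(fe_row("beta1", coefs[["x1"]], ses[2L], crit),
                  fe_row("beta2", coefs[["x2"]], ses[3L], crit))
  J <- dataset$config$n_levels
  group_effects <- coefs[[1L]] +
    c(0, if (J > 1L) coefs[4:(2L + J)] else numeric(0))
  names(group_effects) <- paste0("alpha", seq_len(J))
  structure(
    list(slopes = slopes, group_effects = group_effects,
         sigma2_resid_hat = sigma2, df_resid = df_resid, alpha = alpha),
    class = "lm_fit"
  )
}

# Internal REML workhorse on an arbitrary fixed-effect design.
#
# Marginal covariance V(theta) = I + theta^2 Z Z', block-diagonal by group,
# inverted analytically (Woodbury): within a group of size n_j,
# V^{-1} = I - theta^2 / (1 + theta^2 n_j) * J. All quantities needed by the
# restricted likelihood reduce to per-group sums.
reml_parts <- function(y, X, group, n_levels, theta) {
  n <- length(y)
  p <- ncol(X)
  nj <- tabulate(group, nbins = n_levels)
  w <- theta^2 / (1 + theta^2 * nj)  # per-group Woodbury weight
  # V^{-1} M for a matrix/vector M: M - w_g * colSums-by-group expanded
  gs_X <- rowsum(X, group)                 # n_levels x p group sums
  gs_y <- rowsum(y, group)[, 1L]
  A <- crossprod(X) - crossprod(gs_X * sqrt(w), gs_X * sqrt(w))  # X'V^{-1}X
  b <- crossprod(X, y) - crossprod(gs_X * w, gs_y)               # X'V^{-1}y
  yVy <- sum(y^2) - sum(w * gs_y^2)
  cA <- chol(A)
  beta <- backsolve(cA, forwardsolve(t(cA), b))
  quad <- yVy - sum(b * beta)              # r'V^{-1}r at the GLS solution
  quad <- max(quad, 0)
  logdetV <- sum(log1p(theta^2 * nj))
  logdetA <- 2 * sum(log(diag(cA)))
  list(beta = drop(beta), quad = quad, logdetV = logdetV, logdetA = logdetA,
       A = A, n = n, p = p)
}

reml_objective_value <- function(y, X, group, n_levels, theta) {
  parts <- reml_parts(y, X, group, n_levels, theta)
  parts$logdetV + parts$logdetA + (parts$n - parts$p) * log(parts$quad)
}

#' Profiled REML criterion of the random-intercept model
#'
#' Minus twice the restricted log-likelihood, up to an additive constant,
#' profiled over the fixed effects and the residual variance so that it
#' depends only on `theta`, the ratio of the random-intercept standard
#' deviation to the residual standard deviation. With
#' `V(theta) = I + theta^2 Z Z'` (`Z` the group indicator matrix) and
#' `r` the GLS residual,
#' `criterion = log det V + log det(X' V^{-1} X) + (n - p) log(r' V^{-1} r)`.
#'
#' @param dataset A `sim_dataset`.
#' @param theta Nonnegative scalar (or vector, evaluated elementwise).
#' @return Criterion value(s); finite for all finite `theta`.
#' @examples
#' d <- gen_dataset(scenario_config(30, 3), seed = 1)
#' reml_criterion(d, c(0, 0.5, 1))
#' @export
reml_criterion <- function(dataset, theta) {
  stopifnot(inherits(dataset, "sim_dataset"),
            is.numeric(theta), all(theta >= 0))
  X <- cbind(`(Intercept)` = 1, x1 = dataset$x1, x2 = dataset$x2)
  vapply(theta, function(th) {
    reml_objective_value(dataset$y, X, dataset$group,
                         dataset$config$n_levels, th)
  }, numeric(1))
}

# Profile-REML optimum over theta >= 0 for response y, design X, grouping.
# Bracket grown geometrically until the criterion increases; boundary theta=0
# compared explicitly; ties resolve to the smaller theta.
reml_profile_fit <- function(y, X, group, n_levels) {
  obj <- function(th) reml_objective_value(y, X, group, n_levels, th)
  f0 <- obj(0)
  upper <- 1
  f_up <- obj(upper)
  while (obj(upper * 2) < f_up && upper < 1e6) {
    upper <- upper * 2
    f_up <- obj(upper)
  }
  opt <- stats::optimize(obj, c(0, upper * 2), tol = 1e-8)
  theta <- opt$minimum
  f_min <- opt$objective
  if (f0 <= f_min + 1e-9) {  # boundary at least as good: take theta = 0
    theta <- 0
    f_min <- f0
  }
  converged <- is.finite(f_min)
  parts <- reml_parts(y, X, group, n_levels, theta)
  sigma2_resid <- parts$quad / (parts$n - parts$p)
  list(theta = theta, objective = f_min, beta = parts$beta,
       sigma2_resid = sigma2_resid,
       sigma2_site = theta^2 * sigma2_resid,
       cov_beta = sigma2_resid * chol2inv(chol(parts$A)),
       converged = converged)
}

#' Fit the random-intercept linear mixed model by profiled REML
#'
#' Estimates the model `y ~ x1 + x2 + (1 | group)`: fixed intercept and two
#' slopes, a Gaussian random intercept per group level, Gaussian residuals.
#' The REML criterion is profiled down to the single ratio
#' `theta = sd(random intercept) / sd(residual)` and minimized over
#' `theta >= 0`; the boundary is permitted and a fit with `theta` below
#' `singular_tol` is flagged singular (random-effect variance estimated at,
#' or numerically at, zero).
#'
#' @param dataset A `sim_dataset`.
#' @param alpha Two-sided interval miscoverage (default 0.05).
#' @param singular_tol Threshold on `theta` below which the fit is declared
#'   singular (default 1e-4, the de facto standard in mixed-model software).
#' @param ci_method `"z"` (default) for Wald intervals with standard-normal
#'   quantiles, or `"t"` for t quantiles with `n - 3` degrees of freedom.
#' @return An object of class `lmm_fit`: list with `intercept` and `slopes`
#'   (data frames of estimates, SEs, Wald CIs), `sigma2_site_hat`,
#'   `sigma2_resid_hat`, `theta_hat`, `singular`, `converged`.
#' @examples
#' d <- gen_dataset(scenario_config(120, 10), seed = 3)
#' fit_lmm(d)$slopes
#' @export
fit_lmm <- function(dataset, alpha = 0.05, singular_tol = 1e-4,
                    ci_method = c("z", "t")) {
  stopifnot(inherits(dataset, "sim_dataset"),
            is.numeric(alpha), alpha > 0, alpha < 1,
            is.numeric(singular_tol), singular_tol > 0)
  ci_method <- match.arg(ci_method)
  X <- cbind(`(Intercept)` = 1, x1 = dataset$x1, x2 = dataset$x2)
  check_full_rank(X)
  fit <- reml_profile_fit(dataset$y, X, dataset$group,
                          dataset$config$n_levels)
  ses <- sqrt(diag(fit$cov_beta))
  crit <- if (ci_method == "z") {
    stats::qnorm(1 - alpha / 2)
  } else {
    stats::qt(1 - alpha / 2, length(dataset$y) - 3L)
  }
  structure(
    list(intercept = fe_row("intercept", fit$beta[1L], ses[1L], crit),
         slopes = rbind(fe_row("beta1", fit$beta[2L], ses[2L], crit),
                        fe_row("beta2", fit$beta[3L], ses[3L], crit)),
         sigma2_site_hat = fit$sigma2_site,
         sigma2_resid_hat = fit$sigma2_resid,
         theta_hat = fit$theta,
         singular = fit$theta < singular_tol,
         converged = fit$converged,
         alpha = alpha, singular_tol = singular_tol, ci_method = ci_method),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (profiled REML)\n")
  print(rbind(x$intercept, x$slopes), row.names = FALSE)
  cat(sprintf("  sigma2_site = %.4f, sigma2_resid = %.4f, theta = %.4f%s\n",
              x$sigma2_site_hat, x$sigma2_resid_hat, x$theta_hat,
              if (x$singular) " (singular)" else ""))
  invisible(x)
}

#' @export
print.lm_fit <- function(x, ...) {
  cat("Dummy-coded linear model (OLS)\n")
  print(x$slopes, row.names = FALSE)
  cat(sprintf("  sigma2_resid = %.4f on %d df\n",
              x$sigma2_resid_hat, x$df_resid))
  invisible(x)
}

#' Slope estimates in the infinite-random-variance limit
#'
#' As the random-intercept variance grows without bound, the GLS slope
#' estimator of the mixed model converges to the fixed-effects (dummy-coded
#' LM) estimator: partial pooling interpolates between full pooling
#' (`theta = 0`) and no pooling (`theta = Inf`). The limit is computed by
#' the within-group centered regression (equivalently, by the
#' Frisch-Waugh-Lovell projection that sweeps out the group means).
#'
#' @param dataset A `sim_dataset`.
#' @return Named numeric vector `c(beta1, beta2)`.
#' @export
slopes_at_infinite_variance <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  g <- dataset$group
  center <- function(v) v - stats::ave(v, g)
  Xc <- cbind(center(dataset$x1), center(dataset$x2))
  yc <- center(dataset$y)
  beta <- solve(crossprod(Xc), crossprod(Xc, yc))
  c(beta1 = beta[1L], beta2 = beta[2L])
}
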