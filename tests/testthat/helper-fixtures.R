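# Shared fixtures for the test suite. The reduced-replication study grid is
# expensive, so it is computed once per test run and cached in an
# environment local to the suite.

.fixture_cache <- new.env(parent = emptyenv())

# Full 3x3 study grid at 2,000 replicates per cell (the desk-scale
# replication used throughout the suite; the study's canonical run is
# 10,000 per cell).
study_grid <- function() {
  if (is.null(.fixture_cache$grid)) {
    plan <- experiment_plan(n_reps = 2000L, seed = 20260923L)
    .fixture_cache$grid <- run_experiment(plan)
  }
  .fixture_cache$grid
}

# A handful of seeded datasets spanning the grid corners, for oracle checks.
oracle_datasets <- function() {
  if (is.null(.fixture_cache$oracle)) {
    specs <- expand.grid(seed = c(101L, 202L, 303L, 404L),
                         cell = 1:3)
    cells <- list(c(30L, 3L), c(60L, 5L), c(120L, 10L))
    .fixture_cache$oracle <- lapply(seq_len(nrow(specs)), function(i) {
      cfg <- cells[[specs$cell[i]]]
      gen_dataset(scenario_config(cfg[1L], cfg[2L]), seed = specs$seed[i])
    })
  }
  .fixture_cache$oracle
}

# Build a sim_dataset by hand (bypassing the generator) for degenerate or
# adversarial inputs.
manual_dataset <- function(y, x1, x2, group, config) {
  structure(
    list(y = y, x1 = x1, x2 = x2, group = as.integer(group),
         true_site_effects = rep(0, config$n_levels), config = config),
    class = "sim_dataset"
  )
}

# Dense brute-force REML criterion: explicit V, determinants and inverses.
# Deliberately the naive O(n^3) formulation, independent of the package's
# Woodbury/profile implementation.
dense_reml_criterion <- function(dataset, theta) {
  n <- dataset$config$n_obs
  J <- dataset$config$n_levels
  Z <- matrix(0, n, J)
  Z[cbind(seq_len(n), dataset$group)] <- 1
  X <- cbind(1, dataset$x1, dataset$x2)
  V <- diag(n) + theta^2 * Z %*% t(Z)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% dataset$y)
  r <- dataset$y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  as.numeric(determinant(V)$modulus) +
    as.numeric(determinant(A)$modulus) +
    (n - 3) * log(quad)
}
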