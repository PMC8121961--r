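# shared fixtures for the test suite; everything is built in code

toy_matrix <- function() {
  score_matrix(matrix(c(1, 2, 3,
                        4, 5, 6,
                        2, 4, 6,
                        1, 1, 1), nrow = 4, byrow = TRUE),
               person_ids = c("a", "b", "c", "d"),
               measure_names = c("x", "y", "z"))
}

write_toy_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# multivariate normal draws via Cholesky, for oracle covariance structures
rmvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  matrix(rnorm(n * p), n, p) %*% chol(Sigma)
}

# standardized matrix straight from a simulation config
sim_standardized <- function(...) standardize(simulate_scores(sim_config(...)))

# full-sample SLODR metrics for one simulated dataset
full_sample_metrics <- function(coupling, seed, n = 2000, p = 10) {
  z <- sim_standardized(n_persons = n, n_measures = p, coupling = coupling,
                        seed = seed)
  pr <- wim_wisd(z)
  sol <- fit_single_factor(z, seed = seed)
  f <- factor_scores(sol, z)
  lat <- predicted_and_residuals(sol, f, z)
  list(rho = spearman_rho(pr$wim, pr$wisd)$rho,
       g1 = skewness_test(lat$fscore)$g1,
       r = corr_latent_residvar(lat)$r,
       converged = sol$converged)
}
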