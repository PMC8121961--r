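test_that("just-identified triad matches the closed-form solution", {
  # p = 3: lambda_1 = sqrt(s12 s13 / s23) etc., chi2 = 0, df = 0
  set.seed(5)
  lam <- c(0.8, 0.6, 0.7)
  Sigma <- tcrossprod(lam) + diag(1 - lam^2)
  z <- standardize(score_matrix(rmvn(400, Sigma)))
  sol <- fit_single_factor(z)
  X <- scale(unclass(z), scale = FALSE)
  S <- crossprod(X) / nrow(X)
  oracle <- c(sqrt(S[1, 2] * S[1, 3] / S[2, 3]),
              sqrt(S[1, 2] * S[2, 3] / S[1, 3]),
              sqrt(S[1, 3] * S[2, 3] / S[1, 2]))
  expect_true(sol$converged)
  expect_equal(unname(sol$loadings), oracle, tolerance = 1e-6)
  expect_lt(sol$chi2, 1e-6)
  expect_equal(sol$df, 0)
  expect_equal(unname(sol$rmsea), 0)
})

test_that("loadings are recovered from model-generated data", {
  z <- sim_standardized(n_persons = 5000, n_measures = 10, seed = 31)
  sol <- fit_single_factor(z)
  expect_true(sol$converged)
  expect_true(all(abs(sol$loadings - 0.7) < 0.05))
  # standardized decomposition: lambda^2 + theta ~ diag(S)
  expect_true(all(abs(sol$loadings^2 + sol$theta - 1) < 0.05))
})

test_that("ML fit agrees with factanal as an independent cross-check", {
  z <- sim_standardized(n_persons = 3000, n_measures = 8, seed = 17)
  sol <- fit_single_factor(z)
  fa <- factanal(unclass(z), factors = 1, rotation = "none")
  lam_fa <- as.vector(fa$loadings)
  if (sum(lam_fa) < 0) lam_fa <- -lam_fa
  expect_true(sol$converged)
  expect_equal(unname(sol$loadings), lam_fa, tolerance = 0.01)
  expect_equal(unname(sol$theta), as.vector(fa$uniquenesses),
               tolerance = 0.02)
})

test_that("independent measures imply no common variance", {
  # with no common factor the ML solution is degenerate: it collapses onto
  # a single indicator (factanal does the same); the meaningful check is
  # that the implied shared variance between distinct measures stays tiny
  set.seed(9)
  X <- matrix(rnorm(5000 * 6), ncol = 6)
  sol <- fit_single_factor(standardize(score_matrix(X)))
  off <- sol$Sigma_hat[lower.tri(sol$Sigma_hat)]
  expect_lt(max(abs(off)), 0.05)
  fa <- factanal(X, factors = 1, rotation = "none")
  lam_fa <- as.vector(fa$loadings)
  if (sum(lam_fa) < 0) lam_fa <- -lam_fa
  expect_equal(unname(sol$loadings), lam_fa, tolerance = 0.05)
})

test_that("a Heywood case is reported, not hidden", {
  # triad with r12 = r13 = .7, r23 = .25 implies lambda_1^2 = 1.96 > 1
  Sigma <- matrix(c(1, .7, .7,
                    .7, 1, .25,
                    .7, .25, 1), 3, 3)
  set.seed(11)
  z <- standardize(score_matrix(rmvn(300, Sigma)))
  sol <- fit_single_factor(z)
  expect_true(sol$heywood)
  expect_false(sol$converged)
})

test_that("regression factor scores match the closed form", {
  # p = 2 is under-identified for fitting, so build the solution by hand
  # and check the score formula against an independent 2x2 inversion
  lam <- c(0.8, 0.6); theta <- c(0.36, 0.64)
  Sigma <- tcrossprod(lam) + diag(theta)
  sol <- structure(list(loadings = lam, theta = theta, Sigma_hat = Sigma,
                        converged = TRUE, p = 2L),
                   class = "factor_solution")
  x <- c(1, 1)
  det2 <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2] * Sigma[2, 1]
  Sinv <- matrix(c(Sigma[2, 2], -Sigma[1, 2],
                   -Sigma[2, 1], Sigma[1, 1]), 2, 2) / det2
  hand <- sum(lam * (Sinv %*% x))
  f <- factor_scores(sol, matrix(x, 1, 2))
  expect_equal(unname(f), hand, tolerance = 1e-12)
  expect_equal(unname(factor_scores(sol, matrix(0, 1, 2))), 0)  # linearity

  # and on a fitted model: recomputation via an explicit solve matches
  z <- sim_standardized(n_persons = 500, seed = 13)
  sol10 <- fit_single_factor(z)
  f10 <- factor_scores(sol10, z)
  f_ind <- as.vector(unclass(z) %*% (solve(sol10$Sigma_hat) %*%
                                       sol10$loadings))
  expect_equal(unname(f10), f_ind, tolerance = 1e-8)
})

test_that("factor scores track true ability on simulated data", {
  m <- simulate_scores(sim_config(n_persons = 2000, seed = 23))
  z <- standardize(m)
  sol <- fit_single_factor(z)
  f <- factor_scores(sol, z)
  expect_gt(cor(f, true_values(m)$ability), 0.9)
})

test_that("residual variances equal the mean squared prediction error", {
  lam <- c(0.8, 0.6); theta <- c(0.36, 0.64)
  sol <- structure(list(loadings = lam, theta = theta,
                        Sigma_hat = tcrossprod(lam) + diag(theta),
                        converged = TRUE, p = 2L),
                   class = "factor_solution")
  X <- matrix(c(1, 1,
                0.5, -0.2), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  f <- factor_scores(sol, X)
  lat <- predicted_and_residuals(sol, f, X)
  for (i in 1:2) {
    hand <- mean((X[i, ] - lam * f[i])^2)
    expect_equal(lat$resid_var[i], hand, tolerance = 1e-12)
  }
  expect_equal(lat$log_resid_var, log(lat$resid_var))

  # doubling residuals quadruples resid_var
  X2 <- t(lam %o% f[1] + 2 * (X[1, ] - lam * f[1]))
  lat2 <- predicted_and_residuals(sol, f[1], X2)
  expect_equal(lat2$resid_var, 4 * lat$resid_var[1], tolerance = 1e-12)

  # exact reproduction is floored, not -Inf
  X0 <- t(lam * 0.3)
  f0 <- 0.3
  lat0 <- predicted_and_residuals(sol, f0, X0)
  expect_equal(attr(lat0, "n_floored"), 1L)
  expect_true(is.finite(lat0$log_resid_var))
})

test_that("negating every column leaves the reported solution unchanged", {
  z <- sim_standardized(n_persons = 800, seed = 19)
  neg <- score_matrix(-unclass(z), standardized = TRUE)
  s1 <- fit_single_factor(z)
  s2 <- fit_single_factor(neg)
  expect_equal(s2$loadings, s1$loadings, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(s2$chi2, s1$chi2, tolerance = 1e-6)
  expect_equal(s2$cfi, s1$cfi, tolerance = 1e-8)
  f1 <- factor_scores(s1, z); f2 <- factor_scores(s2, neg)
  expect_equal(unname(f2), -unname(f1), tolerance = 1e-3)
  l1 <- predicted_and_residuals(s1, f1, z)
  l2 <- predicted_and_residuals(s2, f2, neg)
  expect_equal(l2$resid_var, l1$resid_var, tolerance = 1e-3)
})

test_that("fit indices follow their definitions at the boundary cases", {
  perfect <- fit_indices(0, 35, 500, 45, 1000)
  expect_equal(unname(perfect), c(1, 1, 0))
  nofit <- fit_indices(500, 45, 500, 45, 1000)
  expect_equal(unname(nofit["nfi"]), 0)
  ji <- fit_indices(0.5, 0, 300, 3, 100)
  expect_equal(unname(ji["rmsea"]), 0)
  expect_true(isTRUE(attr(ji, "just_identified")))
  # hand-computed middle case
  fi <- fit_indices(chi2 = 70, df = 35, baseline_chi2 = 700,
                    baseline_df = 45, n = 500)
  expect_equal(unname(fi["nfi"]), (700 - 70) / 700)
  expect_equal(unname(fi["cfi"]), 1 - 35 / 655)
  expect_equal(unname(fi["rmsea"]), sqrt(35 / (35 * 500)))
})

test_that("preconditions are enforced", {
  z <- sim_standardized(n_persons = 30, n_measures = 10, seed = 1)
  m_raw <- simulate_scores(sim_config(n_persons = 100, seed = 1))
  expect_error(fit_single_factor(m_raw), "standardized")
  expect_error(fit_single_factor(score_matrix(
    unclass(z)[1:12, ], standardized = TRUE)), "too small")
})
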