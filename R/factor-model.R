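# Single-factor covariance structure model, fitted by maximum likelihood.
#
# Model: Sigma(lambda, theta) = lambda lambda' + diag(theta), factor
# variance fixed at 1, so on standardized scores the loadings are directly
# standardized loadings. The ML discrepancy
#   F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p
# is minimized over (lambda, ln theta) by BFGS with analytic gradient;
# chi-square = n * F at the optimum (ML covariance S with denominator n).

theta_floor <- 1e-4

ml_discrepancy <- function(lambda, theta, S, logdetS) {
  Sigma <- tcrossprod(lambda) + diag(theta, length(lambda))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(F = Inf))
  logdet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  list(F = logdet + sum(Sinv * S) - logdetS - length(lambda),
       Sinv = Sinv)
}

# gradient of F wrt (lambda, u = ln theta): dF/dSigma = Sinv (Sigma - S) Sinv
ml_gradient <- function(lambda, theta, S, Sinv) {
  G <- Sinv - Sinv %*% S %*% Sinv        # Sinv (Sigma - S) Sinv
  c(2 * as.vector(G %*% lambda), diag(G) * theta)
}

#' Fit a single-latent-factor model by maximum likelihood
#'
#' Regresses all standardized scores on one latent factor: the implied
#' covariance is \eqn{\Sigma = \Lambda\Lambda' + diag(\theta)} with the
#' factor variance fixed at 1. The ML discrepancy is minimized by BFGS on
#' \eqn{(\Lambda, \ln\theta)} with analytic gradients, a principal-axis
#' start and `restarts` additional randomly perturbed starts (seeded, so
#' the fit is deterministic). The factor sign is fixed so that the loading
#' sum is positive ("higher latent score = better performance").
#'
#' A solution with any residual variance pinned at the lower bound
#' (a Heywood case) or a failed optimizer is reported with
#' `converged = FALSE` rather than hidden.
#'
#' @param m a standardized [score_matrix()] with `n >= p + 5` rows.
#' @param restarts number of random restarts after the principal-axis
#'   start (default 3).
#' @param seed seed for the restart perturbations.
#' @param tol convergence tolerance on the discrepancy.
#' @return an object of class `factor_solution`: list with `loadings`,
#'   `theta`, `Sigma_hat`, `converged`, `heywood`, `discrepancy`, `chi2`,
#'   `df`, `baseline_chi2`, `baseline_df`, `nfi`, `cfi`, `rmsea`, `n`, `p`.
#' @export
fit_single_factor <- function(m, restarts = 3, seed = 1L, tol = 1e-8) {
  if (!is_standardized(m))
    stop("fit_single_factor requires standardized scores; run standardize()")
  X <- unclass(m)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 5)
    stop("n = ", n, " too small for p = ", p, " measures (need n >= p + 5)")
  Xc <- scale(X, scale = FALSE)
  S <- crossprod(Xc) / n                 # ML covariance
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) stop("singular sample covariance; cannot fit")
  logdetS <- 2 * sum(log(diag(ch)))

  fn <- function(par) {
    ml_discrepancy(par[1:p], exp(par[-(1:p)]), S, logdetS)$F
  }
  gr <- function(par) {
    lambda <- par[1:p]; theta <- exp(par[-(1:p)])
    d <- ml_discrepancy(lambda, theta, S, logdetS)
    if (!is.finite(d$F)) return(rep(0, 2 * p))
    ml_gradient(lambda, theta, S, d$Sinv)
  }

  # principal-axis start: first eigenvector scaled to explain its eigenvalue
  ev <- eigen(S, symmetric = TRUE)
  l0 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0.1))
  if (sum(l0) < 0) l0 <- -l0
  th0 <- pmax(diag(S) - l0^2, 0.05)
  starts <- list(c(l0, log(th0)))
  with_seed(seed, {
    for (r in seq_len(restarts))
      starts[[r + 1]] <- c(l0 * stats::runif(p, 0.5, 1.5),
                           log(th0 * stats::runif(p, 0.5, 1.5)))
  })

  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = tol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimizer failed on every start")

  lambda <- best$par[1:p]
  if (sum(lambda) < 0) lambda <- -lambda   # sign convention
  theta <- pmax(exp(best$par[-(1:p)]), theta_floor)
  heywood <- any(theta <= theta_floor * (1 + 1e-6))
  converged <- (best$convergence == 0) && !heywood
  Sigma_hat <- tcrossprod(lambda) + diag(theta, p)
  names(lambda) <- names(theta) <- colnames(X)

  Fm <- best$value
  df <- p * (p + 1) / 2 - 2 * p
  chi2 <- n * Fm
  # independence baseline: Sigma_b = diag(S)
  Fb <- sum(log(diag(S))) - logdetS
  baseline_chi2 <- n * Fb
  baseline_df <- p * (p - 1) / 2
  fi <- fit_indices(chi2, df, baseline_chi2, baseline_df, n)

  structure(list(loadings = lambda, theta = theta, Sigma_hat = Sigma_hat,
                 converged = converged, heywood = heywood,
                 discrepancy = Fm, chi2 = chi2, df = df,
                 baseline_chi2 = baseline_chi2, baseline_df = baseline_df,
                 nfi = fi["nfi"], cfi = fi["cfi"], rmsea = fi["rmsea"],
                 n = n, p = p),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf(
    "single-factor solution: p = %d, n = %d, %s\n", x$p, x$n,
    if (x$converged) "converged" else
      if (x$heywood) "NOT converged (Heywood case)" else "NOT converged"))
  cat(sprintf("  mean loading %.3f  chi2(%d) = %.1f  NFI %.3f  CFI %.3f  RMSEA %.3f\n",
              mean(x$loadings), x$df, x$chi2, x$nfi, x$cfi, x$rmsea))
  invisible(x)
}

#' Incremental and absolute fit indices
#'
#' NFI, CFI and RMSEA from model and independence-baseline chi-squares.
#' A just-identified model (df = 0) reports RMSEA 0 with attribute
#' `just_identified`.
#'
#' @param chi2,df model chi-square and degrees of freedom.
#' @param baseline_chi2,baseline_df independence-model chi-square and df.
#' @param n sample size.
#' @return named numeric vector `c(nfi, cfi, rmsea)`.
#' @export
fit_indices <- function(chi2, df, baseline_chi2, baseline_df, n) {
  nfi <- (baseline_chi2 - chi2) / baseline_chi2
  num <- max(chi2 - df, 0)
  den <- max(baseline_chi2 - baseline_df, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  if (df == 0) {
    out <- c(nfi = nfi, cfi = cfi, rmsea = 0)
    attr(out, "just_identified") <- TRUE
    return(out)
  }
  c(nfi = nfi, cfi = cfi, rmsea = sqrt(max(chi2 - df, 0) / (df * n)))
}

#' Estimate latent ability scores (regression method)
#'
#' Regression-method factor scores \eqn{\hat f_i = \Lambda' \hat\Sigma^{-1}
#' x_i} using the model-implied covariance — the default estimator for
#' continuous indicators in standard SEM software.
#'
#' @param sol a converged [fit_single_factor()] solution.
#' @param m the standardized [score_matrix()] the model was fitted to (or
#'   any matrix with the same columns).
#' @return named numeric vector of factor scores, one per person.
#' @export
factor_scores <- function(sol, m) {
  stopifnot(inherits(sol, "factor_solution"))
  X <- unclass(m)
  w <- solve(sol$Sigma_hat, sol$loadings)
  f <- as.vector(X %*% w)
  names(f) <- rownames(X)
  f
}

#' Predicted scores and within-individual residual variance
#'
#' Predicted manifest values \eqn{\hat x_{ij} = \lambda_j \hat f_i}; each
#' person's residual variance is the mean squared difference between their
#' observed and predicted scores across the p measures, and its natural log
#' is the quantity correlated with ability downstream. Zero residual
#' variances are floored at a machine-safe epsilon so the log stays finite;
#' floor events are counted in attribute `n_floored`.
#'
#' @param sol a [fit_single_factor()] solution.
#' @param fscores factor scores from [factor_scores()].
#' @param m the matching standardized [score_matrix()].
#' @param eps floor for the residual variance (default 1e-12).
#' @return data frame `person_id`, `fscore`, `resid_var`, `log_resid_var`.
#' @export
predicted_and_residuals <- function(sol, fscores, m, eps = 1e-12) {
  X <- unclass(m)
  pred <- tcrossprod(fscores, sol$loadings)
  rv <- rowMeans((X - pred)^2)
  floored <- rv < eps
  rv[floored] <- eps
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  out <- data.frame(person_id = ids, fscore = as.vector(fscores),
                    resid_var = rv, log_resid_var = log(rv),
                    stringsAsFactors = FALSE)
  attr(out, "n_floored") <- sum(floored)
  out
}
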