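# The two testable criteria of Spearman's law of diminishing returns
# (SLODR): (1) negatively skewed latent ability, (2) a positive correlation
# between latent ability and within-individual residual variance.

#' Moment skewness with the D'Agostino z-test
#'
#' Sample skewness \eqn{g_1 = m_3 / m_2^{3/2}} and its two-sided
#' significance by D'Agostino's normalizing transformation of the skewness
#' statistic, valid for n >= 8.
#'
#' @param values numeric vector, n >= 8, non-constant.
#' @return list with `g1`, `z`, `p`.
#' @export
skewness_test <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 8) stop("skewness test requires n >= 8")
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) stop("constant input: skewness undefined")
  g1 <- mean(x^3) / m2^1.5
  # D'Agostino (1970) transformation
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z <- delta * asinh(Y / alpha)
  list(g1 = g1, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Correlation between latent ability and log residual variance
#'
#' Pearson correlation (default) between estimated factor scores and the
#' log of within-individual residual variance, with the t-approximation
#' p-value on n - 2 df. A Spearman variant is available; under ranks the
#' log transform is immaterial.
#'
#' @param latents data frame from [predicted_and_residuals()] (columns
#'   `fscore` and `log_resid_var`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r` and `p`.
#' @export
corr_latent_residvar <- function(latents, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  f <- latents$fscore; lrv <- latents$log_resid_var
  n <- length(f)
  if (n < 4) stop("need at least 4 persons")
  if (method == "spearman") return(spearman_rho(f, lrv))
  if (stats::sd(f) == 0 || stats::sd(lrv) == 0)
    stop("zero variance in factor scores or residual variances")
  r <- stats::cor(f, lrv)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

#' Evaluate the SLODR criteria for one cell
#'
#' Combines the per-cell quantities into one record and sets the criterion
#' flags: significant negative latent skewness, significant positive
#' latent-residual-variance correlation, and their conjunction. No
#' multiplicity correction is applied.
#'
#' @param cell a cell from [slice_cells()] (identity and WIM-WISD
#'   correlation).
#' @param latents data frame from [predicted_and_residuals()] for the
#'   cell's members.
#' @param alpha significance level for both criteria (default 0.05).
#' @param corr_method correlation type passed to [corr_latent_residvar()].
#' @return one-row data frame with class `slodr_cell_result`: the cell
#'   identity, `skew_g1`, `skew_z`, `skew_p`, `r_latent_logrv`, `r_p`,
#'   `criterion_skew`, `criterion_corr`, `slodr_both`, `converged`.
#' @export
evaluate_cell <- function(cell, latents, alpha = 0.05,
                          corr_method = "pearson") {
  sk <- skewness_test(latents$fscore)
  cr <- corr_latent_residvar(latents, method = corr_method)
  criterion_skew <- isTRUE(sk$g1 < 0 && sk$p <= alpha)
  criterion_corr <- isTRUE(cr$r > 0 && cr$p <= alpha)
  data.frame(direction = cell$direction, k = cell$k,
             slice_index = cell$slice_index, n = cell$n,
             rho_wim_wisd = cell$rho_wim_wisd, rho_p = cell$rho_p,
             skew_g1 = sk$g1, skew_z = sk$z, skew_p = sk$p,
             r_latent_logrv = cr$r, r_p = cr$p,
             criterion_skew = criterion_skew,
             criterion_corr = criterion_corr,
             slodr_both = criterion_skew && criterion_corr,
             converged = TRUE, status = "converged",
             stringsAsFactors = FALSE)
}

#' Size-weighted probability of meeting both SLODR criteria
#'
#' \eqn{\sum_c n_c I(both_c) / \sum_c n_c} over converged cells. Skipped
#' or non-converged cells are excluded from numerator and denominator by
#' default; `count_failures = TRUE` keeps them in the denominator instead.
#'
#' @param results data frame of cell records from [evaluate_cell()] /
#'   [run_sweep()].
#' @param count_failures include non-converged cells in the denominator.
#' @return the weighted probability in `[0, 1]`.
#' @export
weighted_probability <- function(results, count_failures = FALSE) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  conv <- results$converged %in% TRUE
  if (!count_failures) results <- results[conv, , drop = FALSE]
  if (nrow(results) == 0) stop("no converged cells")
  both <- results$slodr_both %in% TRUE
  sum(results$n * both) / sum(results$n)
}
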