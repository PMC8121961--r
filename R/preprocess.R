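#' Reverse the orientation of selected measures
#'
#' Negates the named columns so that higher uniformly means better —
#' the standard treatment of response times before any latent-ability
#' analysis. Applying it twice restores the original matrix.
#'
#' @param m a [score_matrix()].
#' @param columns character vector of column names to negate.
#' @return the matrix with the listed columns negated.
#' @export
reverse_scores <- function(m, columns) {
  bad <- setdiff(columns, colnames(m))
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "))
  m[, columns] <- -m[, columns, drop = FALSE]
  restamp(m, m, standardized = FALSE)
}

#' Convert running times to speeds
#'
#' Replaces each listed column of times (seconds) by distance/time (m/s),
#' as done for decathlon track events so that higher values mean better
#' performance in every event.
#'
#' @param m a [score_matrix()].
#' @param distances named numeric vector mapping column name to distance in
#'   meters, e.g. `c(r100 = 100, r1500 = 1500)`.
#' @return the matrix with the listed columns converted to speeds.
#' @export
times_to_speed <- function(m, distances) {
  cols <- names(distances)
  bad <- setdiff(cols, colnames(m))
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "))
  for (cl in cols) {
    t <- m[, cl]
    nonpos <- which(!is.na(t) & t <= 0)
    if (length(nonpos))
      stop("non-positive time in column '", cl, "', row ",
           rownames(m)[nonpos[1]])
    m[, cl] <- distances[[cl]] / t
  }
  restamp(m, m, standardized = FALSE)
}

#' Delete extreme scores by percentile
#'
#' Marks as missing all values below the low or above the high percentile
#' of the pooled distribution of the trimmed columns (the outlier rule
#' applied to response latencies, where single extreme trials would
#' otherwise dominate). Percentiles use the linear-interpolation rule
#' (R's default quantile type 7). A per-column mode is available for data
#' whose columns live on different scales.
#'
#' @param m a [score_matrix()].
#' @param low_pct,high_pct percentiles in (0,100), low < high; defaults 1
#'   and 99.
#' @param columns which columns to trim (default: all).
#' @param per_column trim each column against its own percentiles instead
#'   of the pooled distribution.
#' @return the matrix with extreme cells set to `NA`; the number of deleted
#'   cells is attached as attribute `n_trimmed`.
#' @export
percentile_trim <- function(m, low_pct = 1, high_pct = 99,
                            columns = colnames(m), per_column = FALSE) {
  stopifnot(low_pct > 0, high_pct < 100, low_pct < high_pct)
  bad <- setdiff(columns, colnames(m))
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "))
  probs <- c(low_pct, high_pct) / 100
  n_trimmed <- 0L
  if (per_column) {
    for (cl in columns) {
      v <- m[, cl]
      q <- stats::quantile(v, probs, na.rm = TRUE, names = FALSE)
      if (q[1] == q[2]) { warning("degenerate percentiles in '", cl,
                                  "'; column left untouched"); next }
      kill <- !is.na(v) & (v < q[1] | v > q[2])
      n_trimmed <- n_trimmed + sum(kill)
      m[kill, cl] <- NA_real_
    }
  } else {
    pool <- as.vector(m[, columns, drop = FALSE])
    q <- stats::quantile(pool, probs, na.rm = TRUE, names = FALSE)
    if (q[1] == q[2]) {
      warning("degenerate percentiles (all trimmed values equal); no-op")
    } else {
      sub <- m[, columns, drop = FALSE]
      kill <- !is.na(sub) & (sub < q[1] | sub > q[2])
      n_trimmed <- sum(kill)
      sub[kill] <- NA_real_
      m[, columns] <- sub
    }
  }
  out <- restamp(m, m, standardized = FALSE)
  attr(out, "n_trimmed") <- n_trimmed
  out
}

#' Keep only persons with complete data
#'
#' Removes every row containing a missing value, the complete-case rule
#' used before standardization and factor fitting.
#'
#' @param m a [score_matrix()].
#' @return the complete rows; the number of removed rows is attached as
#'   attribute `n_removed`. Errors if nothing remains.
#' @export
complete_cases <- function(m) {
  keep <- stats::complete.cases(unclass(m))
  if (!any(keep)) stop("no complete cases remain")
  out <- restamp(m[keep, , drop = FALSE], m)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Standardize each measure to z-scores
#'
#' Centers and scales each column to mean 0 and sample SD 1 (denominator
#' n - 1), the common metric required before fitting the single-factor
#' model. Idempotent; errors on constant columns.
#'
#' @param m a complete [score_matrix()].
#' @return the standardized matrix with its `standardized` flag set.
#' @export
standardize <- function(m) {
  if (anyNA(m)) stop("standardize requires a complete matrix; run complete_cases() first")
  sds <- apply(m, 2, stats::sd)
  zero <- colnames(m)[sds == 0 | !is.finite(sds)]
  if (length(zero))
    stop("zero-variance column(s): ", paste(zero, collapse = ", "))
  z <- scale(unclass(m))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  restamp(z, m, standardized = TRUE)
}

#' Within-individual mean and standard deviation
#'
#' For each person, the mean (WIM) and sample standard deviation (WISD,
#' denominator p - 1) of their p scores. On standardized scores these are
#' the per-person location and spread whose correlation the slicing
#' machinery manipulates.
#'
#' @param m a complete [score_matrix()] (standardized for the main
#'   analysis, though the computation itself does not require it).
#' @return data frame with columns `person_id`, `wim`, `wisd`.
#' @export
wim_wisd <- function(m) {
  if (anyNA(m)) stop("wim_wisd requires a complete matrix")
  v <- unclass(m)
  data.frame(person_id = rownames(v),
             wim = rowMeans(v),
             wisd = apply(v, 1, stats::sd),
             stringsAsFactors = FALSE)
}
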