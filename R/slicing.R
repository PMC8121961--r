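#' Spearman correlation with t-approximation p-value
#'
#' Rank correlation using mid-ranks for ties, with the p-value from the
#' t approximation on n - 2 degrees of freedom. Used for the per-cell
#' WIM-WISD correlation, where tied values are common and the exact
#' permutation null is unnecessary.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return list with elements `rho` and `p`. `rho` is `NA` (with `p` `NA`)
#'   when either variable is constant in rank.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 observations for a rank correlation")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

slice_directions <- c("antidiagonal", "diagonal", "horizontal")

# Slicing score: the coordinate along which the stripes are stacked.
# Conditioning on a narrow band of the score leaves the within-stripe
# variation perpendicular to it, so banding on zWIM - zWISD (stripes
# stacked along the antidiagonal of the WIM-WISD plane) leaves positive
# WIM-WISD covariation, banding on zWIM + zWISD (main diagonal) leaves
# negative covariation, and banding on zWISD alone leaves essentially none.
slicing_score <- function(wim, wisd, direction, zscore = TRUE) {
  if (zscore) {
    wim <- as.vector(scale(wim)); wisd <- as.vector(scale(wisd))
  }
  switch(direction,
         antidiagonal = wim - wisd,
         diagonal     = wim + wisd,
         horizontal   = wisd,
         stop("unknown direction: ", direction))
}

#' Slice a sample into stripes of the WIM-WISD plane
#'
#' Strategic slicing: persons are ordered by a slicing score and cut into k
#' contiguous, approximately equally sized groups. Stripes stacked along the
#' antidiagonal of the (WIM, WISD) plane (score zWIM - zWISD) induce
#' positive within-stripe WIM-WISD correlations, stripes stacked along the
#' main diagonal (zWIM + zWISD) negative ones, and horizontal stripes
#' (zWISD) correlations near zero — the experimental manipulation at the
#' heart of the method. The sign pattern follows from the band geometry:
#' within a stripe the remaining covariation runs perpendicular to the
#' slicing score.
#'
#' WIM and WISD are z-scored across the sample before forming the score, so
#' both axes contribute on a common scale; set `zscore = FALSE` for
#' raw-scale slicing. Group sizes differ by at most one, with the remainder
#' going to the lowest-score groups; ties are broken by input order, so the
#' partition is deterministic given the row order. `k = 1` returns the full
#' sample whatever the direction.
#'
#' @param profiles data frame from [wim_wisd()].
#' @param direction one of `"antidiagonal"`, `"diagonal"`, `"horizontal"`.
#' @param k number of slices, `1 <= k <= nrow(profiles)`.
#' @param zscore z-score WIM and WISD before slicing (default TRUE).
#' @return list of cells; each cell is a list with `direction`, `k`,
#'   `slice_index`, `person_ids`, `n`, `rho_wim_wisd`, `rho_p` (the
#'   within-cell Spearman WIM-WISD correlation, `NA` when n < 4 or ranks
#'   are constant).
#' @export
slice_cells <- function(profiles, direction = slice_directions, k,
                        zscore = TRUE) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(profiles),
            all(c("person_id", "wim", "wisd") %in% names(profiles)))
  n <- nrow(profiles)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds sample size n = ", n)
  s <- slicing_score(profiles$wim, profiles$wisd, direction, zscore)
  if (k > 1 && length(unique(s)) < 2)
    stop("fewer than 2 distinct slicing scores; cannot slice")
  ord <- order(s)                        # radix sort: stable in input order
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    idx <- sort(ord[starts[i]:stops[i]])   # members kept in input order
    rs <- if (length(idx) >= 4)
      spearman_rho(profiles$wim[idx], profiles$wisd[idx])
    else list(rho = NA_real_, p = NA_real_)
    list(direction = direction, k = as.integer(k),
         slice_index = i, person_ids = profiles$person_id[idx],
         n = length(idx), rho_wim_wisd = rs$rho, rho_p = rs$p)
  })
}

#' Enumerate all cells of a slicing sweep
#'
#' For each direction and each k from 1 to `k_max` there are k cells, so a
#' full sweep holds `|directions| * k_max * (k_max + 1) / 2` cells. The
#' paper-style sweep over four datasets with k_max 7, 20, 15 and 30 along
#' three directions yields 2469 cells in total.
#'
#' @param k_max largest number of slices.
#' @param directions slicing directions to include.
#' @return data frame with one row per cell: `direction`, `k`,
#'   `slice_index`.
#' @export
enumerate_sweep <- function(k_max, directions = slice_directions) {
  stopifnot(k_max >= 1)
  directions <- match.arg(directions, slice_directions, several.ok = TRUE)
  ks <- rep(seq_len(k_max), seq_len(k_max))
  idx <- unlist(lapply(seq_len(k_max), seq_len))
  out <- expand.grid(cell = seq_along(ks), direction = directions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(direction = out$direction,
             k = ks[out$cell], slice_index = idx[out$cell],
             stringsAsFactors = FALSE)
}
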