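#' Standard decathlon track distances
#'
#' Distances in meters for the four running events, used to convert times
#' (seconds) to speeds (m/s) so that higher uniformly means better across
#' all ten events. Names follow the column naming of the openly available
#' Olympic decathlon results table; rename or remap as needed with the
#' `distances` argument of [analyze_decathlon()].
#' @export
decathlon_run_distances <- c(r100 = 100, r400 = 400, r110h = 110,
                             r1500 = 1500)

#' Full SLODR slicing analysis of a decathlon results table
#'
#' Convenience wrapper reproducing the decathlon arm of the analysis:
#' read the event results (one row per athlete-games, ten numeric event
#' columns), convert running times to speeds, keep complete cases,
#' standardize, and run the full slicing sweep with `k_max = 15` over all
#' three directions.
#'
#' The Olympic decathlon table itself is third-party research data and is
#' not bundled; download it from the public repository accompanying the
#' original analysis and pass its path here.
#'
#' @param path CSV of decathlon results.
#' @param id_column identifier column name.
#' @param distances named vector mapping running-event columns to meters
#'   (default [decathlon_run_distances]).
#' @param k_max sweep extent (default 15).
#' @param ... further arguments to [run_config()].
#' @return list with `summary` (the [run_sweep()] result), `profiles`
#'   (WIM/WISD per athlete), `spearman_wim_wisd` (full-sample rho and p),
#'   `mean_correlation` (mean off-diagonal inter-event correlation), and
#'   `solution` (the full-sample factor fit).
#' @export
analyze_decathlon <- function(path, id_column = "person_id",
                              distances = decathlon_run_distances,
                              k_max = 15, ...) {
  m <- read_scores(path, id_column = id_column)
  missing_cols <- setdiff(names(distances), colnames(m))
  if (length(missing_cols))
    stop("running-event column(s) not found: ",
         paste(missing_cols, collapse = ", "),
         "; available: ", paste(colnames(m), collapse = ", "),
         ". Remap with the `distances` argument.")
  m <- times_to_speed(m, distances)
  m <- complete_cases(m)
  z <- standardize(m)
  profiles <- wim_wisd(z)
  rs <- spearman_rho(profiles$wim, profiles$wisd)
  R <- stats::cor(unclass(z))
  mean_cor <- mean(R[lower.tri(R)])
  sol <- fit_single_factor(z)
  summary <- run_sweep(run_config(z, k_max = k_max, ...))
  list(summary = summary, profiles = profiles,
       spearman_wim_wisd = rs, mean_correlation = mean_cor,
       solution = sol)
}
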