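#' Configuration for the synthetic score generator
#'
#' Describes a population with a single common ability factor and a
#' per-person noise scale that may be coupled to ability, so that the
#' correlation between within-individual mean (WIM) and within-individual
#' spread (WISD) can be dialled to either sign. Optional monotone skewing,
#' hard floor/ceiling censoring, and a positively skewed person-level
#' disturbance emulate the score distortions real performance data show.
#'
#' The generative model is
#' \deqn{a_i \sim N(0,1), \qquad \sigma_i = \sigma_0 e^{c a_i},}
#' \deqn{x_{ij} = \lambda_j a_i + \sigma_i \epsilon_{ij}, \quad
#'       \epsilon_{ij} \sim N(0,1),}
#' optionally followed by a disturbance \eqn{x_{ij} - d_i b_{ij}} with
#' \eqn{d_i \sim Exp(rate)}, \eqn{b_{ij} \sim U(0,1)}; a skewing transform
#' \eqn{y = (e^{\beta x} - 1)/\beta} (identity at \eqn{\beta = 0}); and
#' censoring of y at its empirical low/high quantiles.
#'
#' Defaults (n = 2000 persons, p = 10 measures, loadings 0.7, baseline noise
#' SD 0.714, no coupling/skew/censoring/disturbance) give unit-variance
#' columns with a common factor explaining about half of each measure's
#' variance — a neutral, moderately g-saturated battery.
#'
#' @param n_persons number of persons (rows).
#' @param n_measures number of measures (columns), at least 3.
#' @param loadings common-factor loading per measure; a scalar is recycled.
#' @param noise_scale baseline within-person noise SD \eqn{\sigma_0 > 0}.
#' @param coupling real c: log-linear dependence of a person's noise SD on
#'   ability. c < 0 gives a negative WIM-WISD correlation (the
#'   intelligence/RT/decathlon pattern), c > 0 a positive one (income).
#' @param skew_beta real \eqn{\beta} for the monotone skewing transform;
#'   negative values compress the upper tail (negative score skewness), 0 is
#'   the identity.
#' @param censor_quantiles optional `c(low, high)` in `[0,1]`: scores are
#'   clamped at those empirical quantiles per column (hard floor/ceiling).
#' @param disturbance_rate optional rate of an exponential person-level
#'   disturbance severity; larger severities pull a minority of persons well
#'   below their true level, skewing scores negatively.
#' @param seed integer seed for the generator's dedicated RNG stream.
#' @return an object of class `sim_config`.
#' @seealso [simulate_scores()], [true_values()]
#' @export
sim_config <- function(n_persons = 2000, n_measures = 10, loadings = 0.7,
                       noise_scale = 0.714, coupling = 0, skew_beta = 0,
                       censor_quantiles = NULL, disturbance_rate = NULL,
                       seed = 1L) {
  stopifnot(n_persons >= 1, n_measures >= 3, noise_scale > 0,
            is.numeric(coupling), length(coupling) == 1,
            is.numeric(skew_beta), length(skew_beta) == 1)
  if (length(loadings) == 1L) loadings <- rep(loadings, n_measures)
  if (length(loadings) != n_measures)
    stop("loadings must have length 1 or n_measures (", n_measures, ")")
  if (!is.null(censor_quantiles)) {
    cq <- censor_quantiles
    if (length(cq) != 2 || cq[1] < 0 || cq[2] > 1 || cq[1] >= cq[2])
      stop("censor_quantiles must be c(low, high) with 0 <= low < high <= 1")
  }
  if (!is.null(disturbance_rate) && disturbance_rate <= 0)
    stop("disturbance_rate must be positive")
  structure(list(n_persons = as.integer(n_persons),
                 n_measures = as.integer(n_measures),
                 loadings = as.numeric(loadings),
                 noise_scale = noise_scale, coupling = coupling,
                 skew_beta = skew_beta,
                 censor_quantiles = censor_quantiles,
                 disturbance_rate = disturbance_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# run expr with a private RNG stream, restoring global .Random.seed after
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic score matrix
#'
#' Draws scores from the model described in [sim_config()]. The true ability
#' and per-person noise SD used are attached so that parameter-recovery
#' checks can compare estimates against ground truth; retrieve them with
#' [true_values()]. Identical configurations (including the seed) give
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @return a [score_matrix()] with a `truth` attribute (data frame of
#'   `person_id`, `ability`, `noise_sd`).
#' @export
simulate_scores <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_persons; p <- config$n_measures
  with_seed(config$seed, {
    a <- stats::rnorm(n)
    sigma <- config$noise_scale * exp(config$coupling * a)
    eps <- matrix(stats::rnorm(n * p), n, p)
    x <- tcrossprod(a, config$loadings) + sigma * eps
    if (!is.null(config$disturbance_rate)) {
      d <- stats::rexp(n, rate = config$disturbance_rate)
      b <- matrix(stats::runif(n * p), n, p)
      x <- x - d * b
    }
    beta <- config$skew_beta
    if (beta != 0) x <- expm1(beta * x) / beta
    if (!any(is.finite(range(x))) || anyNA(x) || any(!is.finite(x)))
      stop("non-finite scores generated; skew_beta = ", beta,
           " overflows for this configuration")
    if (!is.null(config$censor_quantiles)) {
      lo <- apply(x, 2, stats::quantile, probs = config$censor_quantiles[1])
      hi <- apply(x, 2, stats::quantile, probs = config$censor_quantiles[2])
      x <- pmin(pmax(x, rep(lo, each = n)), rep(hi, each = n))
    }
    ids <- sprintf("p%05d", seq_len(n))
    m <- score_matrix(x, person_ids = ids)
    attr(m, "truth") <- data.frame(person_id = ids, ability = a,
                                   noise_sd = sigma,
                                   stringsAsFactors = FALSE)
    m
  })
}

#' Ground truth behind a simulated score matrix
#'
#' Returns the ability vector \eqn{a_i} and noise-SD vector \eqn{\sigma_i}
#' actually used by [simulate_scores()]. Accepts either the simulated
#' matrix (truth travels with it) or the `sim_config` itself, in which case
#' the deterministic generator is re-run.
#'
#' @param x a simulated `score_matrix` or a `sim_config`.
#' @return data frame with columns `person_id`, `ability`, `noise_sd`.
#' @export
true_values <- function(x) {
  if (inherits(x, "sim_config")) x <- simulate_scores(x)
  tr <- attr(x, "truth")
  if (is.null(tr))
    stop("no ground truth attached; was this matrix simulated?")
  tr
}
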