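#' Scenario parameters for the screening simulation
#'
#' Bundles everything that defines one simulated scenario: the population
#' size, the disease-progression base `dp`, the coefficient of variation of
#' the mean annual risk across years (`cvmr`), the common pairwise
#' correlation `r` between an individual's annual risks, the target detection
#' rate, and replication/seeding settings.
#'
#' The standard deviation of the mean annual risk implied by `cvmr` is
#' `sdmr = cvmr * mean_5y_risk / n_intervals`; e.g. `cvmr = 0.5` with a 10%
#' five-year risk over five intervals corresponds to `sdmr = 0.01`.
#'
#' @param n_patients Number of simulated patients (default 5000).
#' @param dp Progression base in (0, 1]: the probability that a disease
#'   occurrence is still fully curable after a delay of one year. Smaller
#'   values mean faster progression (0.6 slow, 0.3 intermediate, 0.1 fast).
#' @param cvmr Coefficient of variation of the five population mean annual
#'   risks, `>= 0`.
#' @param r Equicorrelation in `[0, 1)` between an individual's annual risks.
#' @param tdr_target Target detection rate in (0, 1): the fraction of the
#'   curable detections achievable under full screening that a schedule must
#'   reach.
#' @param mean_5y_risk Population mean cumulative risk over all intervals
#'   (default 0.10).
#' @param n_intervals Number of annual intervals / possible exam times
#'   (default 5).
#' @param reps Number of Monte-Carlo repetitions per scenario (default 100).
#' @param seed Integer root seed; all randomness in a scenario run is derived
#'   from it through named substreams.
#' @param sigma_scale Scale of the individual per-year risk spread. The
#'   per-year standard deviation is `sigma_scale / abs(log10(m_i))` where
#'   `m_i` is that year's population mean risk, so spread grows (sub-linearly)
#'   with the mean. Default 0.01.
#' @param redraw_trajectory If `TRUE` (default) a fresh mean-risk trajectory
#'   is drawn for every repetition; if `FALSE` one trajectory is fixed per
#'   scenario.
#' @param ra_mode How random-allocation draws are counted: with a duplicate
#'   slot consuming a draw (`"with_replacement"`, default) or drawing over
#'   remaining slots only (`"without_replacement"`). The distinct examination
#'   count at stopping has the same distribution in both modes; only the
#'   reported draw total differs.
#'
#' @return An object of class `scenario_params` (a validated list).
#' @examples
#' scenario_params(dp = 0.6, cvmr = 0.5, r = 0.2, tdr_target = 0.9, reps = 5)
#' @export
scenario_params <- function(n_patients = 5000L, dp = 0.3, cvmr = 0.5, r = 0.2,
                            tdr_target = 0.9, mean_5y_risk = 0.10,
                            n_intervals = 5L, reps = 100L, seed = 1L,
                            sigma_scale = 0.01, redraw_trajectory = TRUE,
                            ra_mode = c("with_replacement", "without_replacement")) {
  ra_mode <- match.arg(ra_mode)
  stopifnot(
    "n_patients must be a positive count" = is.numeric(n_patients) &&
      length(n_patients) == 1L && n_patients >= 1,
    "dp must be in (0, 1]" = is.numeric(dp) && length(dp) == 1L &&
      dp > 0 && dp <= 1,
    "cvmr must be >= 0" = is.numeric(cvmr) && length(cvmr) == 1L && cvmr >= 0,
    "r must be in [0, 1)" = is.numeric(r) && length(r) == 1L && r >= 0 && r < 1,
    "tdr_target must be in (0, 1)" = is.numeric(tdr_target) &&
      length(tdr_target) == 1L && tdr_target > 0 && tdr_target < 1,
    "mean_5y_risk must be in (0, 1)" = is.numeric(mean_5y_risk) &&
      length(mean_5y_risk) == 1L && mean_5y_risk > 0 && mean_5y_risk < 1,
    "n_intervals must be >= 1" = is.numeric(n_intervals) &&
      length(n_intervals) == 1L && n_intervals >= 1,
    "reps must be >= 1" = is.numeric(reps) && length(reps) == 1L && reps >= 1,
    "seed must be a single integer" = is.numeric(seed) && length(seed) == 1L,
    "sigma_scale must be >= 0" = is.numeric(sigma_scale) &&
      length(sigma_scale) == 1L && sigma_scale >= 0,
    "redraw_trajectory must be TRUE/FALSE" = isTRUE(redraw_trajectory) ||
      isFALSE(redraw_trajectory)
  )
  p <- list(
    n_patients = as.integer(n_patients), dp = dp, cvmr = cvmr, r = r,
    tdr_target = tdr_target, mean_5y_risk = mean_5y_risk,
    n_intervals = as.integer(n_intervals), reps = as.integer(reps),
    seed = as.integer(seed), sigma_scale = sigma_scale,
    redraw_trajectory = redraw_trajectory, ra_mode = ra_mode
  )
  p$sdmr <- sdmr(p)
  class(p) <- "scenario_params"
  p
}

#' Standard deviation of the mean annual risk implied by cvmr
#'
#' @param params A [scenario_params()] object.
#' @return `cvmr * mean_5y_risk / n_intervals`.
#' @export
sdmr <- function(params) {
  params$cvmr * params$mean_5y_risk / params$n_intervals
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Screening scenario parameters\n")
  cat(sprintf("  N = %d patients, %d annual intervals, mean 5y risk %.3f\n",
              x$n_patients, x$n_intervals, x$mean_5y_risk))
  cat(sprintf("  dp = %.2f, cvmr = %.2f (sdmr = %.4f), r = %.2f\n",
              x$dp, x$cvmr, x$sdmr, x$r))
  cat(sprintf("  tdr target = %.2f, reps = %d, seed = %d, sigma_scale = %g\n",
              x$tdr_target, x$reps, x$seed, x$sigma_scale))
  cat(sprintf("  RA mode: %s; trajectory %s per repetition\n", x$ra_mode,
              if (x$redraw_trajectory) "redrawn" else "fixed"))
  invisible(x)
}

# Deterministic substream seed derivation: mixes the root seed with integer
# labels so each component (trajectory, matrix, RA run, scenario cell) gets an
# independent, reproducible seed below 2^31.
.substream <- function(seed, ...) {
  idx <- as.double(c(...))
  h <- (as.double(seed) %% 2147483647)
  for (v in idx) {
    h <- (h * 48271 + (v %% 2147483647) * 8191 + 11) %% 2147483647
  }
  out <- as.integer(h)
  if (out < 1L) out <- out + 2147483646L
  out
}
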