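#' Run one simulated screening scenario
#'
#' For each repetition a fresh mean-risk trajectory and individual risk
#' matrix are drawn (from substreams of the scenario seed, so results are
#' reproducible and strategies are compared on identical populations), the
#' three threshold strategies are calibrated to the target detection rate,
#' the random-allocation reference is run `ra_runs` times and averaged, and
#' the saving percentage of each strategy versus the random reference is
#' computed. Savings use the random reference's *distinct* examination
#' count; the raw draw total (which counts draws wasted on already-screened
#' slots in `"with_replacement"` mode) is reported alongside.
#'
#' @param params A [scenario_params()] object.
#' @param ra_runs Number of random-allocation runs averaged per repetition
#'   (default 5).
#' @param keep_reps If `TRUE`, the per-repetition results are retained in
#'   the `reps_detail` field.
#' @return An object of class `screening_scenario` with fields `params`,
#'   `strategies` (data frame: strategy, mean exams, mean saving %,
#'   Monte-Carlo standard errors), `ra` (mean exams and draws), `reps`.
#' @examples
#' p <- scenario_params(n_patients = 200, dp = 0.6, cvmr = 0.5, r = 0.2,
#'                      reps = 2, seed = 7)
#' run_scenario(p)
#' @export
run_scenario <- function(params, ra_runs = 5L, keep_reps = FALSE) {
  stopifnot(inherits(params, "scenario_params"))
  strategies <- c("CA", "CAIR", "ISA")
  reps <- params$reps
  sav <- matrix(NA_real_, reps, 3L, dimnames = list(NULL, strategies))
  exams <- matrix(NA_real_, reps, 3L, dimnames = list(NULL, strategies))
  ra_exams <- numeric(reps)
  ra_draws <- numeric(reps)
  fixed_traj <- if (!params$redraw_trajectory) {
    make_mean_trajectory(params, seed = .substream(params$seed, 0L, 1L))
  }
  for (t in seq_len(reps)) {
    traj <- if (params$redraw_trajectory) {
      make_mean_trajectory(params, seed = .substream(params$seed, t, 1L))
    } else {
      fixed_traj
    }
    rm <- sample_risk_matrix(traj, params, seed = .substream(params$seed, t, 2L))
    for (j in seq_along(strategies)) {
      cal <- calibrate_threshold(strategies[j], rm, params$dp,
                                 params$tdr_target)
      exams[t, j] <- cal$exams_at_target
    }
    ra_e <- ra_d <- numeric(ra_runs)
    for (u in seq_len(ra_runs)) {
      ra <- schedule_ra(rm, params$dp, params$tdr_target,
                        ra_mode = params$ra_mode,
                        seed = .substream(params$seed, t, 3L, u))
      ra_e[u] <- ra$exams
      ra_d[u] <- ra$draws
    }
    ra_exams[t] <- mean(ra_e)
    ra_draws[t] <- mean(ra_d)
    sav[t, ] <- saving_percentage(exams[t, ], ra_exams[t])
  }
  se <- function(x) sd(x) / sqrt(length(x))
  out <- list(
    params = params,
    strategies = data.frame(
      strategy = strategies,
      exams = colMeans(exams),
      saving = colMeans(sav),
      se_exams = apply(exams, 2L, se),
      se_saving = apply(sav, 2L, se),
      row.names = NULL
    ),
    ra = list(exams = mean(ra_exams), draws = mean(ra_draws),
              se_exams = se(ra_exams)),
    reps = reps
  )
  if (keep_reps) {
    out$reps_detail <- list(exams = exams, saving = sav,
                            ra_exams = ra_exams, ra_draws = ra_draws)
  }
  class(out) <- "screening_scenario"
  out
}

#' @export
print.screening_scenario <- function(x, ...) {
  p <- x$params
  cat(sprintf("Scenario: dp = %.2f, cvmr = %.2f, r = %.2f, tdr = %.2f (N = %d, %d reps)\n",
              p$dp, p$cvmr, p$r, p$tdr_target, p$n_patients, x$reps))
  cat(sprintf("Random reference: %.0f exams (%.0f draws incl. repeats)\n",
              x$ra$exams, x$ra$draws))
  df <- x$strategies
  cat(sprintf("  %-5s %10s %10s %8s\n", "", "exams", "saving(%)", "SE"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-5s %10.1f %10.1f %8.2f\n", df$strategy[i], df$exams[i],
                df$saving[i], df$se_saving[i]))
  }
  invisible(x)
}

#' @export
summary.screening_scenario <- function(object, ...) {
  print(object)
  invisible(object$strategies)
}

#' @export
as.data.frame.screening_scenario <- function(x, ...) {
  p <- x$params
  df <- x$strategies
  data.frame(
    dp = p$dp, cvmr = p$cvmr, r = p$r, tdr = p$tdr_target,
    strategy = df$strategy, exams = df$exams, saving = df$saving,
    se_saving = df$se_saving, ra_exams = x$ra$exams, ra_draws = x$ra$draws,
    reps = x$reps
  )
}
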