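#' Read / write a cohort table
#'
#' The cohort dialect is a CSV with header exactly
#' `patient_id,risk_y1,risk_y2,risk_y3,risk_y4,risk_y5,event_year`; an empty
#' `event_year` means the patient had no observed event. Risks are annual
#' conditional risks as fractions in `[0, 1)`; `event_year` is the 1-based
#' interval of an observed event.
#'
#' @param file Path of the cohort CSV.
#' @param cohort A cohort data frame.
#' @return `read_cohort` returns a validated cohort data frame.
#' @export
read_cohort <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, file) {
  cohort <- validate_cohort(cohort)
  out <- cohort
  out$event_year[is.na(out$event_year)] <- ""
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname read_cohort
#' @export
validate_cohort <- function(cohort) {
  risk_cols <- paste0("risk_y", 1:5)
  missing_cols <- setdiff(c("patient_id", risk_cols), names(cohort))
  if (length(missing_cols)) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"event_year" %in% names(cohort)) cohort$event_year <- NA_integer_
  cohort$event_year[cohort$event_year %in% ""] <- NA
  cohort$event_year <- as.integer(cohort$event_year)
  risks <- as.matrix(cohort[risk_cols])
  if (any(!is.finite(risks)) || any(risks < 0) || any(risks >= 1)) {
    stop("cohort risks must be fractions in [0, 1)")
  }
  ev <- cohort$event_year
  if (any(!is.na(ev) & (ev < 1L | ev > 5L))) {
    stop("event_year must be in 1..5 (or empty for no event)")
  }
  cohort
}

# Default moment targets for the synthetic cohort generator: annual means
# with the year-1 minimum (0.35%) and year-2 maximum (0.68%), declining
# thereafter, summing to 2.35% with a coefficient of variation of the five
# means of 0.24 (population-SD form); Spearman correlations decay linearly
# with lag and average 0.61 over the ten interval pairs.
.influence_annual_means <- c(0.0035, 0.0068, 0.00475, 0.0044, 0.00405)
.influence_rank_corr_lag <- c(0.77, 0.61, 0.45, 0.29)

#' Generate a synthetic cohort with INFLUENCE-like moment structure
#'
#' Draws right-skewed annual risk predictions from lognormal marginals
#' coupled by a Gaussian copula whose rank correlations decay with the lag
#' between years. Columns are rescaled multiplicatively so the population
#' annual means match `annual_means` exactly. At most one event is sampled
#' per patient, sequentially: the interval-`i` event probability equals the
#' patient's conditional annual risk given no earlier event. This generator
#' emulates published summary moments of a real nomogram cohort; it is
#' synthetic and carries none of the real registry's covariate structure.
#'
#' @param n_patients Number of patients (`>= 100`; default 6520).
#' @param seed Optional integer seed.
#' @param annual_means Target population means of the five annual risks.
#' @param sdlog Lognormal log-scale SD of each marginal (default 1.2, giving
#'   a heavy right skew comparable to nomogram risk distributions).
#' @param rank_corr_lag Target Spearman correlations at lags 1..4; the
#'   defaults average 0.61 over the ten pairs.
#' @return A cohort data frame (see [read_cohort()] for the dialect).
#' @examples
#' co <- synth_influence_cohort(500, seed = 1)
#' mean(rowSums(co[paste0("risk_y", 1:5)]))  # about 0.0235
#' @export
synth_influence_cohort <- function(n_patients = 6520L, seed = NULL,
                                   annual_means = .influence_annual_means,
                                   sdlog = 1.2,
                                   rank_corr_lag = .influence_rank_corr_lag) {
  stopifnot(
    "n_patients must be >= 100" = n_patients >= 100,
    "annual_means must be 5 fractions in (0, 1)" = length(annual_means) == 5L &&
      all(annual_means > 0 & annual_means < 1),
    "rank_corr_lag must be 4 values in [0, 1)" = length(rank_corr_lag) == 4L &&
      all(rank_corr_lag >= 0 & rank_corr_lag < 1)
  )
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_patients)
  k <- 5L
  # Spearman targets -> Pearson correlations of the latent normals
  pearson_lag <- 2 * sin(pi * rank_corr_lag / 6)
  sigma <- diag(k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    sigma[i, j] <- sigma[j, i] <- pearson_lag[j - i]
  }
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop("infeasible moment targets: latent correlation matrix is not ",
         "positive definite (", conditionMessage(e), ")")
  })
  z <- matrix(rnorm(n * k), n, k) %*% ch
  meanlog <- log(annual_means) - sdlog^2 / 2
  x <- exp(sweep(z * sdlog, 2L, meanlog, `+`))
  x <- pmin(x, 0.95)
  x <- sweep(x, 2L, annual_means / colMeans(x), `*`)
  # sequential conditional event sampling, at most one event per patient
  u <- matrix(runif(n * k), n, k)
  event <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  for (i in seq_len(k)) {
    hit <- alive & (u[, i] < x[, i])
    event[hit] <- i
    alive[hit] <- FALSE
  }
  df <- data.frame(patient_id = seq_len(n), x, event_year = event)
  names(df) <- c("patient_id", paste0("risk_y", 1:5), "event_year")
  df
}

# Quintile assignment by cumulative 5-year risk, ties broken by patient
# order; groups are near-equal (within 1).
.risk_quintiles <- function(cum_risk) {
  n <- length(cum_risk)
  ceiling(5 * rank(cum_risk, ties.method = "first") / n)
}

#' Descriptive summary of a cohort's risk structure
#'
#' Reports the five annual mean risks, their coefficient of variation
#' (population-SD form: the five yearly means are a complete set, not a
#' sample), the full Spearman rank-correlation matrix with lag-wise
#' averages and the overall mean off-diagonal correlation, and the 5-year
#' cumulative-risk quintile boundaries. Constant-risk cohorts (zero
#' variance) are flagged and their correlations reported as `NA`.
#'
#' @param cohort A cohort data frame.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  risks <- as.matrix(cohort[paste0("risk_y", 1:5)])
  means <- colMeans(risks)
  mbar <- mean(means)
  cvmr <- sqrt(mean((means - mbar)^2)) / mbar
  degenerate <- any(apply(risks, 2L, sd) == 0)
  if (degenerate) {
    rho <- matrix(NA_real_, 5L, 5L)
  } else {
    rho <- cor(risks, method = "spearman")
  }
  lag_means <- vapply(1:4, function(l) {
    mean(rho[cbind(1:(5 - l), (1 + l):5)])
  }, numeric(1))
  mean_rank_corr <- mean(rho[upper.tri(rho)])
  cum <- rowSums(risks)
  structure(list(
    n_patients = nrow(risks),
    annual_means = means,
    mean_annual = mbar,
    mean_5y = sum(means),
    cvmr = cvmr,
    rank_corr = rho,
    lag_means = lag_means,
    mean_rank_corr = mean_rank_corr,
    quintile_breaks = quantile(cum, probs = seq(0, 1, 0.2)),
    n_events = sum(!is.na(cohort$event_year)),
    degenerate = degenerate
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients, %d observed events\n",
              x$n_patients, x$n_events))
  cat(sprintf("Annual mean risks (%%): %s\n",
              paste(sprintf("%.3f", 100 * x$annual_means), collapse = " ")))
  cat(sprintf("Mean annual %.3f%%, 5-year %.2f%%, cvmr of means %.3f\n",
              100 * x$mean_annual, 100 * x$mean_5y, x$cvmr))
  if (x$degenerate) {
    cat("Rank correlations undefined (constant risk column)\n")
  } else {
    cat(sprintf("Mean Spearman correlation %.3f (lags 1-4: %s)\n",
                x$mean_rank_corr,
                paste(sprintf("%.2f", x$lag_means), collapse = " ")))
  }
  cat("5-year risk quintile breaks (%):",
      paste(sprintf("%.2f", 100 * x$quintile_breaks), collapse = " "), "\n")
  invisible(x)
}

# Expected curable detections of observed binary events under a schedule:
# reuse the occurrence-mass kernel with a one-hot event matrix.
.event_matrix <- function(cohort) {
  n <- nrow(cohort)
  e <- matrix(0, n, 5L)
  ev <- cohort$event_year
  has <- !is.na(ev)
  e[cbind(which(has), ev[has])] <- 1
  e
}

#' Evaluate screening strategies on a cohort with observed events
#'
#' Calibrates the CA, CAIR and ISA thresholds on the cohort's predicted
#' risks (expected-occurrence accounting, sensitivity cascade), applies the
#' resulting schedules — and a random-allocation reference — to the
#' observed events, and reports follow-up counts, savings versus random
#' allocation, expected curable detections, and per-quintile breakdowns.
#' Calibrating on predictions mirrors prospective deployment (a planner
#' only has predictions); set `calibrate_on = "events"` to calibrate on the
#' observed events instead.
#'
#' The strategy schedules applied are those at the calibrated
#' lower-threshold bracket, i.e. the discrete schedule that still achieves
#' at least the target detection rate.
#'
#' @param cohort A cohort data frame.
#' @param dp Progression base (default 0.3, intermediate progression).
#' @param tdr_target Target detection rate (default 0.90).
#' @param sensitivity Examination sensitivity (default 0.8); successive
#'   exams form an independent-miss cascade.
#' @param seed Optional integer seed for the random-allocation reference.
#' @param ra_mode Random-allocation mode (default `"without_replacement"`
#'   for cohorts, so draws equal exams).
#' @param ra_runs Random-allocation runs averaged (default 5).
#' @param calibrate_on `"risks"` (default) or `"events"`.
#' @return An object of class `cohort_eval`.
#' @export
evaluate_cohort <- function(cohort, dp = 0.3, tdr_target = 0.90,
                            sensitivity = 0.8, seed = NULL,
                            ra_mode = "without_replacement", ra_runs = 5L,
                            calibrate_on = c("risks", "events")) {
  calibrate_on <- match.arg(calibrate_on)
  cohort <- validate_cohort(cohort)
  if (!nrow(cohort)) stop("cohort is empty")
  risks <- as.matrix(cohort[paste0("risk_y", 1:5)])
  events <- .event_matrix(cohort)
  cal_mass <- if (calibrate_on == "risks") risks else events
  quint <- .risk_quintiles(rowSums(risks))
  n_events <- sum(events)
  full <- full_schedule(nrow(risks))
  max_detect <- .n_actual(events, full, dp, sensitivity)

  strat_names <- c("CA", "CAIR", "ISA")
  per_strategy <- list()
  for (s in strat_names) {
    cal <- calibrate_threshold(s, cal_mass, dp, tdr_target, sensitivity)
    sched <- .strategy_builder(s)(risks, cal$threshold_lo)
    per_strategy[[s]] <- list(
      calibration = cal, schedule = sched, exams = sum(sched),
      detections = .n_actual(events, sched, dp, sensitivity),
      followups_by_quintile = tapply(rowSums(sched), quint, mean),
      detections_by_quintile = vapply(1:5, function(q) {
        idx <- quint == q
        .n_actual(events[idx, , drop = FALSE],
                  sched[idx, , drop = FALSE], dp, sensitivity)
      }, numeric(1))
    )
  }

  ra_exams <- ra_draws <- ra_det <- numeric(ra_runs)
  ra_fq <- matrix(0, ra_runs, 5L)
  ra_dq <- matrix(0, ra_runs, 5L)
  base_seed <- if (is.null(seed)) NULL else seed
  for (u in seq_len(ra_runs)) {
    ra <- schedule_ra(cal_mass, dp, tdr_target, ra_mode = ra_mode,
                      sensitivity = sensitivity,
                      seed = if (is.null(base_seed)) NULL else
                        .substream(base_seed, 4L, u))
    ra_exams[u] <- ra$exams
    ra_draws[u] <- ra$draws
    ra_det[u] <- .n_actual(events, ra$schedule, dp, sensitivity)
    ra_fq[u, ] <- tapply(rowSums(ra$schedule), quint, mean)
    ra_dq[u, ] <- vapply(1:5, function(q) {
      idx <- quint == q
      .n_actual(events[idx, , drop = FALSE],
                ra$schedule[idx, , drop = FALSE], dp, sensitivity)
    }, numeric(1))
  }
  ra_summary <- list(
    exams = mean(ra_exams), draws = mean(ra_draws),
    detections = mean(ra_det),
    followups_by_quintile = colMeans(ra_fq),
    detections_by_quintile = colMeans(ra_dq)
  )

  tab <- data.frame(
    strategy = c("RA", strat_names),
    exams = c(ra_summary$exams,
              vapply(per_strategy, `[[`, numeric(1), "exams")),
    saving = c(0, vapply(per_strategy, function(p) {
      saving_percentage(p$exams, ra_summary$exams)
    }, numeric(1))),
    detections = c(ra_summary$detections,
                   vapply(per_strategy, `[[`, numeric(1), "detections")),
    row.names = NULL
  )
  structure(list(
    table = tab, strategies = per_strategy, ra = ra_summary,
    quintiles = quint, quintile_breaks = quantile(rowSums(risks),
                                                  probs = seq(0, 1, 0.2)),
    n_events = n_events, max_detections = max_detect,
    settings = list(dp = dp, tdr_target = tdr_target,
                    sensitivity = sensitivity, ra_mode = ra_mode,
                    ra_runs = ra_runs, calibrate_on = calibrate_on)
  ), class = "cohort_eval")
}

#' @export
print.cohort_eval <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Cohort evaluation: dp = %.2f, tdr target = %.2f, sensitivity = %.2f\n",
              s$dp, s$tdr_target, s$sensitivity))
  cat(sprintf("%d observed events; %.1f expected curable detections under full screening\n",
              x$n_events, x$max_detections))
  tab <- x$table
  cat(sprintf("  %-5s %10s %12s %12s\n", "", "followups", "avoided(%)",
              "detections"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-5s %10.0f %12s %12.1f\n", tab$strategy[i], tab$exams[i],
                if (tab$strategy[i] == "RA") "ref." else
                  sprintf("%.1f", tab$saving[i]),
                tab$detections[i]))
  }
  invisible(x)
}

#' @export
summary.cohort_eval <- function(object, ...) {
  print(object)
  cat("\nMean follow-ups per patient by 5-year-risk quintile:\n")
  fq <- rbind(RA = object$ra$followups_by_quintile,
              do.call(rbind, lapply(object$strategies, `[[`,
                                    "followups_by_quintile")))
  colnames(fq) <- paste0("Q", 1:5)
  print(round(fq, 2))
  cat("\nExpected curable detections by quintile:\n")
  dq <- rbind(RA = object$ra$detections_by_quintile,
              do.call(rbind, lapply(object$strategies, `[[`,
                                    "detections_by_quintile")))
  colnames(dq) <- paste0("Q", 1:5)
  print(round(dq, 2))
  invisible(object)
}

#' @export
plot.cohort_eval <- function(x, ...) {
  fq <- rbind(RA = x$ra$followups_by_quintile,
              do.call(rbind, lapply(x$strategies, `[[`,
                                    "followups_by_quintile")))
  graphics::barplot(fq, beside = TRUE, names.arg = paste0("Q", 1:5),
                    legend.text = rownames(fq),
                    xlab = "5-year risk quintile",
                    ylab = "mean follow-ups per patient", ...)
  invisible(x)
}
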