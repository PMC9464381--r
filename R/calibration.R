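.strategy_builder <- function(strategy) {
  switch(strategy,
    CA = schedule_ca, CAIR = schedule_cair, ISA = schedule_isa,
    stop("unknown strategy: ", strategy)
  )
}

.threshold_upper <- function(strategy, r) {
  if (strategy == "ISA") max(r) + 1e-6 else max(rowSums(r)) + 1e-6
}

#' Calibrate a strategy threshold to a target detection rate
#'
#' Finds, by bisection on the threshold, the point where the achieved
#' detection rate of a strategy crosses `tdr_target`. Because schedules are
#' discrete the target is in general not hit exactly: the function returns
#' the bracketing thresholds (`threshold_lo < threshold_hi`, with
#' `tdr_lo >= tdr_target >= tdr_hi`) and the linearly interpolated
#' real-valued examination count at exactly the target,
#' `exams_at_target = e_hi + (e_lo - e_hi) * (tdr_target - tdr_hi) / (tdr_lo - tdr_hi)`.
#' A degenerate bracket (`tdr_lo == tdr_hi`) resolves to the fewer-exams
#' side. If the bisection bracket ever looks non-monotone (possible in
#' principle for CAIR, whose resets make monotonicity non-obvious), the
#' function falls back to a monotone envelope over a 512-point threshold
#' grid.
#'
#' @inheritParams detection_summary
#' @param strategy One of `"CA"`, `"CAIR"`, `"ISA"`.
#' @param tdr_target Target detection rate in (0, 1).
#' @param tol Bracket width at which bisection stops (risk units, default
#'   `1e-8`).
#' @return An object of class `calibrated_strategy`: `strategy`,
#'   `threshold_lo`, `threshold_hi`, `tdr_lo`, `tdr_hi`, `exams_lo`,
#'   `exams_hi`, `exams_at_target`.
#' @examples
#' r <- matrix(c(0.09, 0.10, 0.11) / 5, 3, 5)
#' calibrate_threshold("CA", r, dp = 0.3, tdr_target = 0.9)
#' @export
calibrate_threshold <- function(strategy, risks, dp, tdr_target,
                                sensitivity = 1.0, tol = 1e-8) {
  strategy <- match.arg(strategy, c("CA", "CAIR", "ISA"))
  r <- .risks(risks)
  stopifnot(
    "tdr_target must be in (0, 1)" = tdr_target > 0 && tdr_target < 1,
    "dp must be in (0, 1]" = dp > 0 && dp <= 1
  )
  builder <- .strategy_builder(strategy)
  n_max <- .n_max(r, dp, sensitivity)
  if (n_max <= 0) stop("infeasible-target: risk matrix carries no occurrence mass")
  eval_thr <- function(th) {
    s <- builder(r, th)
    c(tdr = .n_actual(r, s, dp, sensitivity) / n_max, exams = sum(s))
  }
  lo <- 0
  hi <- .threshold_upper(strategy, r)
  f_lo <- eval_thr(lo)
  f_hi <- eval_thr(hi)
  if (f_lo[["tdr"]] < tdr_target) {
    stop("infeasible-target: full schedule achieves tdr ", f_lo[["tdr"]],
         " < target ", tdr_target)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- eval_thr(mid)
    if (f_mid[["tdr"]] >= tdr_target) {
      lo <- mid
      f_lo <- f_mid
    } else {
      hi <- mid
      f_hi <- f_mid
    }
  }
  if (f_lo[["tdr"]] < tdr_target - 1e-12 || f_hi[["tdr"]] > tdr_target) {
    # calibration-anomaly: rebuild a monotone envelope on a fixed grid
    grid <- seq(0, .threshold_upper(strategy, r), length.out = 512L)
    ev <- vapply(grid, eval_thr, numeric(2))
    tdrs <- rev(cummax(rev(ev["tdr", ])))  # enforce non-increasing in threshold
    i_hi <- which(tdrs < tdr_target)[1L]
    if (is.na(i_hi) || i_hi == 1L) {
      stop("calibration-anomaly: no bracketing thresholds found for ", strategy)
    }
    lo <- grid[i_hi - 1L]
    hi <- grid[i_hi]
    f_lo <- ev[, i_hi - 1L]
    f_hi <- ev[, i_hi]
  }
  tdr_lo <- f_lo[["tdr"]]
  tdr_hi <- f_hi[["tdr"]]
  e_lo <- f_lo[["exams"]]
  e_hi <- f_hi[["exams"]]
  exams_at_target <- if (tdr_lo == tdr_hi) e_hi else
    e_hi + (e_lo - e_hi) * (tdr_target - tdr_hi) / (tdr_lo - tdr_hi)
  structure(list(
    strategy = strategy, tdr_target = tdr_target,
    threshold_lo = lo, threshold_hi = hi,
    tdr_lo = tdr_lo, tdr_hi = tdr_hi,
    exams_lo = e_lo, exams_hi = e_hi,
    exams_at_target = exams_at_target
  ), class = "calibrated_strategy")
}

#' @export
print.calibrated_strategy <- function(x, ...) {
  cat(sprintf("%s calibrated to tdr %.3f:\n", x$strategy, x$tdr_target))
  cat(sprintf("  threshold in [%.6g, %.6g], tdr bracket [%.5f, %.5f]\n",
              x$threshold_lo, x$threshold_hi, x$tdr_hi, x$tdr_lo))
  cat(sprintf("  exams at target: %.1f (bracket %d..%d)\n",
              x$exams_at_target, as.integer(x$exams_hi), as.integer(x$exams_lo)))
  invisible(x)
}

#' Percentage of examinations saved relative to random allocation
#'
#' @param exams_strategy Real-valued examination count of a strategy.
#' @param exams_ra Examination count of the random-allocation reference,
#'   `> 0`.
#' @return `100 * (exams_ra - exams_strategy) / exams_ra`; negative when the
#'   strategy needs more examinations than random allocation.
#' @examples
#' saving_percentage(768, 1000)  # 23.2
#' @export
saving_percentage <- function(exams_strategy, exams_ra) {
  if (any(exams_ra <= 0)) stop("exams_ra must be > 0")
  100 * (exams_ra - exams_strategy) / exams_ra
}
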