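#' Curability after a detection delay
#'
#' The probability that a disease occurrence is still fully curable when
#' detected `delay` years after onset follows an exponential decay
#' `dp^delay`, where `dp` is the progression base (near 1: slow progression;
#' near 0: fast).
#'
#' @param dp Progression base in (0, 1].
#' @param delay Detection delay in years, `>= 0` (vectorized).
#' @return `dp^delay`.
#' @examples
#' curability(0.3, 0)    # 1
#' curability(0.6, 0.5)  # 0.7745967
#' @export
curability <- function(dp, delay) {
  stopifnot("dp must be in (0, 1]" = is.numeric(dp) && all(dp > 0 & dp <= 1))
  if (any(delay < 0)) {
    stop("logic error: negative detection delay (an exam cannot detect a future occurrence)")
  }
  dp^delay
}

#' Screening schedules
#'
#' A screening schedule is an `n_patients x n_intervals` 0/1 integer matrix;
#' entry `(k, i) = 1` means patient `k` is examined at the end of interval
#' `i`, i.e. at time `t = i` years. Intervals are 1-based and interval `i`
#' spans `(i - 1, i]`; an occurrence in interval `i` is placed at its
#' midpoint `t_occ = i - 0.5`, so the exam of the same interval detects it
#' with the minimum delay of half a year.
#'
#' @param n_patients,n_intervals Schedule dimensions.
#' @return An integer 0/1 matrix.
#' @export
full_schedule <- function(n_patients, n_intervals = 5L) {
  matrix(1L, n_patients, n_intervals)
}

#' @rdname full_schedule
#' @export
empty_schedule <- function(n_patients, n_intervals = 5L) {
  matrix(0L, n_patients, n_intervals)
}

.as_schedule <- function(s) {
  if (is.data.frame(s)) s <- as.matrix(s[grep("^exam_y", names(s))])
  storage.mode(s) <- "integer"
  if (!all(s %in% c(0L, 1L))) stop("schedule entries must be 0/1")
  s
}

# Closed-form maximum: under the all-ones schedule the q-th exam after an
# interval-i occurrence happens q years later, so
# n_max = sum_i colsum_i * sum_q sens (1-sens)^q dp^(q + 0.5).
.n_max <- function(risks, dp, sensitivity) {
  k <- ncol(risks)
  cs <- colSums(risks)
  sum(vapply(seq_len(k), function(i) {
    q <- 0:(k - i)
    cs[i] * sum(sensitivity * (1 - sensitivity)^q * dp^(q + 0.5))
  }, numeric(1)))
}

.n_actual <- function(risks, schedule, dp, sensitivity) {
  n_actual_cpp(risks, schedule, dp, sensitivity)
}

#' Expected curable detections for a schedule
#'
#' Treats each annual conditional risk `p[k, i]` as expected occurrence mass
#' placed at the interval midpoint `t_occ = i - 0.5`. For a schedule, the
#' mass of interval `i` contributes through each of the patient's exams at
#' times `t_j >= i` (in order, missed-exam rank `q = 0, 1, ...`):
#' `sensitivity * (1 - sensitivity)^q * dp^(t_j - t_occ)`. Occurrences with
#' no subsequent exam contribute nothing. `n_max` is the same computation
#' under the all-ones schedule, so the achieved target detection rate
#' `tdr = n_actual / n_max` equals 1 for full screening regardless of
#' sensitivity. Everything is an exact expectation; no binary events are
#' sampled.
#'
#' @param risks A `risk_matrix`, cohort table, or numeric matrix of
#'   occurrence mass.
#' @param schedule A 0/1 matrix of the same dimensions (see
#'   [full_schedule()]).
#' @param dp Progression base in (0, 1].
#' @param sensitivity Per-exam detection sensitivity in (0, 1]; successive
#'   exams form an independent-miss cascade.
#' @return An object of class `detection_summary`: list with `n_max`,
#'   `n_actual`, `tdr_achieved` and `exams`.
#' @examples
#' r <- matrix(0.02, 1, 5)
#' s <- matrix(c(0, 1, 0, 0, 1), 1, 5)
#' detection_summary(r, s, dp = 0.3)  # tdr_achieved = 0.538
#' @export
detection_summary <- function(risks, schedule, dp, sensitivity = 1.0) {
  r <- .risks(risks)
  s <- .as_schedule(schedule)
  stopifnot(
    "dimensions of risks and schedule must agree" = all(dim(r) == dim(s)),
    "dp must be in (0, 1]" = dp > 0 && dp <= 1,
    "sensitivity must be in (0, 1]" = sensitivity > 0 && sensitivity <= 1
  )
  n_max <- .n_max(r, dp, sensitivity)
  n_act <- .n_actual(r, s, dp, sensitivity)
  structure(list(
    n_max = n_max, n_actual = n_act,
    tdr_achieved = if (n_max > 0) n_act / n_max else 0,
    exams = sum(s)
  ), class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf("Detection summary: %d exams, n_actual = %.4f / n_max = %.4f (tdr = %.4f)\n",
              x$exams, x$n_actual, x$n_max, x$tdr_achieved))
  invisible(x)
}

#' @export
as.list.detection_summary <- function(x, ...) unclass(x)
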