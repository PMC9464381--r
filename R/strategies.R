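#' Threshold-based screening allocation strategies
#'
#' Three deterministic rules build a screening schedule from a matrix of
#' annual risk predictions and a risk threshold (all comparisons are
#' inclusive, so threshold 0 yields the full schedule):
#'
#' * **CA** (cumulative approach): a patient whose five annual risks sum to
#'   at least the threshold is screened every year; otherwise never.
#' * **CAIR** (cumulative approach with interval-wise reevaluation): risks
#'   are accumulated year by year; when the running sum reaches the
#'   threshold an exam is scheduled at the end of that year and the sum
#'   resets to zero.
#' * **ISA** (interval-specific approach): an exam is scheduled after every
#'   year whose own annual risk reaches the threshold.
#'
#' @param risks A `risk_matrix`, cohort table, or numeric matrix.
#' @param threshold Risk threshold, `>= 0`.
#' @return A 0/1 integer schedule matrix.
#' @examples
#' r <- matrix(c(0.01, 0.02, 0.03, 0.02, 0.02), 1, 5)
#' schedule_cair(r, 0.04)  # exams after years 3 and 5
#' @export
schedule_ca <- function(risks, threshold) {
  r <- .risks(risks)
  stopifnot("threshold must be >= 0" = threshold >= 0)
  high <- rowSums(r) >= threshold
  matrix(as.integer(high), nrow(r), ncol(r))
}

#' @rdname schedule_ca
#' @export
schedule_cair <- function(risks, threshold) {
  r <- .risks(risks)
  stopifnot("threshold must be >= 0" = threshold >= 0)
  n <- nrow(r)
  k <- ncol(r)
  if (threshold <= 0) return(full_schedule(n, k))
  s <- matrix(0L, n, k)
  running <- numeric(n)
  for (i in seq_len(k)) {
    running <- running + r[, i]
    hit <- running >= threshold
    s[hit, i] <- 1L
    running[hit] <- 0
  }
  s
}

#' @rdname schedule_ca
#' @export
schedule_isa <- function(risks, threshold) {
  r <- .risks(risks)
  stopifnot("threshold must be >= 0" = threshold >= 0)
  s <- (r >= threshold)
  storage.mode(s) <- "integer"
  s
}

#' Random allocation of screening examinations
#'
#' The uninformed reference strategy: patient-interval slots are drawn
#' uniformly at random one at a time and the achieved detection rate is
#' updated after every draw; allocation stops at the first draw for which
#' `tdr_achieved >= tdr_target`. In `"with_replacement"` mode a repeated
#' slot consumes a draw without adding an exam (so the draw total can exceed
#' the number of slots); in `"without_replacement"` mode draws are over
#' remaining slots only and the draw total equals the exam count.
#'
#' @inheritParams detection_summary
#' @param tdr_target Target detection rate, in (0, 1].
#' @param ra_mode Draw-counting mode, see above.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A list of class `ra_allocation`: `schedule`, `draws`, `exams`,
#'   `tdr_achieved`.
#' @export
schedule_ra <- function(risks, dp, tdr_target,
                        ra_mode = c("with_replacement", "without_replacement"),
                        sensitivity = 1.0, seed = NULL) {
  ra_mode <- match.arg(ra_mode)
  r <- .risks(risks)
  stopifnot(
    "dp must be in (0, 1]" = dp > 0 && dp <= 1,
    "sensitivity must be in (0, 1]" = sensitivity > 0 && sensitivity <= 1
  )
  if (tdr_target > 1) {
    stop("infeasible-target: tdr_target exceeds 1, unreachable even at full coverage")
  }
  if (!is.null(seed)) set.seed(seed)
  slots <- length(r)
  n_max <- .n_max(r, dp, sensitivity)
  target_actual <- tdr_target * n_max - 1e-9
  if (ra_mode == "without_replacement") {
    draws <- sample.int(slots)
  } else {
    draws <- sample.int(slots, 8L * slots, replace = TRUE)
  }
  res <- ra_allocate_cpp(r, dp, sensitivity, target_actual, draws)
  tries <- 0L
  while (res$draws < 0L && ra_mode == "with_replacement" && tries < 8L) {
    # extend the same stream; rerunning the full prefix is deterministic
    draws <- c(draws, sample.int(slots, 8L * slots, replace = TRUE))
    res <- ra_allocate_cpp(r, dp, sensitivity, target_actual, draws)
    tries <- tries + 1L
  }
  if (res$draws < 0L) {
    stop("infeasible-target: random allocation failed to reach tdr_target ",
         tdr_target)
  }
  structure(list(
    schedule = res$schedule, draws = res$draws, exams = res$exams,
    tdr_achieved = if (n_max > 0) res$n_actual / n_max else 0,
    ra_mode = ra_mode
  ), class = "ra_allocation")
}

#' @export
print.ra_allocation <- function(x, ...) {
  cat(sprintf("Random allocation (%s): %d draws, %d exams, tdr achieved %.4f\n",
              x$ra_mode, x$draws, x$exams, x$tdr_achieved))
  invisible(x)
}

#' Export a schedule in the shared table dialect
#'
#' @param schedule A 0/1 schedule matrix.
#' @param file Path to write a CSV with header
#'   `patient_id,exam_y1,...,exam_y<k>`.
#' @return `file`, invisibly.
#' @export
write_schedule <- function(schedule, file) {
  s <- .as_schedule(schedule)
  df <- data.frame(patient_id = seq_len(nrow(s)), s)
  names(df) <- c("patient_id", paste0("exam_y", seq_len(ncol(s))))
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
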