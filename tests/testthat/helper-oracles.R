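# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package kernels.

# Expected curable detections: loop over patient x occurrence-interval x exam.
naive_n_actual <- function(risks, schedule, dp, sens = 1) {
  n <- nrow(risks)
  k <- ncol(risks)
  total <- 0
  for (pat in seq_len(n)) {
    exam_years <- which(schedule[pat, ] == 1)
    for (occ in seq_len(k)) {
      t_occ <- occ - 0.5
      later <- exam_years[exam_years >= occ]
      if (!length(later)) next
      for (rank in seq_along(later)) {
        p_reach <- sens * (1 - sens)^(rank - 1)
        total <- total + risks[pat, occ] * p_reach * dp^(later[rank] - t_occ)
      }
    }
  }
  total
}

naive_n_max <- function(risks, dp, sens = 1) {
  naive_n_actual(risks, matrix(1L, nrow(risks), ncol(risks)), dp, sens)
}

# Exhaustive CA calibration: sweep every distinct row-sum threshold and
# interpolate between the two detection-rate plateaus straddling the target.
brute_ca_exams <- function(risks, dp, target, sens = 1) {
  sums <- rowSums(risks)
  thresholds <- sort(unique(c(0, sums, max(sums) + 1e-9)))
  nmx <- naive_n_max(risks, dp, sens)
  tdrs <- exams <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    sched <- matrix(as.integer(sums >= thresholds[i]), nrow(risks), ncol(risks))
    tdrs[i] <- naive_n_actual(risks, sched, dp, sens) / nmx
    exams[i] <- sum(sched)
  }
  i_hi <- which(tdrs < target)[1]
  if (is.na(i_hi)) return(exams[length(exams)])
  i_lo <- i_hi - 1
  if (tdrs[i_lo] == tdrs[i_hi]) return(exams[i_hi])
  exams[i_hi] + (exams[i_lo] - exams[i_hi]) *
    (target - tdrs[i_hi]) / (tdrs[i_lo] - tdrs[i_hi])
}

random_risk_fixture <- function(n = 20, k = 5, seed = 1) {
  set.seed(seed)
  matrix(runif(n * k, 0, 0.05), n, k)
}

random_schedule_fixture <- function(n = 20, k = 5, p = 0.4, seed = 2) {
  set.seed(seed)
  matrix(rbinom(n * k, 1, p), n, k)
}
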