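#' Draw a population mean-risk trajectory with exact moments
#'
#' Draws `n_intervals` standard-normal deviates and affinely standardizes
#' them so the resulting mean annual risks have *exactly* the prescribed
#' sample mean (`mean_5y_risk / n_intervals`) and sample standard deviation
#' (`sdmr`, implied by `cvmr`). With `cvmr = 0` all means are identical. If
#' any standardized mean falls at or below `1e-4` the draw is rejected and
#' redrawn (at most 100 attempts) so that all means stay positive.
#'
#' @param params A [scenario_params()] object.
#' @param seed Optional integer seed applied before drawing; `NULL` uses the
#'   current RNG state.
#' @return An object of class `mean_risk_trajectory`: a list with `means`
#'   (length `n_intervals`), `sdmr` and `cvmr`.
#' @examples
#' tr <- make_mean_trajectory(scenario_params(cvmr = 0.5), seed = 1)
#' sum(tr$means)   # exactly 0.10
#' sd(tr$means)    # exactly 0.01
#' @export
make_mean_trajectory <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_intervals
  mbar <- params$mean_5y_risk / n
  s <- sdmr(params)
  if (s == 0 || n == 1L) {
    means <- rep(mbar, n)
  } else {
    means <- NULL
    for (attempt in seq_len(100L)) {
      z <- rnorm(n)
      if (sd(z) == 0) next
      m <- mbar + s * (z - mean(z)) / sd(z)
      if (all(m > 1e-4)) {
        means <- m
        break
      }
    }
    if (is.null(means)) {
      stop("invalid-parameter: could not construct positive mean annual risks ",
           "for cvmr = ", params$cvmr, " (sdmr = ", s, ") in 100 attempts")
    }
  }
  structure(list(means = means, sdmr = s, cvmr = params$cvmr),
            class = "mean_risk_trajectory")
}

#' @export
print.mean_risk_trajectory <- function(x, ...) {
  cat("Mean annual risk trajectory (cvmr =", x$cvmr, "):\n")
  print(round(x$means, 5))
  invisible(x)
}

# Equicorrelated standard-normal draws: one shared factor plus independent
# noise gives corr(Z_i, Z_j) = r exactly for all pairs.
.sample_equicorr_normal <- function(n, k, r) {
  if (r < 0 || r >= 1) stop("invalid-parameter: r must be in [0, 1)")
  u <- rnorm(n)
  sqrt(r) * matrix(u, n, k) + sqrt(1 - r) * matrix(rnorm(n * k), n, k)
}

#' Sample an individual risk matrix around a trajectory
#'
#' Individual annual risks are jointly normal around the year-specific
#' population means, with equicorrelation `r` between all interval pairs and
#' per-year standard deviation `sigma_scale / abs(log10(m_i))` (spread
#' inversely related to the magnitude of the log mean risk). Negative draws
#' are truncated at zero and each column is then rescaled multiplicatively so
#' its mean equals the trajectory mean exactly, preserving the population
#' occurrence total that the detection-rate denominator depends on.
#'
#' @param trajectory A [make_mean_trajectory()] result.
#' @param params A [scenario_params()] object.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return An object of class `risk_matrix`: list with `risks`
#'   (`n_patients x n_intervals`, non-negative) and `trajectory`.
#' @examples
#' p <- scenario_params(n_patients = 100, cvmr = 0, r = 0.5, reps = 1)
#' rm <- sample_risk_matrix(make_mean_trajectory(p), p, seed = 1)
#' colMeans(rm$risks)  # equals the trajectory means
#' @export
sample_risk_matrix <- function(trajectory, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- trajectory$means
  k <- length(m)
  sig <- if (params$sigma_scale == 0) rep(0, k) else
    params$sigma_scale / abs(log10(m))
  z <- .sample_equicorr_normal(params$n_patients, k, params$r)
  x <- sweep(sweep(z, 2L, sig, `*`), 2L, m, `+`)
  x[x < 0] <- 0
  cm <- colMeans(x)
  if (any(cm <= 0)) stop("invalid-parameter: a risk column truncated to zero mass")
  x <- sweep(x, 2L, m / cm, `*`)
  structure(list(risks = x, trajectory = trajectory), class = "risk_matrix")
}

#' @export
print.risk_matrix <- function(x, ...) {
  cat(sprintf("Risk matrix: %d patients x %d intervals\n",
              nrow(x$risks), ncol(x$risks)))
  cat("Column means:", paste(signif(colMeans(x$risks), 4), collapse = " "), "\n")
  invisible(x)
}

# Accept a risk_matrix, a cohort table, or a plain numeric matrix.
.risks <- function(risks) {
  if (inherits(risks, "risk_matrix")) return(risks$risks)
  if (is.data.frame(risks)) return(as.matrix(risks[grep("^risk_y", names(risks))]))
  if (is.matrix(risks)) return(risks)
  stop("risks must be a risk_matrix, a cohort data.frame, or a numeric matrix")
}

#' Write / read a risk matrix as a delimited table
#'
#' The table dialect is shared with the cohort module: a header
#' `patient_id,risk_y1,...,risk_y<k>` and one row per patient.
#'
#' @param risks A `risk_matrix` or numeric matrix.
#' @param file Path to write to / read from.
#' @return `read_risk_matrix` returns a numeric matrix with a
#'   `patient_id` rownames; `write_risk_matrix` returns `file` invisibly.
#' @export
write_risk_matrix <- function(risks, file) {
  x <- .risks(risks)
  df <- data.frame(patient_id = seq_len(nrow(x)), x)
  names(df) <- c("patient_id", paste0("risk_y", seq_len(ncol(x))))
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_risk_matrix
#' @export
read_risk_matrix <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  cols <- grep("^risk_y", names(df), value = TRUE)
  x <- as.matrix(df[cols])
  rownames(x) <- df$patient_id
  x
}
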