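#' Parse and validate a run configuration
#'
#' Merges user overrides into the default configuration (the standard
#' scenario grid: N = 5000, reps = 100, tdr 0.9, dp {0.6, 0.3, 0.1},
#' cvmr {0.5, 0.25, 0.05}, r {0.2, 0.5, 0.8}) and validates every numeric
#' field against its documented range, collecting *all* violations into one
#' error message.
#'
#' @param overrides A named list of settings to override (unknown names are
#'   an error). List-valued fields (`dp`, `cvmr`, `r`, `tdr`) may be given
#'   as numeric vectors or comma-separated strings.
#' @return A validated configuration list of class `run_config`.
#' @examples
#' parse_config(list(reps = 20))$reps
#' @export
parse_config <- function(overrides = list()) {
  defaults <- list(
    n_patients = 5000L, reps = 100L, seed = 1L,
    dp = c(0.6, 0.3, 0.1), cvmr = c(0.5, 0.25, 0.05), r = c(0.2, 0.5, 0.8),
    tdr = 0.9, sigma_scale = 0.01, ra_mode = "with_replacement",
    ra_runs = 5L, sensitivity = 1.0, tol = 1e-8, out = "."
  )
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (nm %in% c("dp", "cvmr", "r", "tdr") && is.character(v)) {
      v <- as.numeric(strsplit(v, ",")[[1L]])
    }
    cfg[[nm]] <- v
  }
  problems <- character()
  chk <- function(ok, msg) if (!all(ok)) problems <<- c(problems, msg)
  chk(cfg$n_patients >= 1, "n_patients must be >= 1")
  chk(cfg$reps >= 1, "reps must be >= 1")
  chk(cfg$dp > 0 & cfg$dp <= 1, "dp must be in (0, 1]")
  chk(cfg$cvmr >= 0, "cvmr must be >= 0")
  chk(cfg$r >= 0 & cfg$r < 1, "r must be in [0, 1)")
  chk(cfg$tdr > 0 & cfg$tdr < 1, "tdr must be in (0, 1)")
  chk(cfg$sigma_scale >= 0, "sigma_scale must be >= 0")
  chk(cfg$sensitivity > 0 & cfg$sensitivity <= 1,
      "sensitivity must be in (0, 1]")
  chk(cfg$ra_mode %in% c("with_replacement", "without_replacement"),
      "ra_mode must be with_replacement or without_replacement")
  chk(cfg$tol > 0, "tol must be > 0")
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg$reps <- as.integer(cfg$reps)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Write grid results, marginal tables and a manifest to a directory
#'
#' Emits `grid_results.csv` (full precision, one row per scenario and tdr),
#' `marginals_dp.csv`, `marginals_cvmr.csv`, `marginals_r.csv` (savings
#' rounded to one decimal, matching the precision of summary tables), and
#' `manifest.json` recording the seed, package version, RA convention,
#' sigma_scale and the scenario-id-to-parameters mapping.
#'
#' @param grid A `screening_grid` from [run_grid()].
#' @param out_dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_grid_results <- function(grid, out_dir = ".") {
  stopifnot(inherits(grid, "screening_grid"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  p <- file.path(out_dir, "grid_results.csv")
  write.csv(grid$results, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  for (by in c("dp", "cvmr", "r")) {
    m <- marginal_savings(grid, by)
    m[c("ca_saving", "cair_saving", "isa_saving")] <-
      round(m[c("ca_saving", "cair_saving", "isa_saving")], 1)
    p <- file.path(out_dir, paste0("marginals_", by, ".csv"))
    write.csv(m, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  manifest <- c(grid$settings, list(scenario_mapping = grid$mapping))
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
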