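test_that("scenario numbering honours the printed parameter pairs", {
  m <- scenario_grid_mapping()
  lookup <- function(id) unlist(m[m$scenario_id == id, c("dp", "cvmr", "r")])
  expect_equal(lookup(1), c(dp = 0.6, cvmr = 0.5, r = 0.2))
  expect_equal(lookup(3), c(dp = 0.6, cvmr = 0.05, r = 0.2))
  expect_equal(lookup(9), c(dp = 0.6, cvmr = 0.05, r = 0.8))
  expect_equal(lookup(14), c(dp = 0.3, cvmr = 0.25, r = 0.5))
  expect_equal(lookup(25), c(dp = 0.1, cvmr = 0.5, r = 0.8))
  expect_equal(lookup(27), c(dp = 0.1, cvmr = 0.05, r = 0.8))
  expect_equal(nrow(m), 27)
})

test_that("a one-cell grid reproduces the single-scenario run", {
  g <- run_grid(dp = 0.6, cvmr = 0.5, r = 0.2, tdr = 0.9, n_patients = 200,
                reps = 2, seed = 77)
  expect_equal(nrow(g$results), 1)
  cell_seed <- riskscreen:::.substream(77, 1, 1)
  ref <- run_scenario(scenario_params(n_patients = 200, dp = 0.6, cvmr = 0.5,
                                      r = 0.2, tdr_target = 0.9, reps = 2,
                                      seed = cell_seed))
  expect_equal(g$results$cair_saving,
               ref$strategies$saving[ref$strategies$strategy == "CAIR"])
  expect_equal(g$results$ra_exams, ref$ra$exams)
})

test_that("marginal summaries average scenarios sharing a parameter", {
  g <- run_grid(dp = c(0.6, 0.3), cvmr = c(0.5, 0.05), r = 0.2, tdr = 0.9,
                n_patients = 150, reps = 1, seed = 3)
  m <- marginal_savings(g, "dp")
  expect_equal(nrow(m), 2)
  manual <- mean(g$results$isa_saving[g$results$dp == 0.6])
  expect_equal(m$isa_saving[m$dp == 0.6], manual)
})

test_that("grid outputs round-trip deterministically through the file set", {
  g <- run_grid(dp = 0.3, cvmr = 0.25, r = c(0.2, 0.8), tdr = 0.9,
                n_patients = 150, reps = 1, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_grid_results(g, d1)
  expect_true(all(file.exists(file.path(
    d1, c("grid_results.csv", "marginals_dp.csv", "marginals_cvmr.csv",
          "marginals_r.csv", "manifest.json")))))
  back <- read.csv(file.path(d1, "grid_results.csv"))
  expect_equal(back$cair_saving, g$results$cair_saving, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$seed, 9)
  expect_equal(manifest$ra_mode, "with_replacement")
  expect_equal(manifest$sigma_scale, 0.01)
  expect_equal(length(manifest$scenario_mapping), 2)
  # re-running with the same seed writes byte-identical tables
  g2 <- run_grid(dp = 0.3, cvmr = 0.25, r = c(0.2, 0.8), tdr = 0.9,
                 n_patients = 150, reps = 1, seed = 9)
  write_grid_results(g2, d2)
  expect_identical(readLines(file.path(d1, "grid_results.csv")),
                   readLines(file.path(d2, "grid_results.csv")))
})
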