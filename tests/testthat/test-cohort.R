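test_that("the synthetic cohort reproduces its target moment structure", {
  co <- synth_influence_cohort(3000, seed = 42)
  sm <- summarize_cohort(co)
  expect_equal(unname(sm$annual_means),
               c(0.0035, 0.0068, 0.00475, 0.0044, 0.00405), tolerance = 1e-9)
  expect_equal(sm$mean_5y, 0.022, tolerance = 0.1)
  expect_equal(sm$cvmr, 0.24, tolerance = 0.01)
  expect_equal(sm$mean_rank_corr, 0.61, tolerance = 0.05)
  # correlation declines with increasing lag
  expect_true(all(diff(sm$lag_means) < 0))
  # year 1 is the minimum, year 2 the maximum
  expect_equal(unname(which.min(sm$annual_means)), 1L)
  expect_equal(unname(which.max(sm$annual_means)), 2L)
})

test_that("event counts follow the generator's own binomial expectation", {
  co <- synth_influence_cohort(6520, seed = 7)
  n_events <- sum(!is.na(co$event_year))
  expected <- 6520 * 0.022
  expect_lt(abs(n_events - expected), 3 * sqrt(6520 * 0.022 * 0.978) + 10)
  expect_true(all(co$event_year %in% c(NA, 1:5)))
})

test_that("an uncorrelated generator yields near-zero rank correlations", {
  co <- synth_influence_cohort(800, seed = 3, rank_corr_lag = rep(0, 4))
  sm <- summarize_cohort(co)
  expect_equal(sm$mean_rank_corr, 0, tolerance = 0.1)
})

test_that("cohort summaries handle constant risks and split clean quintiles", {
  const <- data.frame(patient_id = 1:200,
                      risk_y1 = 0.01, risk_y2 = 0.01, risk_y3 = 0.01,
                      risk_y4 = 0.01, risk_y5 = 0.01,
                      event_year = NA_integer_)
  sm <- summarize_cohort(const)
  expect_true(sm$degenerate)
  expect_equal(sm$cvmr, 0)
  expect_true(all(is.na(sm$rank_corr)))
  co <- synth_influence_cohort(501, seed = 5)
  q <- riskscreen:::.risk_quintiles(rowSums(co[paste0("risk_y", 1:5)]))
  expect_true(all(abs(table(q) - 501 / 5) <= 1))
})

test_that("cohort tables round-trip and are validated", {
  co <- synth_influence_cohort(150, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  expect_identical(readLines(f, n = 1),
                   "patient_id,risk_y1,risk_y2,risk_y3,risk_y4,risk_y5,event_year")
  back <- read_cohort(f)
  expect_equal(back$risk_y3, co$risk_y3, tolerance = 1e-12)
  expect_equal(back$event_year, co$event_year)
  bad <- co
  bad$event_year[1] <- 7L
  expect_error(validate_cohort(bad), "event_year")
  bad2 <- co[setdiff(names(co), "risk_y2")]
  expect_error(validate_cohort(bad2), "risk_y2")
})

test_that("event detection follows the sensitivity cascade exactly", {
  # a single patient with an event in year 2 examined in years 2 and 5
  ev <- matrix(0, 1, 5)
  ev[1, 2] <- 1
  s <- matrix(c(0L, 1L, 0L, 0L, 1L), 1, 5)
  got <- riskscreen:::.n_actual(ev, s, 0.3, 0.8)
  expect_equal(got, 0.8 * 0.3^0.5 + 0.2 * 0.8 * 0.3^3.5, tolerance = 1e-12)
  expect_equal(got, naive_n_actual(ev, s, 0.3, 0.8), tolerance = 1e-12)
  # full screening with perfect sensitivity catches every event at delay 0.5
  ev5 <- diag(5)
  expect_equal(riskscreen:::.n_actual(ev5, full_schedule(5), 0.3, 1),
               5 * 0.3^0.5, tolerance = 1e-12)
})

test_that("cohort evaluation reports exams even when no events occurred", {
  co <- synth_influence_cohort(400, seed = 11)
  co$event_year <- NA_integer_
  ev <- evaluate_cohort(co, seed = 1, ra_runs = 2)
  expect_true(all(ev$table$detections == 0))
  expect_true(all(ev$table$exams > 0))
  expect_equal(ev$n_events, 0)
})

test_that("cohort evaluation achieves the target rate and stratifies quintiles", {
  co <- synth_influence_cohort(1200, seed = 21)
  ev <- evaluate_cohort(co, dp = 0.3, tdr_target = 0.9, sensitivity = 0.8,
                        seed = 4, ra_runs = 2)
  for (s in c("CA", "CAIR", "ISA")) {
    cal <- ev$strategies[[s]]$calibration
    expect_gte(cal$tdr_lo, 0.9)
    expect_equal(sum(ev$strategies[[s]]$detections_by_quintile),
                 ev$strategies[[s]]$detections, tolerance = 1e-9)
  }
  # risk-targeted strategies concentrate follow-ups in the top quintile
  fq <- ev$strategies[["CAIR"]]$followups_by_quintile
  expect_gt(fq[5], fq[1])
  # detections never exceed the full-screening benchmark
  expect_true(all(ev$table$detections <= ev$max_detections + 1e-9))
  # calibrating on observed events is supported
  ev2 <- evaluate_cohort(co, seed = 4, ra_runs = 1, calibrate_on = "events")
  expect_true(is.finite(ev2$table$saving[2]))
})
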