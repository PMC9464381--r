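test_that("curability follows the exponential decay closed form", {
  expect_equal(curability(0.3, 0), 1.0)
  expect_equal(curability(0.6, 0.5), 0.774597, tolerance = 1e-6)
  expect_equal(curability(0.1, 2.5), 0.0031623, tolerance = 1e-4)
  expect_error(curability(0.3, -1), "logic error")
  expect_error(curability(1.3, 1))
})

test_that("hand-traced single-patient accounting matches", {
  r <- matrix(0.02, 1, 5)
  s <- matrix(c(0L, 1L, 0L, 0L, 1L), 1, 5)
  d <- detection_summary(r, s, dp = 0.3)
  expect_equal(d$n_actual,
               0.02 * (0.3^1.5 + 0.3^0.5) + 0.02 * (0.3^2.5 + 0.3^1.5 + 0.3^0.5),
               tolerance = 1e-12)
  expect_equal(d$n_max, 0.1 * 0.3^0.5, tolerance = 1e-12)
  expect_equal(d$tdr_achieved, 0.53800, tolerance = 1e-5)
})

test_that("full screening attains tdr 1 and empty screening detects nothing", {
  r <- random_risk_fixture(seed = 11)
  for (sens in c(1, 0.8)) {
    for (dp in c(0.1, 0.6)) {
      d_full <- detection_summary(r, full_schedule(20), dp, sens)
      expect_equal(d_full$tdr_achieved, 1.0, tolerance = 1e-12)
    }
  }
  d_empty <- detection_summary(r, empty_schedule(20), dp = 0.3)
  expect_equal(d_empty$n_actual, 0)
  expect_equal(d_empty$tdr_achieved, 0)
})

test_that("with perfect sensitivity only the first subsequent exam counts", {
  r <- random_risk_fixture(seed = 3)
  s <- random_schedule_fixture(seed = 4)
  # first-exam-only oracle
  first_only <- 0
  for (pat in 1:20) for (occ in 1:5) {
    later <- which(s[pat, ] == 1)
    later <- later[later >= occ]
    if (length(later)) first_only <- first_only + r[pat, occ] * 0.3^(later[1] - occ + 0.5)
  }
  expect_equal(detection_summary(r, s, 0.3)$n_actual, first_only,
               tolerance = 1e-12)
})

test_that("vectorized accounting matches the naive triple loop", {
  for (seed in 1:8) {
    r <- random_risk_fixture(seed = seed)
    s <- random_schedule_fixture(seed = seed + 100, p = runif(1, 0.1, 0.9))
    dp <- runif(1, 0.05, 0.95)
    sens <- sample(c(1, runif(1, 0.5, 1)), 1)
    d <- detection_summary(r, s, dp, sens)
    expect_equal(d$n_actual, naive_n_actual(r, s, dp, sens), tolerance = 1e-12)
    expect_equal(d$n_max, naive_n_max(r, dp, sens), tolerance = 1e-12)
  }
})

test_that("adding an exam never decreases expected detections", {
  set.seed(9)
  for (case in 1:20) {
    r <- random_risk_fixture(seed = case + 30)
    s <- random_schedule_fixture(seed = case + 60, p = 0.3)
    base <- detection_summary(r, s, dp = 0.4, sensitivity = 0.8)$n_actual
    empty_slots <- which(s == 0)
    slot <- sample(empty_slots, 1)
    s2 <- s
    s2[slot] <- 1L
    grown <- detection_summary(r, s2, dp = 0.4, sensitivity = 0.8)$n_actual
    expect_gte(grown, base - 1e-12)
  }
})

test_that("n_max is schedule-independent and closed-form under sensitivity 1", {
  r <- random_risk_fixture(seed = 5)
  d1 <- detection_summary(r, random_schedule_fixture(seed = 6), dp = 0.3)
  d2 <- detection_summary(r, empty_schedule(20), dp = 0.3)
  expect_equal(d1$n_max, d2$n_max, tolerance = 1e-12)
  expect_equal(d1$n_max, sum(r) * 0.3^0.5, tolerance = 1e-12)
})
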