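cfg <- rest_config()

test_that("a 24 h window partitions into 96 intervals; membership is half-open", {
  ps <- theta_stream(rep(0, 60))
  g <- partition_day(ps, T0, T0 + 86400, cfg)
  expect_length(g$state, 96L)
  expect_equal(sum(g$n_accel), 60L)
  # record exactly on a boundary belongs to the interval it starts
  one <- theta_stream(0, start = T0 + 15 * 60)
  g1 <- partition_day(one, T0, T0 + 86400, cfg)
  expect_equal(g1$n_accel[1:3], c(0L, 1L, 0L))
  # empty stream: all intervals MISSING
  ge <- partition_day(theta_stream(numeric()), T0, T0 + 86400, cfg)
  expect_true(all(ge$state == "MISSING"))
  expect_length(ge$state, 96L)
})

test_that("analyzability needs no pairing, >=10 accel and >=2 ECG records", {
  expect_true(is_analyzable(15, 3, FALSE, cfg))
  expect_false(is_analyzable(9, 3, FALSE, cfg))
  expect_false(is_analyzable(15, 1, FALSE, cfg))
  expect_false(is_analyzable(15, 3, TRUE, cfg))
  # any nonzero pairing overlap poisons the interval
  ps <- theta_stream(rep(0, 30))
  ps$pairing <- data.frame(start = T0 + 14 * 60 + 59, end = T0 + 15 * 60 + 1)
  g <- partition_day(ps, T0, T0 + 86400, cfg)
  expect_equal(g$state[1:2], c("MISSING", "MISSING"))
})

test_that("minute rest rule is strict at 30 degrees", {
  expect_true(minute_is_rest(0, cfg))
  expect_true(minute_is_rest(29.99, cfg))
  expect_false(minute_is_rest(30, cfg))
  expect_false(minute_is_rest(90, cfg))
})

test_that("interval classification is strict at 70% of collected records", {
  # 11 rest of 15 (73.3%) -> REST; 10 of 15 (66.7%) -> ACTIVE
  expect_equal(classify_interval(15, 3, FALSE, 11, cfg), "REST")
  expect_equal(classify_interval(15, 3, FALSE, 10, cfg), "ACTIVE")
  # 14 of 20 records is exactly 70% -> ACTIVE (strict inequality)
  cfg20 <- rest_config(interval_minutes = 20)
  expect_equal(classify_interval(20, 4, FALSE, 14, cfg20), "ACTIVE")
  # denominator is collected records, not the nominal 15
  expect_equal(classify_interval(10, 3, FALSE, 8, cfg), "REST")   # 80% of 10
  # 10 rest of 14 collected records is 71.4% -> REST, although 10/15 < 70%
  expect_equal(classify_interval(14, 3, FALSE, 10, cfg), "REST")
  expect_equal(classify_interval(14, 3, FALSE, 9, cfg), "ACTIVE")
})

test_that("every interval gets exactly one state and thresholds are monotone", {
  set.seed(42)
  theta <- runif(1440, 0, 120)
  ps <- theta_stream(theta)
  g <- partition_day(ps, T0, T0 + 86400, cfg)
  expect_equal(sum(g$state == "REST") + sum(g$state == "ACTIVE") +
                 sum(g$state == "MISSING"), 96L)
  # raising the angle never loses rest minutes; raising the fraction never
  # gains REST intervals
  for (ang in c(10, 30, 50, 80)) {
    lo <- sum(minute_is_rest(theta, rest_config(rest_angle_deg = ang)))
    hi <- sum(minute_is_rest(theta, rest_config(rest_angle_deg = ang + 10)))
    expect_lte(lo, hi)
  }
  n_rest_iv <- function(fr) {
    sum(partition_day(ps, T0, T0 + 86400,
                      rest_config(rest_fraction = fr))$state == "REST")
  }
  fr <- c(0.3, 0.5, 0.7, 0.9)
  counts <- vapply(fr, n_rest_iv, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rest fraction ignores non-accel channels", {
  ps <- theta_stream(rep(c(0, 80), c(600, 840)))
  g_full <- partition_day(ps, T0, T0 + 86400, cfg)
  ps_nohr <- ps
  ps_nohr$hr <- ps$hr[ps$hr$timestamp < T0 + 600 * 60, , drop = FALSE]
  g_cut <- partition_day(ps_nohr, T0, T0 + 86400, cfg)
  expect_equal(g_full$rest_fraction, g_cut$rest_fraction)
})

test_that("day windows start at the configured boundary and tile the stream", {
  ps <- theta_stream(rep(0, 3 * 1440), start = as.POSIXct("2024-03-01 05:00:00", tz = "UTC"))
  dw <- day_windows(ps, cfg)
  expect_equal(format(dw$start[1], "%H:%M"), "12:00")
  expect_true(dw$start[1] <= min(ps$accel$timestamp))
  expect_true(dw$end[nrow(dw)] > max(ps$accel$timestamp))
  expect_equal(unique(diff(as.numeric(dw$start))), 86400)
  mid <- rest_config(day_boundary_clock_time = "00:00")
  expect_equal(format(day_windows(ps, mid)$start[1], "%H:%M"), "00:00")
})
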