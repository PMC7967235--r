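cfg <- rest_config()

test_that("z-scores standardize per-day series with sample SD", {
  expect_equal(zscore_series(c(10, 20, 30)), c(-1, 0, 1))
  expect_warning(z <- zscore_series(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  expect_warning(z1 <- zscore_series(7), "fewer than 2")
  expect_true(is.na(z1))
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.1, 10))
    z <- zscore_series(x)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
  # NA days pass through as NA and do not enter the moments
  z <- zscore_series(c(10, NA, 20, 30))
  expect_true(is.na(z[2]))
  expect_equal(z[-2], c(-1, 0, 1))
  # translation invariance: shifting all values leaves z unchanged
  x <- c(420, 435, 480, 510)
  expect_equal(zscore_series(x + 123), zscore_series(x))
})

test_that("composite rest score is the sum of absolute z components", {
  expect_equal(composite_rest(0, 0, 0), 0)
  expect_equal(composite_rest(1, -1, 2), 4)
  expect_equal(composite_rest(-0.5, 0.25, 0), 0.75)
  expect_true(is.na(composite_rest(1, NA, 0)))
  set.seed(5)
  q <- rnorm(50); s <- rnorm(50); d <- rnorm(50)
  comp <- composite_rest(q, s, d)
  expect_true(all(comp >= pmax(abs(q), abs(s), abs(d))))
})

test_that("ingestion rate follows the printed regimen-span definition", {
  mk <- function(patch_days, ing_times) {
    acc <- data.frame(
      timestamp = as.POSIXct("2024-03-01 10:00:00", tz = "UTC") +
        (patch_days - 1) * 86400,
      steps = 0, ax = 0, ay = 0, az = 1)
    patient_stream("p", acc,
                   ingestions = data.frame(timestamp = ing_times))
  }
  # doses on all 7 days of a 7-day span
  full <- mk(1:7, as.POSIXct("2024-03-01 09:00:00", tz = "UTC") + (0:6) * 86400)
  expect_equal(ingestion_rate(full)$rate, 1.0)
  # 5 dose days over days 1..10: 0.5
  half <- mk(1:10, as.POSIXct("2024-03-01 09:00:00", tz = "UTC") +
               c(0, 2, 4, 6, 9) * 86400)
  expect_equal(ingestion_rate(half)$rate, 0.5)
  # two events on one day count once
  dup <- mk(1:5, as.POSIXct(c("2024-03-01 09:00:00", "2024-03-01 21:00:00",
                              "2024-03-05 09:00:00"), tz = "UTC"))
  r <- ingestion_rate(dup)
  expect_equal(r$n_ingestion_days, 2L)
  expect_equal(r$rate, 2 / 5)
  # no ingestions: rate 0 with a warning
  expect_warning(r0 <- ingestion_rate(mk(1:7, as.POSIXct(character(), tz = "UTC"))),
                 "no ingestion")
  expect_equal(r0$rate, 0)
})

test_that("ingestion time z-scores use clock minutes from midnight", {
  acc <- data.frame(timestamp = as.POSIXct("2024-03-01 10:00:00", tz = "UTC") +
                      0:2 * 86400, steps = 0, ax = 0, ay = 0, az = 1)
  ps <- patient_stream("p", acc, ingestions = data.frame(
    timestamp = as.POSIXct(c("2024-03-01 08:00:00", "2024-03-02 09:00:00",
                             "2024-03-03 10:00:00"), tz = "UTC")))
  itz <- ingestion_time_z(ps)
  expect_equal(itz$ingestion_time_min, c(480, 540, 600))
  expect_equal(itz$ingestion_z, c(-1, 0, 1))
  # constant dosing time: all zero after the degenerate-SD rule
  ps2 <- patient_stream("p", acc, ingestions = data.frame(
    timestamp = as.POSIXct("2024-03-01 09:00:00", tz = "UTC") + 0:2 * 86400))
  expect_warning(itz2 <- ingestion_time_z(ps2), "constant")
  expect_equal(itz2$ingestion_z, c(0, 0, 0))
  # a +4 h day carries the largest |z|
  ps3 <- patient_stream("p", acc, ingestions = data.frame(
    timestamp = as.POSIXct(c("2024-03-01 09:00:00", "2024-03-02 13:00:00",
                             "2024-03-03 09:05:00"), tz = "UTC")))
  itz3 <- ingestion_time_z(ps3)
  expect_equal(which.max(abs(itz3$ingestion_z)), 2L)
})

test_that("outlier coincidences pair single-day outliers within the lag", {
  d0 <- as.Date("2024-03-01")
  comp <- data.frame(day = d0 + 0:29, composite_z = rep(0.5, 30))
  ing <- data.frame(day = d0 + 0:29, ingestion_z = rep(0.1, 30))
  expect_equal(nrow(outlier_coincidences(comp, ing, cfg)), 0L)
  # matched outliers on day 15
  comp$composite_z[15] <- 3
  ing$ingestion_z[15] <- -2.6
  hits <- outlier_coincidences(comp, ing, cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$rest_day, d0 + 14)
  expect_equal(hits$ingestion_day, d0 + 14)
  # |lag| of 2 days is not a coincidence at lag 1
  comp2 <- data.frame(day = d0 + 0:29, composite_z = rep(0.5, 30))
  ing2 <- data.frame(day = d0 + 0:29, ingestion_z = rep(0.1, 30))
  comp2$composite_z[10] <- 3
  ing2$ingestion_z[12] <- 2.7
  expect_equal(nrow(outlier_coincidences(comp2, ing2, cfg)), 0L)
  # symmetric in lag: +/- 1 day both match
  for (shift in c(-1, 1)) {
    ing3 <- data.frame(day = d0 + 0:29, ingestion_z = rep(0.1, 30))
    ing3$ingestion_z[10 + shift] <- 2.7
    expect_equal(nrow(outlier_coincidences(comp2, ing3, cfg)), 1L)
  }
  # a two-day excursion is not a single-day outlier under the strict rule
  comp3 <- data.frame(day = d0 + 0:29, composite_z = rep(0.5, 30))
  comp3$composite_z[15:16] <- 3
  ing4 <- data.frame(day = d0 + 0:29, ingestion_z = rep(0.1, 30))
  ing4$ingestion_z[15] <- 2.7
  expect_equal(nrow(outlier_coincidences(comp3, ing4, cfg)), 0L)
  lax <- rest_config(single_day_outliers = FALSE)
  expect_equal(nrow(outlier_coincidences(comp3, ing4, lax)), 2L)
})

test_that("analyze_patient assembles a consistent daily table", {
  sim <- simulate_patient(sim_config(n_days = 12, rng_seed = 33), "pt")
  a <- analyze_patient(sim$stream)
  d <- a$daily
  expect_true(all(diff(as.numeric(d$day)) == 1))
  ok <- !is.na(d$composite_z)
  expect_equal(d$composite_z[ok],
               abs(d$quality_z[ok]) + abs(d$start_z[ok]) + abs(d$duration_z[ok]))
  expect_true(all(d$composite_z[ok] >=
                    pmax(abs(d$quality_z[ok]), abs(d$start_z[ok]),
                         abs(d$duration_z[ok])) - 1e-12))
  # start_z is translation invariant: re-deriving from shifted starts matches
  z1 <- zscore_series(a$lrps$start_min)
  z2 <- zscore_series(a$lrps$start_min + 37)
  expect_equal(z1, z2)
  expect_equal(a$summary$ingestion_rate, ingestion_rate(sim$stream)$rate)
})
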