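cfg <- rest_config()

test_that("window count law: max(0, n - w + 1) contiguous, 13 for a full interval", {
  full <- theta_stream(rep(0, 15))
  expect_equal(nrow(rolling_windows(full$accel, T0, cfg)), 13L)
  three <- theta_stream(rep(0, 3))
  expect_equal(nrow(rolling_windows(three$accel, T0, cfg)), 1L)
  # 12 contiguous records of 15 slots -> 10 windows
  twelve <- theta_stream(rep(0, 12), start = T0 + 3 * 60)
  expect_equal(nrow(rolling_windows(twelve$accel, T0, cfg)), 10L)
  # a missing middle slot drops the windows that overlap it
  gap <- theta_stream(rep(0, 15))
  gap$accel <- gap$accel[-8, ]
  expect_equal(nrow(rolling_windows(gap$accel, T0, cfg)), 13L - 3L)
  expect_equal(nrow(rolling_windows(gap$accel[0, ], T0, cfg)), 0L)
})

test_that("canonical features reproduce hand-computed values", {
  expect_equal(feat_yz_circ_dev(feat_block(ay = 0, az = 1)), 0)
  expect_equal(feat_yz_circ_dev(feat_block(ay = 0, az = 0)), 1)
  # minutes with yz magnitudes 0.8, 1.0, 1.4 -> mean deviation 0.2
  b <- feat_block(ay = 0, az = c(0.8, 1, 1.4))
  expect_equal(feat_yz_circ_dev(b), 0.2, tolerance = 1e-12)
  expect_equal(feat_theta_mean(feat_block(theta = c(10, 20, 30))), 20)
  expect_equal(feat_theta_mean(feat_block(theta = 90)), 90)
  expect_equal(feat_accel_norm_mean(feat_block(ax = c(1, 0, 0), ay = c(0, 1, 0),
                                               az = c(0, 0, 1))), 1)
  expect_equal(feat_accel_norm_mean(feat_block(az = c(2, 1, 1))), 4 / 3)
  expect_equal(feat_ax_sd(feat_block(ax = 0.1)), 0)
  expect_equal(feat_ax_sd(feat_block(ax = c(-1, 0, 1))), sqrt(2 / 3))
  # SD homogeneity
  b2 <- feat_block(ax = c(0.3, -0.2, 0.5))
  expect_equal(feat_ax_sd(feat_block(ax = c(0.3, -0.2, 0.5) * 3)),
               3 * feat_ax_sd(b2))
})

test_that("yz features are rotation-invariant in the y-z plane", {
  set.seed(9)
  for (i in 1:20) {
    ay <- rnorm(3); az <- rnorm(3); ang <- runif(1, 0, 2 * pi)
    b <- feat_block(ax = rnorm(3), ay = ay, az = az)
    br <- b
    br$ay <- cos(ang) * ay - sin(ang) * az
    br$az <- sin(ang) * ay + cos(ang) * az
    expect_equal(feat_yz_circ_dev(br), feat_yz_circ_dev(b), tolerance = 1e-12)
    expect_equal(feat_accel_norm_mean(br), feat_accel_norm_mean(b),
                 tolerance = 1e-12)
  }
})

test_that("vectorized interval features agree with the registry functions", {
  set.seed(13)
  n <- 15
  ps <- theta_stream(runif(n, 0, 90))
  ps$accel$ax <- rnorm(n); ps$accel$ay <- rnorm(n); ps$accel$az <- rnorm(n)
  fast <- actirest:::interval_features(ps$accel, T0, cfg)
  reg <- feature_registry()
  canon <- reg[reg$canonical, ]
  wins <- rolling_windows(ps$accel, T0, cfg)
  slow <- evaluate_registry(ps, wins, canon)
  expect_equal(nrow(fast), 13L)
  expect_equal(unname(as.matrix(fast[, canon$name])), unname(slow),
               tolerance = 1e-12)
})

test_that("the registry holds 35 documented candidates incl. the 4 canonical", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 35L)
  expect_equal(sum(reg$canonical), 4L)
  expect_setequal(reg$name[reg$canonical],
                  c("yz_circ_dev_mean", "theta_mean", "accel_norm_mean", "ax_sd"))
  expect_false(anyDuplicated(reg$name) > 0)
  # every candidate is finite on a generic block
  b <- feat_block(ax = c(0.1, -0.3, 0.2), ay = c(0.9, 1, 0.8),
                  az = c(0.3, 0.1, 0.2), theta = c(5, 10, 3), steps = c(0, 2, 1))
  vals <- vapply(reg$fn, function(f) f(b), numeric(1))
  expect_true(all(is.finite(vals)))
})

test_that("feature agglomeration merges duplicates and keeps distinct features", {
  set.seed(101)
  base <- matrix(rnorm(200 * 4), ncol = 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
  dup <- base
  colnames(dup) <- paste0("dup", 1:4)
  m <- cbind(base, dup)
  sel <- select_features(list(m), k = 4)
  expect_setequal(sel, paste0("f", 1:4))
  # k equal to the registry size: identity selection
  expect_setequal(select_features(list(base), k = 4), colnames(base))
  # correlated pair collapses to one representative
  set.seed(102)
  cohort <- lapply(1:3, function(i) {
    x1 <- rnorm(300)
    cbind(g1 = x1, g2 = x1 + rnorm(300, sd = sqrt(1 - 0.99^2) / 0.99),
          g3 = rnorm(300), g4 = rnorm(300), g5 = rnorm(300))
  })
  sel2 <- select_features(cohort, k = 4)
  expect_length(sel2, 4L)
  expect_equal(sum(c("g1", "g2") %in% sel2), 1L)
  expect_true(all(c("g3", "g4", "g5") %in% sel2))
  # degenerate registries are rejected
  flat <- cbind(a = rep(1, 50), b = rnorm(50), c = rnorm(50))
  expect_error(select_features(list(flat), k = 3), "nonzero variance")
})
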