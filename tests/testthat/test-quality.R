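cfg <- rest_config()

test_that("min-max normalization maps ranges to [0,1] and handles degeneracy", {
  nz <- normalize_features(cbind(f = c(2, 4, 6)))
  expect_equal(unname(nz$points[, 1]), c(0, 0.5, 1))
  expect_warning(nz2 <- normalize_features(cbind(f = c(5, 5, 5))), "degenerate")
  expect_equal(unname(nz2$points[, 1]), c(0, 0, 0))
  # idempotence: normalizing already-normalized data changes nothing
  x <- cbind(a = c(0, 0.3, 1), b = c(0, 1, 0.2))
  expect_equal(normalize_features(normalize_features(x)$points)$points,
               normalize_features(x)$points)
})

test_that("k-means recovers well-separated blobs and designates RR by posture", {
  set.seed(7)
  n <- 50
  lo <- matrix(rnorm(4 * n, 0, 0.05), ncol = 4)
  hi <- matrix(rnorm(4 * n, 1, 0.05), ncol = 4)
  pts <- rbind(lo, hi)
  colnames(pts) <- c("yz_circ_dev_mean", "theta_mean", "accel_norm_mean", "ax_sd")
  model <- fit_clusters(pts, cfg)
  expect_true(all(abs(model$centers["RR", ] - 0) < 0.05))
  expect_true(all(abs(model$centers["DFR", ] - 1) < 0.05))
  # duplication leaves centroids unchanged; same seed is bit-identical
  model2 <- fit_clusters(rbind(pts, pts), cfg)
  expect_equal(model2$centers, model$centers, tolerance = 1e-12)
  expect_identical(fit_clusters(pts, cfg), fit_clusters(pts, cfg))
  # all-identical points cannot form two clusters
  flat <- matrix(0.5, nrow = 10, ncol = 4,
                 dimnames = list(NULL, colnames(pts)))
  expect_error(fit_clusters(flat, cfg), "single rest cluster")
})

test_that("RR points score 0 and DFR points score distance to the RR centroid", {
  model <- structure(
    list(centers = rbind(RR = rep(0, 4), DFR = rep(1, 4)),
         feature_names = paste0("f", 1:4)),
    class = "rest_cluster_model")
  expect_equal(rest_distance(rep(0, 4), model), 0)
  expect_equal(rest_distance(c(0.1, 0, 0.1, 0), model), 0)  # assigned RR
  expect_equal(rest_distance(rep(1, 4), model), 2)          # sqrt(4) to RR
  expect_equal(rest_distance(rep(0.5, 4), model), 0)        # tie goes to RR
  expect_error(rest_distance(rep(0, 3), model), "dimension")
})

test_that("interval sums rescale short intervals and LRP quality is their mean", {
  expect_equal(window_quality(rep(0, 13)), 0)
  expect_equal(window_quality(c(rep(0, 12), 2)), 2)
  expect_equal(window_quality(rep(0.5, 10)), 6.5)
  expect_true(is.na(window_quality(numeric())))
  expect_equal(lrp_quality(c(2, 4)), 3)
  expect_equal(lrp_quality(c(2, 4, 3)), 3)  # adding the mean leaves it fixed
  expect_true(is.na(lrp_quality(c(NA, NA))))
})

test_that("min-max normalization removes a global scale from homogeneous features", {
  # acceleration norm, ax SD and posture angle are homogeneous of degree one
  # (or independent) in the raw accelerations, so their normalized columns
  # are exactly scale-free; the y-z circular deviation is deliberately
  # anchored to the absolute 1-g circle and is exercised separately above
  sim <- simulate_patient(sim_config(n_days = 8, rng_seed = 21), "s")
  grids <- classify_intervals(sim$stream, cfg)
  lrps <- daily_lrps(grids, cfg)
  fw1 <- compute_feature_windows(sim$stream, grids, lrps, cfg)
  sc <- sim$stream
  sc$accel$ax <- 3 * sc$accel$ax
  sc$accel$ay <- 3 * sc$accel$ay
  sc$accel$az <- 3 * sc$accel$az
  fw2 <- compute_feature_windows(sc, grids, lrps, cfg)
  homog <- c("theta_mean", "accel_norm_mean", "ax_sd")
  n1 <- normalize_features(as.matrix(fw1[homog]))$points
  n2 <- normalize_features(as.matrix(fw2[homog]))$points
  expect_equal(n2, n1, tolerance = 1e-9)
})

test_that("restless nights score worse (higher) than matched quiet nights", {
  # the metric is relative to the patient's own cluster model, so the paired
  # comparison lives inside one stream: alternate quiet / restless nights
  worse <- 0L
  n_rep <- 25L
  restless_idx <- seq(2, 10, by = 2)
  for (r in seq_len(n_rep)) {
    sim <- simulate_patient(sim_config(
      n_days = 10, rng_seed = 1000 + r, missing_span_rate = 0,
      restless_nights = restless_idx), "p")
    a <- analyze_patient(sim$stream, check_eligibility = FALSE)
    q <- a$quality$daily
    is_restless <- q$day %in% (as.Date(sim$config$start_date) + restless_idx - 1)
    if (mean(q$lrp_quality[is_restless]) > mean(q$lrp_quality[!is_restless])) {
      worse <- worse + 1L
    }
  }
  expect_gte(worse, ceiling(0.95 * n_rep))
})
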