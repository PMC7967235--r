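cfg <- rest_config()

test_that("LCRP is the longest all-REST run, earliest on ties", {
  expect_equal(find_lcrp(c("R", "R", "R", "A", "R", "R")), c(1L, 3L))
  expect_equal(find_lcrp(c("R", "R", "A", "R", "R")), c(1L, 2L))
  expect_null(find_lcrp(c("A", "M", "A")))
  set.seed(11)
  for (i in 1:200) {
    st <- random_states(sample(1:50, 1))
    expect_equal(find_lcrp(st), oracle_lcrp(st))
  }
})

test_that("extension bridges all-missing gaps and applies the rescue rules", {
  # all-MISSING gap within reach: annex
  expect_equal(lrp_span(c("R","R","R","R","R","M","M","R","R")), c(1L, 9L))
  # one ACTIVE in the gap: annex only runs of >= 4 consecutive REST
  expect_equal(lrp_span(c("R","R","R","R","R","A","R","R","R","R")), c(1L, 10L))
  expect_equal(lrp_span(c("R","R","R","R","R","A","R","R","R")), c(1L, 5L))
  # two ACTIVE intervals block that end
  expect_equal(lrp_span(c("R","R","R","R","R","A","A","R","R","R","R")), c(1L, 5L))
  # gap longer than the 5-interval search window: not annexed
  expect_equal(lrp_span(c("R","R","R","R","R","M","M","M","M","M","M","R","R")),
               c(1L, 5L))
  # extension works leftward too, and annexation can chain
  expect_equal(lrp_span(c("R","R","R","R","M","R","R","R","R","R","M","R","R")),
               c(1L, 13L))
})

test_that("extension never shrinks, is idempotent, and respects closed ends", {
  set.seed(23)
  for (i in 1:500) {
    st <- random_states(sample(2:40, 1))
    lcrp <- find_lcrp(st)
    if (is.null(lcrp)) next
    rp <- extend_lrp(st, lcrp, cfg)
    expect_true(rp$span[1] <= lcrp[1] && rp$span[2] >= lcrp[2])
    # idempotence: treating the output span as the starting rest period
    # (its interior made REST, the outside untouched) annexes nothing more
    st2 <- st
    st2[rp$span[1]:rp$span[2]] <- "R"
    expect_equal(extend_lrp(st2, rp$span, cfg)$span, rp$span)
  }
})

test_that("annexation never crosses a gap holding two or more ACTIVE intervals", {
  set.seed(31)
  for (i in 1:10000) {
    st <- random_states(sample(3:30, 1))
    span <- lrp_span(st)
    if (is.null(span)) next
    lcrp <- find_lcrp(st)
    inside <- st[span[1]:span[2]]
    # between consecutive REST runs inside the span, gaps must obey the rules
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$values)) {
      if (r$values[k] %in% c("A", "M")) {
        gap <- inside[(ends[k] - r$lengths[k] + 1):ends[k]]
        n_act <- sum(gap == "A")
        expect_lte(n_act, 1L)
        expect_lte(length(gap), cfg$gap_search_intervals)
      }
    }
  }
})

test_that("pipeline LRP matches the run-table oracle on random sequences", {
  set.seed(47)
  for (i in 1:2000) {
    st <- random_states(sample(1:25, 1))
    expect_identical(lrp_span(st), oracle_lrp(st))
  }
})

test_that("two_active_blocks = FALSE only blocks three or more active", {
  lax <- rest_config(two_active_blocks = FALSE)
  st2 <- c("R","R","R","R","R","A","A","R","R","R","R")
  expect_equal(lrp_span(st2, lax), c(1L, 11L))
  st3 <- c("R","R","R","R","R","A","A","A","R","R","R","R")
  expect_equal(lrp_span(st3, lax), c(1L, 5L))
})

test_that("daily LRPs: one per day with rest, none otherwise, planted blocks recovered", {
  # all-MISSING day yields nothing; all-REST day spans the full window
  ps_rest <- theta_stream(rep(0, 1440))
  grids <- classify_intervals(ps_rest, cfg)
  lr <- daily_lrps(grids, cfg)
  expect_equal(nrow(lr), 1L)
  expect_equal(lr$duration_min, 1440)
  ps_empty <- theta_stream(rep(80, 1440))  # upright all day: ACTIVE, no rest
  expect_equal(nrow(daily_lrps(classify_intervals(ps_empty, cfg), cfg)), 0L)

  # 7 planted 8 h rest blocks are each recovered with overlap
  sim <- simulate_patient(sim_config(n_days = 7, missing_span_rate = 0,
                                     awakening_rate = 0, rng_seed = 5), "p")
  a_lr <- daily_lrps(classify_intervals(sim$stream, cfg), cfg)
  tr <- sim$truth$rest
  expect_equal(nrow(a_lr), 7L)
  for (i in seq_len(nrow(a_lr))) {
    k <- match(a_lr$day[i], tr$day)
    ov <- min(as.numeric(a_lr$lrp_end[i]), as.numeric(tr$rest_end[k])) -
      max(as.numeric(a_lr$lrp_start[i]), as.numeric(tr$rest_start[k]))
    expect_gt(ov, 0)
  }
})
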