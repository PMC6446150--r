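test_that("tracking ratio counts distinct log days over the inclusive span", {
  r <- tracking_ratio(c(0, 9))
  expect_equal(unlist(r), c(k = 2, n = 10, r = 0.2))
  expect_equal(tracking_ratio(5)$r, 1.0)       # single-day tracker
  expect_equal(tracking_ratio(5)$n, 1L)
  expect_equal(tracking_ratio(0:29)$r, 1.0)
  expect_equal(tracking_ratio(c(3, 3, 3, 8))$k, 2L) # duplicates collapse
  expect_null(tracking_ratio(integer(0)))
})

test_that("the adjusted ratio is the printed shrinkage formula", {
  prior <- list(r_mean = 0.5, strength = 10)
  expect_equal(adjusted_tracking_ratio(5, 10, prior), 0.5)
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:400, 1); k <- sample(0:n, 1); rm <- runif(1, 0.01, 0.99)
    expect_equal(adjusted_tracking_ratio(k, n, list(r_mean = rm, strength = 10)),
                 (k + 10 * rm) / (n + 10))
  }
  expect_error(adjusted_tracking_ratio(11, 10, prior), "k <= n")
  expect_error(adjusted_tracking_ratio(1, 0, prior), "at least 1")
})

test_that("shrinkage pulls toward the mean and vanishes with n", {
  set.seed(8)
  for (i in 1:100) {
    rm <- runif(1, 0.05, 0.95)
    n <- sample(2:200, 1)
    k <- sample(0:n, 1)
    r <- k / n
    adj <- adjusted_tracking_ratio(k, n, list(r_mean = rm, strength = 10))
    if (abs(r - rm) > 1e-12) {
      expect_true(adj > min(r, rm) && adj < max(r, rm))
    }
    # |adjusted - raw| shrinks when the same raw ratio is observed longer
    n2 <- n * 10; k2 <- k * 10
    adj2 <- adjusted_tracking_ratio(k2, n2, list(r_mean = rm, strength = 10))
    expect_lte(abs(adj2 - r), abs(adj - r) + 1e-12)
  }
  # fixed point and large-n limit
  expect_equal(adjusted_tracking_ratio(30, 100,
                                       list(r_mean = 0.3, strength = 10)), 0.3)
  big <- adjusted_tracking_ratio(7e5, 1e6, list(r_mean = 0.2, strength = 10))
  expect_lt(abs(big - 0.7), 1e-5)
})

test_that("mean-constrained MAP variant differs except at r_mean = 0.5", {
  p <- list(r_mean = 0.5, strength = 10)
  expect_equal(adjusted_tracking_ratio(5, 20, p),
               adjusted_tracking_ratio(5, 20, p, variant = "map_mean"))
  p2 <- list(r_mean = 0.3, strength = 10)
  expect_equal(adjusted_tracking_ratio(5, 20, p2, variant = "map_mean"),
               (5 + 12 * 0.3 - 1) / 30)
  expect_false(isTRUE(all.equal(adjusted_tracking_ratio(5, 20, p2),
                                adjusted_tracking_ratio(5, 20, p2, "map_mean"))))
})

test_that("steps per week divides by distinct Monday-start weeks", {
  # 2015-07-01 and 2015-07-11 fall in consecutive calendar weeks
  d <- day_offset(c("2015-07-01", "2015-07-11"))
  expect_equal(steps_per_week(d, c(7000, 7000)), 7000)
  # all logs within one calendar week
  d2 <- day_offset(c("2015-07-07", "2015-07-08", "2015-07-09"))
  expect_equal(steps_per_week(d2, c(1000, 1500, 1000)), 3500)
  expect_true(is.na(steps_per_week(integer(0), numeric(0))))
  expect_error(steps_per_week(d2, c(-1, 1, 1)), "negative")
  # span rule alternative
  expect_equal(steps_per_week(d, c(7000, 7000), week_rule = "span"),
               14000 / ceiling(11 / 7))
})

test_that("metrics eligibility needs two events at least 10 days apart", {
  expect_true(metrics_eligible(c(0, 10)))
  expect_false(metrics_eligible(c(0, 9)))
  expect_false(metrics_eligible(5))
  expect_false(metrics_eligible(integer(0)))
  expect_true(metrics_eligible(c(3, 5, 14)))
})

test_that("the prior is the unweighted mean ratio over trackers", {
  expect_equal(compute_prior(c(0.2, 0.8))$r_mean, 0.5)
  expect_equal(compute_prior(0.3)$r_mean, 0.3)
  expect_equal(compute_prior(c(0.2, NA, 0.8))$r_mean, 0.5)
  expect_error(compute_prior(numeric(0)), "cannot form a prior")
})

test_that("phone-source rows never reach the tracking metrics", {
  fx <- fixture_bundle()
  m <- tracking_metrics(fx$activity, fx$demographics)
  expect_false(m$ever_tracked_any[m$individual_id == 10])  # phone-only logger
  expect_true(all(is.na(m$steps_per_week[m$individual_id == 10])))
  # tracker metrics computed as hand-derived
  m9 <- m[m$individual_id == 9, ]
  expect_equal(m9$k, 2L); expect_equal(m9$n, 9L)
  expect_false(m9$metrics_eligible)
  m11 <- m[m$individual_id == 11, ]
  expect_true(m11$metrics_eligible)
  expect_equal(m11$steps_per_week, 3500)
  # ever_tracked_any is the disjunction of the per-activity flags
  flags <- m[, paste0("ever_tracked_", c("steps", "sleep", "weight", "food"))]
  expect_equal(m$ever_tracked_any, apply(flags, 1, any))
})

test_that("the empirical prior mean tracks the generating tracking rates", {
  cfg <- sim_config(n_individuals = 3000, seed = 23, tracker_adoption_prob = 0.3,
                    phone_steps_prob = 0)
  b <- simulate_cohort(cfg)
  m <- tracking_metrics(b$activity, b$demographics)
  prior <- attr(m, "prior")
  tracked <- !is.na(m$raw_ratio)
  # raw ratios estimate each tracker's daily Bernoulli rate; their mean must
  # sit near the mean generating rate of the adopting subpopulation
  truth <- merge(m[tracked, ], b$truth, by = "individual_id")
  expect_true(all(truth$tracker))
  se <- sd(truth$raw_ratio - truth$p) / sqrt(nrow(truth))
  expect_lt(abs(mean(truth$raw_ratio - truth$p)), max(3 * se, 0.02))
  expect_equal(prior$r_mean, mean(m$raw_ratio[tracked]))
})
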