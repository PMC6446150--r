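test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(female_fraction = 1.2), "probabilities")
  expect_error(sim_config(days_supply_choices = integer(0)), "non-empty")
  expect_error(sim_config(days_supply_choices = c(30, 90),
                          days_supply_probs = c(0.5, 0.2)), "sum to 1")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(adherence_beta = c(-1, 2)), "Beta shapes")
  expect_error(sim_config(condition_prevalences = c(gout = 0.1)), "unknown condition")
})

test_that("identical (config, seed) yields identical bundles", {
  cfg <- sim_config(n_individuals = 300, seed = 99)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$demographics, b2$demographics)
  expect_identical(b1$claims, b2$claims)
  expect_identical(b1$activity, b2$activity)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_cohort(sim_config(n_individuals = 300, seed = 100))
  expect_false(identical(b1$claims, b3$claims))
})

test_that("all tables reference known individuals and stay within the calendar", {
  cfg <- sim_config(n_individuals = 500, seed = 3)
  b <- simulate_cohort(cfg)
  cal <- cfg$calendar
  ids <- b$demographics$individual_id
  expect_true(all(b$claims$individual_id %in% ids))
  expect_true(all(b$diagnoses$individual_id %in% ids))
  expect_true(all(b$activity$individual_id %in% ids))
  dxd <- day_offset(b$diagnoses$service_date)
  expect_true(all(dxd >= cal$diagnosis_start & dxd < cal$diagnosis_end))
  fd <- day_offset(b$claims$fill_date)
  expect_true(all(fd >= cal$supply_start & fd < cal$analysis_end))
  ad <- day_offset(b$activity$log_date)
  expect_true(all(ad >= cal$analysis_start & ad < cal$analysis_end))
  expect_true(all(b$truth$a >= 0 & b$truth$a <= 1))
  expect_true(all(b$truth$p >= 0 & b$truth$p <= 1))
  expect_equal(nrow(b$truth), nrow(b$demographics))
})

test_that("empirical marginals match the configuration within 3 SE", {
  n <- 10000
  cfg <- sim_config(n_individuals = n, seed = 17)
  b <- simulate_cohort(cfg)
  # female fraction
  phat <- mean(b$demographics$sex == "F")
  expect_lt(abs(phat - cfg$female_fraction),
            3 * sqrt(cfg$female_fraction * (1 - cfg$female_fraction) / n))
  # condition prevalences, via ownership of claims for the condition
  for (cnd in names(cfg$condition_prevalences)) {
    q <- cfg$condition_prevalences[[cnd]]
    owners <- length(unique(b$claims$individual_id[b$claims$condition == cnd]))
    expect_lt(abs(owners / n - q), 3 * sqrt(q * (1 - q) / n))
  }
  # latent adherence propensity and tracking rate
  ab <- cfg$adherence_beta
  mu_a <- ab[1] / sum(ab)
  sd_a <- sqrt(ab[1] * ab[2] / (sum(ab)^2 * (sum(ab) + 1)))
  expect_lt(abs(mean(b$truth$a) - mu_a), 3 * sd_a / sqrt(n))
  tb <- cfg$tracking_rate_beta
  mu_p <- tb[1] / sum(tb)
  sd_p <- sqrt(tb[1] * tb[2] / (sum(tb)^2 * (sum(tb) + 1)))
  expect_lt(abs(mean(b$truth$p) - mu_p), 3 * sd_p / sqrt(n))
})

test_that("a null effect leaves tracker and adherent status independent", {
  cfg <- sim_config(n_individuals = 6000, seed = 29,
                    tracker_adherence_log_odds = 0, tracker_age_log_odds = 0)
  b <- simulate_cohort(cfg)
  t2 <- table(tracker = b$truth$tracker,
              adherent = b$truth$true_adherent)
  or <- (t2["TRUE", "TRUE"] * t2["FALSE", "FALSE"]) /
        (t2["TRUE", "FALSE"] * t2["FALSE", "TRUE"])
  se <- sqrt(sum(1 / t2))
  expect_lt(abs(log(or)), 3 * se)
})

test_that("the injected effect is recovered by a large-sample logistic fit", {
  beta <- log(1.5)
  cfg <- sim_config(n_individuals = 20000, seed = 37,
                    condition_prevalences = c(hypertension = 1),
                    n_classes_range = c(1L, 1L),
                    tracker_adherence_log_odds = beta,
                    coverage_gap_prob = 0, phone_steps_prob = 0)
  b <- simulate_cohort(cfg)
  ch <- build_cohort(b$demographics, b$diagnoses, b$claims, "hypertension")
  ad <- adherence_table(ch)
  m <- tracking_metrics(b$activity, b$demographics)
  fits <- run_model_suite(ad, m, b$demographics, methodologies = "fixed")
  row <- fits$fixed.overall$terms
  row <- row[row$term == "trackerTRUE", ]
  expect_lt(abs(row$beta - beta), 3 * row$se)
})

test_that("bundles round-trip losslessly through write and read", {
  cfg <- sim_config(n_individuals = 60, seed = 5)
  b <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  files <- write_bundle(b, dir)
  expect_setequal(basename(files),
                  c("demographics.csv", "diagnoses.csv", "claims.csv",
                    "activity.csv", "truth.json"))
  rb <- read_bundle(dir)
  expect_equal(rb$demographics, b$demographics)
  expect_equal(rb$diagnoses, b$diagnoses)
  expect_equal(rb$claims, b$claims)
  expect_equal(rb$activity, b$activity)
  expect_equal(rb$truth$individuals$a, b$truth$a)
  # claims rows equal the sum of per-individual fill counts
  expect_equal(nrow(rb$claims),
               sum(table(b$claims$individual_id)))
  expect_error(read_bundle(file.path(dir, "nope")), "missing")
})

test_that("an empty activity table writes a header-only CSV that reads back", {
  cfg <- sim_config(n_individuals = 30, seed = 8, tracker_adoption_prob = 1e-9,
                    phone_steps_prob = 0)
  expect_error(sim_config(tracker_adoption_prob = 0), "inside")
  b <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  lines <- readLines(file.path(dir, "activity.csv"))
  rb <- read_bundle(dir)
  expect_equal(nrow(rb$activity), nrow(b$activity))
  if (nrow(b$activity) == 0L) expect_length(lines, 1L)
})
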