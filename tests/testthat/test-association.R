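# expand a 2x2 table (exposed/unexposed x case/noncase) into rows
expand_2x2 <- function(a, b, c, d) {
  data.frame(y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
             x = rep(c(1, 1, 0, 0), c(a, b, c, d)))
}

test_that("a saturated logistic fit reproduces the cross-product odds ratio", {
  d <- expand_2x2(80, 20, 60, 40)
  f <- fit_logistic(d, "y", "x", covariates = character(0))
  or <- f$terms$or[f$terms$term == "x"]
  expect_equal(or, (80 * 40) / (20 * 60), tolerance = 1e-6)
  expect_true(f$converged)
  ci <- f$terms[f$terms$term == "x", c("ci_low", "ci_high")]
  expect_lt(ci$ci_low, or); expect_gt(ci$ci_high, or)
  set.seed(12)
  for (i in 1:20) {
    tb <- 5 + sample(0:60, 4, replace = TRUE)
    f2 <- fit_logistic(expand_2x2(tb[1], tb[2], tb[3], tb[4]), "y", "x",
                       covariates = character(0))
    expect_equal(f2$terms$or[f2$terms$term == "x"],
                 (tb[1] * tb[4]) / (tb[2] * tb[3]), tolerance = 1e-6)
  }
})

test_that("independent exposure gives OR 1 and a flat p value", {
  d <- expand_2x2(300, 300, 300, 300)
  f <- fit_logistic(d, "y", "x", covariates = character(0))
  row <- f$terms[f$terms$term == "x", ]
  expect_equal(row$or, 1.0, tolerance = 1e-8)
  expect_gt(row$p, 0.99)
})

test_that("degenerate model inputs are rejected or flagged", {
  d <- expand_2x2(50, 50, 50, 50)
  expect_error(fit_logistic(d, "y", "x", covariates = "age"), "not in data")
  expect_error(fit_logistic(d[d$y == 1, ], "y", "x", covariates = character(0)),
               "no cases or no non-cases")
  d$z <- 1
  expect_error(fit_logistic(d, "y", "z", covariates = character(0)),
               "constant exposure")
  # perfect separation -> reported, not silently trusted
  sep <- data.frame(y = rep(c(1, 0), each = 30), x = rep(c(1, 0), each = 30))
  fs <- fit_logistic(sep, "y", "x", covariates = character(0))
  expect_true(fs$separation)
  expect_false(fs$converged)
})

test_that("Wald CIs attain nominal coverage over replicates with known effect", {
  set.seed(202)
  beta <- log(2)
  hits <- 0L
  for (i in 1:200) {
    n <- 800
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-0.5 + beta * x))
    f <- fit_logistic(data.frame(y = y, x = x), "y", "x", covariates = character(0))
    row <- f$terms[f$terms$term == "x", ]
    if (row$ci_low <= exp(beta) && exp(beta) <= row$ci_high) hits <- hits + 1L
  }
  expect_gte(hits, 180L) # 90% of 200
  expect_lte(hits, 198L) # 99% of 200
})

test_that("rescaling age leaves exposure ORs untouched", {
  set.seed(33)
  n <- 2000
  age <- runif(n, 30, 90)
  x <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, plogis(-2 + 0.4 * x + 0.02 * age))
  d <- data.frame(y = y, x = x, age_years = age)
  f1 <- fit_logistic(d, "y", "x", covariates = "age_years", interaction = FALSE)
  d2 <- d; d2$age_years <- d$age_years * 10
  f2 <- fit_logistic(d2, "y", "x", covariates = "age_years", interaction = FALSE)
  expect_equal(f1$terms$or[f1$terms$term == "x"],
               f2$terms$or[f2$terms$term == "x"], tolerance = 1e-6)
  expect_equal(f1$terms$beta[f1$terms$term == "age_years"],
               10 * f2$terms$beta[f2$terms$term == "age_years"], tolerance = 1e-6)
})

test_that("scaled ORs exponentiate beta times delta", {
  d <- data.frame(y = rbinom(500, 1, 0.5), r = runif(500))
  f <- fit_logistic(d, "y", "r", covariates = character(0))
  b <- f$terms$beta[f$terms$term == "r"]
  s <- scaled_or(f, "r", 0.5)
  expect_equal(s$or, exp(b * 0.5))
  expect_equal(s$ci_low, exp((b - 1.96 * f$terms$se[f$terms$term == "r"]) * 0.5))
  expect_error(scaled_or(f, "r", 0), "positive")
  expect_error(scaled_or(f, "nope", 1), "not present")
  # beta = ln(1.2) per unit scaled to half a unit
  fake <- f; fake$terms$beta[fake$terms$term == "r"] <- log(1.2)
  expect_equal(scaled_or(fake, "r", 0.5)$or, 1.2^0.5)
})

test_that("Welch t test handles identical, symmetric and separated groups", {
  expect_equal(welch_t_test(c(1, 1, 1), c(1, 1, 1))$p, 1)
  a <- c(1.2, 3.4, 2.2, 5.0); b <- c(2.0, 2.5, 4.4)
  t1 <- welch_t_test(a, b); t2 <- welch_t_test(b, a)
  expect_equal(t1$t, -t2$t)
  expect_equal(t1$p, t2$p)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  set.seed(61)
  power_hits <- sum(vapply(1:100, function(i) {
    welch_t_test(rnorm(1000, 0, 1), rnorm(1000, 1, 1))$p < 0.001
  }, logical(1)))
  expect_gte(power_hits, 99L)
})

test_that("the model suite emits the full inventory and skips empty scopes", {
  cfg <- sim_config(n_individuals = 2500, seed = 42, tracker_adoption_prob = 0.25)
  res <- run_pipeline(pipeline_config(sim = cfg, verbose = FALSE))
  per_m <- table(sub("\\..*", "", names(res$fits)))
  # 1 overall + 3 conditions + 4 activities + 3 metric models per methodology
  expect_equal(as.vector(per_m[c("fixed", "variable")]), c(11L, 11L))
  # removing all food logs drops exactly the food-activity model
  b <- res$bundle
  b$activity <- b$activity[b$activity$activity != "food", ]
  ad <- res$adherence
  m2 <- tracking_metrics(b$activity, b$demographics)
  expect_warning(
    fits2 <- run_model_suite(ad, m2, b$demographics, methodologies = "fixed"),
    "activity_food")
  expect_equal(length(fits2), 10L)
  expect_false("fixed.activity_food" %in% names(fits2))
})
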