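test_that("the pipeline runs all stages and writes auditable artifacts", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(sim = sim_config(n_individuals = 800, seed = 13),
                         output_dir = dir, verbose = FALSE)
  res <- run_pipeline(cfg)
  expect_s3_class(res, "pipeline_result")
  expect_true(all(file.exists(file.path(dir, c(
    "attrition.csv", "adherence.csv", "tracking_metrics.csv",
    "models.csv", "models.json", "manifest.json",
    "cohort_summary.csv", "adherence_summary.csv", "or_table.txt")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(man$rows$demographics, 800L)
  expect_equal(man$config$seed, 13L)
  # attrition accounting covers every individual for every condition
  expect_equal(nrow(res$attrition), 800L * 3L)
})

test_that("rerunning with the same seed reproduces the report", {
  cfg <- pipeline_config(sim = sim_config(n_individuals = 400, seed = 21),
                         verbose = FALSE)
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_equal(r1$report$adherence_summary, r2$report$adherence_summary)
  expect_equal(r1$models, r2$models)
})

test_that("a missing input file aborts naming the file and stage", {
  dir <- withr::local_tempdir()
  b <- simulate_cohort(sim_config(n_individuals = 20, seed = 2))
  write_bundle(b, dir)
  file.remove(file.path(dir, "claims.csv"))
  cfg <- pipeline_config(sim = NULL, input_dir = dir, verbose = FALSE)
  expect_error(run_pipeline(cfg), "claims.csv")
  expect_error(run_pipeline(cfg), "input")
})

test_that("summary tables are internally consistent", {
  res <- run_pipeline(pipeline_config(
    sim = sim_config(n_individuals = 1500, seed = 55, tracker_adoption_prob = 0.2),
    verbose = FALSE))
  cs <- res$report$cohort_summary
  ts <- res$report$tracker_summary
  # sex partitions each cohort
  expect_equal(cs$n_female + cs$n_male, cs$n_fixed)
  expect_equal(cs$pct_female + cs$pct_male, rep(100, nrow(cs)))
  # variable-methodology n never exceeds fixed-methodology n
  expect_true(all(cs$n_variable <= cs$n_fixed))
  # tracker-subset n equals cohort members flagged ever-tracked
  for (cnd in cs$condition) {
    expect_equal(ts$n_fixed[ts$condition == cnd],
                 cs$n_fixed[cs$condition == cnd] -
                   cs$track_none[cs$condition == cnd])
  }
  # self-overlap equals the cohort size
  for (cnd in cs$condition) {
    expect_equal(cs[[paste0("overlap_", cnd)]][cs$condition == cnd],
                 cs$n_fixed[cs$condition == cnd])
  }
  # adherence summary percentages against their stated denominators
  as_ <- res$report$adherence_summary
  expect_equal(as_$fixed_adherent_pct,
               100 * as_$fixed_adherent_n / as_$fixed_n)
  expect_equal(as_$variable_adherent_pct,
               100 * as_$variable_adherent_n / as_$variable_n)
})

test_that("rendered tables include formatted text with the stated precision", {
  dir <- withr::local_tempdir()
  res <- run_pipeline(pipeline_config(sim = sim_config(n_individuals = 300, seed = 9),
                                      verbose = FALSE))
  files <- render_tables(res$report, dir)
  expect_true(any(grepl("adherence_summary.txt", files)))
  txt <- readLines(file.path(dir, "adherence_summary.txt"))
  expect_true(any(grepl("0\\.\\d{3}", txt)))  # PDC at 3 decimals
  expect_error(render_tables(res$report, dir, format = "pdf"), "unknown format")
})

test_that("an empty tracker subset yields a zero-row table, not a failure", {
  fx <- fixture_bundle()
  fx$activity <- fx$activity[0, ]
  dir <- withr::local_tempdir()
  write_bundle(structure(list(demographics = fx$demographics,
                              diagnoses = fx$diagnoses, claims = fx$claims,
                              activity = fx$activity, truth = data.frame(),
                              config = sim_config(n_individuals = 12)),
                         class = "synthetic_bundle"), dir)
  res <- run_pipeline(pipeline_config(sim = NULL, input_dir = dir,
                                      conditions = "hypertension",
                                      verbose = FALSE))
  expect_equal(nrow(res$report$tracker_summary), 0L)
  out <- withr::local_tempdir()
  files <- render_tables(res$report, out)
  txt <- readLines(file.path(out, "tracker_summary.txt"))
  expect_true(any(grepl("no rows", txt)))
})
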