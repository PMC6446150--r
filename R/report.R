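#' Pipeline run configuration
#'
#' Bundles everything [run_pipeline()] needs: either a [sim_config()] to
#' simulate inputs inline or a directory of input CSVs, the study calendar,
#' and the methodology toggles (fixed denominator override, refill overlap
#' policy, week-counting rule, interaction variant).
#'
#' @param sim A [sim_config()] for inline simulation, or NULL.
#' @param input_dir Directory with input CSVs (used when `sim` is NULL).
#' @param output_dir Where stage artifacts are written; NULL disables writing.
#' @param calendar A [study_calendar()].
#' @param conditions Condition cohorts to build.
#' @param denominator Fixed-PDC denominator override (e.g. 365); NULL uses the
#'   analysis-window length (366 by default).
#' @param overlap Refill overlap policy, `"stockpile"` or `"union"`.
#' @param week_rule Steps-per-week rule, `"calendar"` or `"span"`.
#' @param interaction Include the age x sex product term in the models.
#' @param verbose Emit per-stage log messages with row counts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            output_dir = NULL, calendar = study_calendar(),
                            conditions = names(condition_code_map()),
                            denominator = NULL, overlap = "stockpile",
                            week_rule = "calendar", interaction = TRUE,
                            verbose = TRUE) {
  if (is.null(sim) && is.null(input_dir)) {
    stop("either a simulation config or an input directory is required")
  }
  structure(list(sim = sim, input_dir = input_dir, output_dir = output_dir,
                 calendar = calendar, conditions = conditions,
                 denominator = denominator, overlap = overlap,
                 week_rule = week_rule, interaction = interaction,
                 verbose = verbose),
            class = "pipeline_config")
}

stage_log <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Sequences the whole workflow: simulate (or read) the input tables, build
#' the per-condition cohorts, compute adherence under both PDC methodologies,
#' compute tracking metrics, fit the association model suite, and assemble the
#' summary tables. Each stage's artifact is written as CSV under
#' `output_dir` (when set) together with a JSON run manifest recording the
#' configuration, seed and per-stage row counts, so inclusion attrition is
#' auditable. Deterministic given (inputs, config, seed).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `bundle`, `cohorts` (per
#'   condition), `attrition`, `adherence`, `metrics`, `fits`, `models`,
#'   `report` (see [report_tables()]), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cal <- config$calendar
  v <- config$verbose
  manifest <- list(config = list(
    conditions = config$conditions,
    denominator = if (is.null(config$denominator)) cal$analysis_end - cal$analysis_start
                  else config$denominator,
    overlap = config$overlap, week_rule = config$week_rule,
    interaction = config$interaction,
    seed = if (!is.null(config$sim)) config$sim$seed else NA))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  bundle <- run_stage("input", {
    if (!is.null(config$sim)) simulate_cohort(config$sim)
    else read_bundle(config$input_dir)
  })
  stage_log(v, "input: %d individuals, %d claims, %d diagnoses, %d activity rows",
            nrow(bundle$demographics), nrow(bundle$claims),
            nrow(bundle$diagnoses), nrow(bundle$activity))
  manifest$rows <- list(demographics = nrow(bundle$demographics),
                        claims = nrow(bundle$claims),
                        diagnoses = nrow(bundle$diagnoses),
                        activity = nrow(bundle$activity))

  cohorts <- list(); attrition <- list(); adherence <- list()
  for (cnd in config$conditions) {
    ch <- run_stage(paste0("cohort:", cnd), build_cohort(
      bundle$demographics, bundle$diagnoses, bundle$claims, cnd,
      calendar = cal))
    cohorts[[cnd]] <- ch
    attrition[[cnd]] <- ch$attrition
    stage_log(v, "cohort %s: %d of %d included (coverage %d, diagnosis %d, fills %d pass)",
              cnd, sum(ch$attrition$included), nrow(ch$attrition),
              sum(ch$attrition$coverage_ok), sum(ch$attrition$diagnosis_ok),
              sum(ch$attrition$fill_ok))
    adherence[[cnd]] <- run_stage(paste0("adherence:", cnd), adherence_table(
      ch, calendar = cal, denominator = config$denominator,
      overlap = config$overlap))
  }
  attrition <- do.call(rbind, c(attrition, list(make.row.names = FALSE)))
  adherence <- do.call(rbind, c(adherence, list(make.row.names = FALSE)))
  manifest$cohorts <- lapply(cohorts, function(ch) list(
    n_included = sum(ch$attrition$included),
    n_screened = nrow(ch$attrition)))
  stage_log(v, "adherence: %d (individual, condition) rows, %d variable-eligible",
            nrow(adherence), sum(!is.na(adherence$variable_pdc)))

  metrics <- run_stage("tracking", tracking_metrics(
    bundle$activity, bundle$demographics, calendar = cal,
    week_rule = config$week_rule))
  stage_log(v, "tracking: %d trackers, %d metrics-eligible",
            sum(metrics$ever_tracked_any), sum(metrics$metrics_eligible))
  manifest$tracking <- list(n_trackers = sum(metrics$ever_tracked_any),
                            n_metrics_eligible = sum(metrics$metrics_eligible))

  fits <- run_stage("association", withCallingHandlers(
    run_model_suite(adherence, metrics, bundle$demographics,
                    interaction = config$interaction),
    warning = function(w) {
      stage_log(v, "association: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  models <- models_table(fits)
  stage_log(v, "association: %d models fitted", length(fits))
  manifest$models <- names(fits)

  report <- run_stage("report", report_tables(adherence, metrics,
                                              bundle$demographics, cohorts, fits))

  result <- structure(list(bundle = bundle, cohorts = cohorts,
                           attrition = attrition, adherence = adherence,
                           metrics = metrics, fits = fits, models = models,
                           report = report, manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    if (!is.null(config$sim)) write_bundle(bundle, file.path(out, "bundle"))
    utils::write.csv(attrition, file.path(out, "attrition.csv"), row.names = FALSE)
    utils::write.csv(adherence, file.path(out, "adherence.csv"), row.names = FALSE)
    utils::write.csv(metrics, file.path(out, "tracking_metrics.csv"), row.names = FALSE)
    utils::write.csv(models, file.path(out, "models.csv"), row.names = FALSE)
    jsonlite::write_json(lapply(fits, function(f) {
      list(scope = f$scope, n = f$n, converged = f$converged, terms = f$terms)
    }), file.path(out, "models.json"), auto_unbox = TRUE, digits = NA)
    render_tables(report, out)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Assemble the summary tables of a run
#'
#' Builds the report structures: per-condition participant characteristics
#' (cohort sizes under each methodology, age, sex, condition overlap, digital
#' tracking activity), the same restricted to individuals with tracker data,
#' the adherence summary (mean/SD PDC and percent adherent per condition and
#' methodology), the age-group and sex adherence summary with Welch t tests,
#' and the odds-ratio table including the rescaled metric effects (per 0.5
#' adjusted-ratio units and per 2000 steps per day tracked).
#'
#' @param adherence,metrics,demographics,cohorts,fits Pipeline stage outputs.
#' @return List of class `report_bundle` with data.frames `cohort_summary`,
#'   `tracker_summary`, `adherence_summary`, `age_sex_summary`,
#'   `age_sex_tests`, `or_table`, `scaled_effects`.
#' @export
report_tables <- function(adherence, metrics, demographics, cohorts, fits) {
  conds <- names(cohorts)
  rows <- merge(adherence,
                demographics[, c("individual_id", "age_years", "sex")],
                by = "individual_id")
  rows <- merge(rows, metrics, by = "individual_id", all.x = TRUE)
  rows$tracker <- !is.na(rows$ever_tracked_any) & rows$ever_tracked_any

  characterize <- function(r) {
    do.call(rbind, lapply(split(r, r$condition)[unique(r$condition)], function(g) {
      out <- data.frame(
        condition = g$condition[1],
        n_fixed = nrow(g),
        n_variable = sum(!is.na(g$variable_pdc)),
        age_mean = mean(g$age_years), age_sd = stats::sd(g$age_years),
        n_female = sum(g$sex == "F"), n_male = sum(g$sex == "M"),
        pct_female = 100 * mean(g$sex == "F"),
        pct_male = 100 * mean(g$sex == "M"))
      for (other in conds) {
        ids_other <- unique(r$individual_id[r$condition == other])
        out[[paste0("overlap_", other)]] <- sum(g$individual_id %in% ids_other)
      }
      out$track_none <- sum(!g$tracker)
      for (tp in ACTIVITIES) {
        cn <- paste0("ever_tracked_", tp)
        out[[paste0("track_", tp)]] <- sum(!is.na(g[[cn]]) & g[[cn]])
      }
      out
    }))
  }
  cohort_summary <- characterize(rows)
  tr <- rows[rows$tracker, , drop = FALSE]
  tracker_summary <- if (nrow(tr)) characterize(tr) else
    cohort_summary[0, , drop = FALSE]

  adherence_summary <- do.call(rbind, lapply(
    split(rows, rows$condition)[unique(rows$condition)], function(g) {
      vv <- g$variable_pdc[!is.na(g$variable_pdc)]
      va <- g$variable_adherent[!is.na(g$variable_adherent)]
      data.frame(
        condition = g$condition[1],
        fixed_n = nrow(g),
        fixed_pdc_mean = mean(g$fixed_pdc), fixed_pdc_sd = stats::sd(g$fixed_pdc),
        fixed_adherent_n = sum(g$fixed_adherent),
        fixed_adherent_pct = 100 * mean(g$fixed_adherent),
        variable_n = length(vv),
        variable_pdc_mean = if (length(vv)) mean(vv) else NA_real_,
        variable_pdc_sd = if (length(vv) > 1) stats::sd(vv) else NA_real_,
        variable_adherent_n = sum(va),
        variable_adherent_pct = if (length(va)) 100 * mean(va) else NA_real_)
    }))
  rownames(adherence_summary) <- NULL

  rows$age_group <- ifelse(rows$age_years < 50, "<50", ">=50")
  grp_summary <- function(g, label) {
    vv <- g$variable_pdc[!is.na(g$variable_pdc)]
    va <- g$variable_adherent[!is.na(g$variable_adherent)]
    data.frame(group = label, n = nrow(g),
               fixed_pdc_mean = mean(g$fixed_pdc), fixed_pdc_sd = stats::sd(g$fixed_pdc),
               fixed_adherent_pct = 100 * mean(g$fixed_adherent),
               variable_pdc_mean = if (length(vv)) mean(vv) else NA_real_,
               variable_pdc_sd = if (length(vv) > 1) stats::sd(vv) else NA_real_,
               variable_adherent_pct = if (length(va)) 100 * mean(va) else NA_real_)
  }
  age_sex_summary <- rbind(
    grp_summary(rows[rows$age_group == "<50", ], "age<50"),
    grp_summary(rows[rows$age_group == ">=50", ], "age>=50"),
    grp_summary(rows[rows$sex == "F", ], "female"),
    grp_summary(rows[rows$sex == "M", ], "male"))

  safe_t <- function(a, b) {
    tryCatch(welch_t_test(a, b), error = function(e) list(t = NA, df = NA, p = NA))
  }
  age_sex_tests <- rbind(
    data.frame(contrast = "age<50 vs age>=50", methodology = "fixed",
               t = safe_t(rows$fixed_pdc[rows$age_group == "<50"],
                          rows$fixed_pdc[rows$age_group == ">=50"])$t,
               p = safe_t(rows$fixed_pdc[rows$age_group == "<50"],
                          rows$fixed_pdc[rows$age_group == ">=50"])$p),
    data.frame(contrast = "age<50 vs age>=50", methodology = "variable",
               t = safe_t(rows$variable_pdc[rows$age_group == "<50"],
                          rows$variable_pdc[rows$age_group == ">=50"])$t,
               p = safe_t(rows$variable_pdc[rows$age_group == "<50"],
                          rows$variable_pdc[rows$age_group == ">=50"])$p),
    data.frame(contrast = "female vs male", methodology = "fixed",
               t = safe_t(rows$fixed_pdc[rows$sex == "F"],
                          rows$fixed_pdc[rows$sex == "M"])$t,
               p = safe_t(rows$fixed_pdc[rows$sex == "F"],
                          rows$fixed_pdc[rows$sex == "M"])$p),
    data.frame(contrast = "female vs male", methodology = "variable",
               t = safe_t(rows$variable_pdc[rows$sex == "F"],
                          rows$variable_pdc[rows$sex == "M"])$t,
               p = safe_t(rows$variable_pdc[rows$sex == "F"],
                          rows$variable_pdc[rows$sex == "M"])$p))

  or_table <- models_table(fits)
  exposure_terms <- c("trackerTRUE", "tracker",
                      paste0("ever_tracked_", ACTIVITIES, "TRUE"),
                      paste0("ever_tracked_", ACTIVITIES),
                      "adjusted_ratio", "steps_per_day_k")
  or_table <- or_table[or_table$term %in% exposure_terms, , drop = FALSE]

  scaled <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if ("adjusted_ratio" %in% f$terms$term) {
      s <- scaled_or(f, "adjusted_ratio", 0.5)
      scaled[[length(scaled) + 1L]] <- data.frame(
        model = nm, term = "adjusted_ratio", delta = "0.5 ratio units",
        or = s$or, ci_low = s$ci_low, ci_high = s$ci_high, p = s$p)
    }
    if ("steps_per_day_k" %in% f$terms$term) {
      s <- scaled_or(f, "steps_per_day_k", 2)  # 2 x 1000 steps/day
      scaled[[length(scaled) + 1L]] <- data.frame(
        model = nm, term = "steps_per_day", delta = "2000 steps",
        or = s$or, ci_low = s$ci_low, ci_high = s$ci_high, p = s$p)
    }
  }
  scaled_effects <- if (length(scaled)) do.call(rbind, scaled) else
    data.frame(model = character(0), term = character(0), delta = character(0),
               or = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               p = numeric(0))

  structure(list(cohort_summary = cohort_summary,
                 tracker_summary = tracker_summary,
                 adherence_summary = adherence_summary,
                 age_sex_summary = age_sex_summary,
                 age_sex_tests = age_sex_tests,
                 or_table = or_table,
                 scaled_effects = scaled_effects),
            class = "report_bundle")
}

#' Write report tables as CSV and plain text
#'
#' PDC values render to 3 decimals and percentages to 2 in the text output.
#' An empty tracker subset emits a zero-row table with a notice rather than
#' failing.
#'
#' @param report A [report_tables()] result.
#' @param directory Output directory.
#' @param format Any of `"csv"`, `"txt"`.
#' @return Invisibly, the files written.
#' @export
render_tables <- function(report, directory, format = c("csv", "txt")) {
  if (!all(format %in% c("csv", "txt"))) {
    stop("unknown format: ", paste(setdiff(format, c("csv", "txt")), collapse = ", "))
  }
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  written <- character(0)
  for (nm in names(report)) {
    tb <- report[[nm]]
    if ("csv" %in% format) {
      p <- file.path(directory, paste0(nm, ".csv"))
      utils::write.csv(tb, p, row.names = FALSE)
      written <- c(written, p)
    }
    if ("txt" %in% format) {
      p <- file.path(directory, paste0(nm, ".txt"))
      ft <- tb
      for (cn in names(ft)) {
        if (!is.numeric(ft[[cn]])) next
        if (grepl("pct", cn)) {
          ft[[cn]] <- sprintf("%.2f", ft[[cn]])
        } else if (grepl("_sd|pdc|ratio|^or$|ci_", cn)) {
          ft[[cn]] <- sprintf("%.3f", ft[[cn]])
        }
      }
      lines <- utils::capture.output(print(ft, row.names = FALSE))
      if (nrow(tb) == 0L) lines <- c(lines, sprintf("[no rows in %s]", nm))
      writeLines(lines, p)
      written <- c(written, p)
    }
  }
  invisible(written)
}
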