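#' Configuration for the synthetic claims/activity generator
#'
#' Defines the joint distribution of the simulated population. Each individual
#' carries a latent adherence propensity `a` ~ Beta(`adherence_beta`) shared
#' across all their drug classes (probability that a day of need is covered)
#' and, if they adopt a tracker, a daily tracking rate `p` ~
#' Beta(`tracking_rate_beta`). Tracker adoption is logistic in a baseline
#' (`tracker_adoption_prob`, the adoption probability of a nonadherent
#' 60-year-old), an injected effect `tracker_adherence_log_odds` on the
#' individual's *true* fixed-methodology adherent status, and an age slope
#' `tracker_age_log_odds` per year (younger individuals adopt more, affecting
#' the exposure only, never the outcome). Because the injection acts on the
#' adherent indicator itself, the injected log-odds equals the tracker <->
#' adherent conditional log odds ratio exactly, and is therefore recoverable
#' by the downstream logistic models.
#'
#' @param n_individuals Population size, >= 1.
#' @param seed Integer master seed; every individual derives an independent
#'   substream from `(seed, id)`.
#' @param condition_prevalences Named probabilities of carrying each condition
#'   (independent draws; overlap arises naturally).
#' @param age_mean,age_sd,age_min,age_max Age distribution (normal, truncated,
#'   rounded to integer years).
#' @param female_fraction Probability of sex `"F"`.
#' @param days_supply_choices,days_supply_probs Per-fill days-supply values
#'   and sampling probabilities.
#' @param adherence_beta `c(shape1, shape2)` of the adherence-propensity Beta.
#' @param tracking_rate_beta `c(shape1, shape2)` of the daily tracking-rate Beta.
#' @param steps_lognormal `c(meanlog, sdlog)` of daily tracked step counts.
#' @param tracker_adoption_prob Baseline adoption probability in (0, 1).
#' @param tracker_adherence_log_odds Injected adherent -> adoption log odds.
#' @param tracker_age_log_odds Adoption log-odds slope per year of age
#'   (centred at 60).
#' @param activity_ownership Named probabilities that a tracker owns each
#'   activity type (steps, sleep, weight, food); ownership of at least one
#'   type is forced.
#' @param phone_steps_prob Probability an individual (tracker or not) also has
#'   passive smartphone step rows, which the tracking metrics must ignore.
#' @param coverage_gap_prob Probability of insurance coverage ending before
#'   the study does (triggers the continuous-coverage exclusion).
#' @param first_fill_in_supply_prob Probability that a refill chain starts in
#'   the supply period (a prevalent user already on therapy at baseline)
#'   rather than at a uniform day of the analysis period (incident user).
#' @param n_classes_range `c(min, max)` drug classes filled per condition.
#' @param calendar A [study_calendar()].
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000,
                       seed = 1,
                       condition_prevalences = c(diabetes = 0.25,
                                                 dyslipidemia = 0.45,
                                                 hypertension = 0.60),
                       age_mean = 70, age_sd = 11, age_min = 21, age_max = 99,
                       female_fraction = 0.55,
                       days_supply_choices = c(30L, 90L),
                       days_supply_probs = c(0.7, 0.3),
                       adherence_beta = c(4, 1.5),
                       tracking_rate_beta = c(3, 2),
                       steps_lognormal = c(meanlog = log(7000), sdlog = 0.5),
                       tracker_adoption_prob = 0.10,
                       tracker_adherence_log_odds = log(1.33),
                       tracker_age_log_odds = -0.04,
                       activity_ownership = c(steps = 0.85, sleep = 0.55,
                                              weight = 0.20, food = 0.12),
                       phone_steps_prob = 0.05,
                       coverage_gap_prob = 0.03,
                       first_fill_in_supply_prob = 0.85,
                       n_classes_range = c(1L, 2L),
                       calendar = study_calendar()) {
  probs <- c(condition_prevalences, female_fraction, tracker_adoption_prob,
             days_supply_probs, activity_ownership, phone_steps_prob,
             coverage_gap_prob, first_fill_in_supply_prob)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stop("configuration error: all probabilities must lie in [0, 1]")
  }
  if (length(days_supply_choices) == 0L || any(days_supply_choices < 1)) {
    stop("configuration error: days_supply_choices must be non-empty positive integers")
  }
  if (length(days_supply_choices) != length(days_supply_probs) ||
      abs(sum(days_supply_probs) - 1) > 1e-8) {
    stop("configuration error: days_supply_probs must match choices and sum to 1")
  }
  if (n_individuals < 1) stop("configuration error: n_individuals must be >= 1")
  if (any(adherence_beta <= 0) || any(tracking_rate_beta <= 0)) {
    stop("configuration error: Beta shapes must be positive")
  }
  if (tracker_adoption_prob <= 0 || tracker_adoption_prob >= 1) {
    stop("configuration error: tracker_adoption_prob must be inside (0, 1)")
  }
  bad_cond <- setdiff(names(condition_prevalences), names(condition_code_map()))
  if (length(bad_cond)) stop("unknown condition(s): ", paste(bad_cond, collapse = ", "))
  cfg <- list(n_individuals = as.integer(n_individuals), seed = as.integer(seed),
              condition_prevalences = condition_prevalences,
              age_mean = age_mean, age_sd = age_sd,
              age_min = age_min, age_max = age_max,
              female_fraction = female_fraction,
              days_supply_choices = as.integer(days_supply_choices),
              days_supply_probs = days_supply_probs,
              adherence_beta = adherence_beta,
              tracking_rate_beta = tracking_rate_beta,
              steps_lognormal = steps_lognormal,
              tracker_adoption_prob = tracker_adoption_prob,
              tracker_adherence_log_odds = tracker_adherence_log_odds,
              tracker_age_log_odds = tracker_age_log_odds,
              activity_ownership = activity_ownership,
              phone_steps_prob = phone_steps_prob,
              coverage_gap_prob = coverage_gap_prob,
              first_fill_in_supply_prob = first_fill_in_supply_prob,
              n_classes_range = as.integer(n_classes_range),
              calendar = calendar)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-individual substream seed below 2^31
individual_seed <- function(seed, id) {
  as.integer((as.double(seed) * 69069 + as.double(id) * 1013904223) %% 2147483647)
}

# small per-condition diagnosis-code pools (family-correct, not frequency-realistic)
DX_POOLS <- list(
  diabetes = list(icd9 = c("250.00", "250.01", "250.50", "250.60"),
                  icd10 = c("E11.9", "E11.65", "E10.9", "E08.9")),
  dyslipidemia = list(icd9 = c("272.0", "272.2", "272.4"),
                      icd10 = c("E78.0", "E78.2", "E78.4", "E78.5")),
  hypertension = list(icd9 = c("401.1", "401.9", "403.90", "405.99"),
                      icd10 = c("I10", "I11.9", "I12.9", "I15.0"))
)

# refill chain for one drug class: prevalent users (the default) start at a
# uniform day of the supply period, incident users at a uniform day of the
# analysis period; each next fill lands at previous-supply exhaustion plus a
# geometric gap with mean (1/a - 1) * days_supply, truncated at the analysis
# end. Because gaps are nonnegative the chain's coverage intervals are
# disjoint by construction.
refill_chain <- function(a, cfg, cal, max_fills = 80L) {
  days <- integer(0); supplies <- integer(0)
  day <- if (stats::runif(1) < cfg$first_fill_in_supply_prob) {
    cal$supply_start + sample.int(cal$supply_end - cal$supply_start, 1L) - 1L
  } else {
    cal$analysis_start + sample.int(cal$analysis_end - cal$analysis_start, 1L) - 1L
  }
  while (day < cal$analysis_end && length(days) < max_fills) {
    supply <- cfg$days_supply_choices[
      sample.int(length(cfg$days_supply_choices), 1L, prob = cfg$days_supply_probs)]
    days <- c(days, day); supplies <- c(supplies, supply)
    mean_gap <- (1 / a - 1) * supply
    gap <- if (mean_gap <= 0) 0L else stats::rgeom(1L, 1 / (1 + mean_gap))
    day <- day + supply + gap
  }
  list(day = days, supply = supplies)
}

# exact covered days of a gap-chain within [ws, we): intervals are disjoint
chain_covered <- function(day, supply, ws, we) {
  sum(pmax(0, pmin(day + supply, we) - pmax(day, ws)))
}

#' Generate a linked synthetic study population
#'
#' Simulates demographics, diagnosis histories, pharmacy refill chains and
#' daily activity logs with the dependence structure the analysis assumes,
#' together with the generation-time ground truth needed for
#' parameter-recovery tests. Fully reproducible: every individual consumes an
#' independent RNG substream derived from `(seed, id)`, so the output is
#' byte-identical across runs of the same configuration.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_bundle` with data.frames `demographics`,
#'   `diagnoses`, `claims`, `activity` (ISO dates throughout, matching the
#'   CSV schemas) and `truth`: per-individual `a` (adherence propensity), `p`
#'   (daily tracking rate), `tracker`, `true_fixed_pdc` (mean of the
#'   by-construction class-level fixed PDCs), `true_adherent`, plus attributes
#'   `injected_log_odds` and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cal <- cfg$calendar
  n <- cfg$n_individuals
  cmap <- condition_code_map()
  conds <- names(cfg$condition_prevalences)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  analysis_len <- cal$analysis_end - cal$analysis_start
  dx_len <- cal$diagnosis_end - cal$diagnosis_start

  # flat accumulators (per-individual data.frames are far too slow at scale)
  d_age <- integer(n); d_sex <- character(n)
  d_cov_start <- integer(n); d_cov_end <- integer(n)
  x_id <- vector("list", n); x_day <- vector("list", n)
  x_ver <- vector("list", n); x_code <- vector("list", n)
  c_id <- vector("list", n); c_day <- vector("list", n); c_sup <- vector("list", n)
  c_cls <- vector("list", n); c_cnd <- vector("list", n)
  a_id <- vector("list", n); a_day <- vector("list", n)
  a_act <- vector("list", n); a_val <- vector("list", n); a_src <- vector("list", n)
  t_a <- numeric(n); t_p <- numeric(n); t_tracker <- logical(n)
  t_pdc <- numeric(n); t_adh <- logical(n)

  for (i in seq_len(n)) {
    set.seed(individual_seed(cfg$seed, i))
    age <- round(min(max(stats::rnorm(1, cfg$age_mean, cfg$age_sd), cfg$age_min),
                     cfg$age_max))
    d_age[i] <- as.integer(age)
    d_sex[i] <- if (stats::runif(1) < cfg$female_fraction) "F" else "M"
    gap <- stats::runif(1) < cfg$coverage_gap_prob
    d_cov_start[i] <- cal$supply_start - 365L - sample.int(365L, 1L)
    d_cov_end[i] <- if (gap) {
      cal$analysis_start + sample.int(analysis_len - 60L, 1L) + 30L
    } else {
      cal$analysis_end + sample.int(90L, 1L) - 1L
    }
    has_cond <- stats::runif(length(conds)) < cfg$condition_prevalences
    a <- stats::rbeta(1, cfg$adherence_beta[1], cfg$adherence_beta[2])
    p <- stats::rbeta(1, cfg$tracking_rate_beta[1], cfg$tracking_rate_beta[2])
    t_a[i] <- a; t_p[i] <- p

    # diagnoses: 1-2 per owned condition inside the diagnosis window,
    # plus an occasional irrelevant wellness code
    dd <- integer(0); dv <- integer(0); dc <- character(0)
    for (cnd in conds[has_cond]) {
      ndx <- 1L + stats::rpois(1, 0.8)
      vers <- ifelse(stats::runif(ndx) < 0.5, 9L, 10L)
      for (j in seq_len(ndx)) {
        pool <- DX_POOLS[[cnd]][[if (vers[j] == 9) "icd9" else "icd10"]]
        dd <- c(dd, cal$diagnosis_start + sample.int(dx_len, 1L) - 1L)
        dv <- c(dv, vers[j])
        dc <- c(dc, pool[sample.int(length(pool), 1L)])
      }
    }
    if (stats::runif(1) < 0.3) {
      v <- if (stats::runif(1) < 0.5) 9L else 10L
      dd <- c(dd, cal$diagnosis_start + sample.int(dx_len, 1L) - 1L)
      dv <- c(dv, v)
      dc <- c(dc, if (v == 9) "V70.0" else "Z00.00")
    }
    if (length(dd)) {
      x_id[[i]] <- rep.int(i, length(dd))
      x_day[[i]] <- dd; x_ver[[i]] <- dv; x_code[[i]] <- dc
    }

    # pharmacy claims: one refill chain per (condition, class); the chain
    # structure gives the class-level fixed PDC in closed form
    class_pdc <- numeric(0)
    kd <- integer(0); ks <- integer(0); kc <- character(0); kn <- character(0)
    for (cnd in conds[has_cond]) {
      pool <- cmap[[cnd]]$drug_classes
      k <- sample(cfg$n_classes_range[1]:cfg$n_classes_range[2], 1L)
      classes <- sample(pool, min(k, length(pool)))
      for (cls in classes) {
        ch <- refill_chain(a, cfg, cal)
        if (!length(ch$day)) next
        cov <- chain_covered(ch$day, ch$supply, cal$analysis_start, cal$analysis_end)
        class_pdc <- c(class_pdc, cov / analysis_len)
        kd <- c(kd, ch$day); ks <- c(ks, ch$supply)
        kc <- c(kc, rep.int(cls, length(ch$day)))
        kn <- c(kn, rep.int(cnd, length(ch$day)))
      }
    }
    if (length(kd)) {
      c_id[[i]] <- rep.int(i, length(kd))
      c_day[[i]] <- kd; c_sup[[i]] <- ks; c_cls[[i]] <- kc; c_cnd[[i]] <- kn
    }
    true_pdc <- if (length(class_pdc)) mean(class_pdc) else NA_real_
    true_adh <- !is.na(true_pdc) && true_pdc >= 0.80
    t_pdc[i] <- true_pdc; t_adh[i] <- true_adh

    # tracker adoption: injected effect on true adherent status + age slope
    eta <- stats::qlogis(cfg$tracker_adoption_prob) +
      cfg$tracker_adherence_log_odds * as.numeric(true_adh) +
      cfg$tracker_age_log_odds * (age - 60)
    tracker <- stats::runif(1) < stats::plogis(eta)
    t_tracker[i] <- tracker

    ad <- integer(0); aa <- character(0); av <- numeric(0); as_ <- character(0)
    if (tracker) {
      tenure_start <- cal$analysis_start + sample.int(analysis_len - 14L, 1L) - 1L
      tenure_days <- tenure_start:(cal$analysis_end - 1L)
      logged <- tenure_days[stats::runif(length(tenure_days)) < p]
      if (!length(logged)) logged <- tenure_days[1]   # adopters log at least once
      owned <- names(cfg$activity_ownership)[
        stats::runif(length(cfg$activity_ownership)) < cfg$activity_ownership]
      if (!length(owned)) owned <- "steps"
      for (tp in owned) {
        vals <- switch(tp,
          steps = round(stats::rlnorm(length(logged), cfg$steps_lognormal[1],
                                      cfg$steps_lognormal[2])),
          sleep = round(pmax(stats::rnorm(length(logged), 7, 1.2), 1), 1),
          weight = round(pmax(stats::rnorm(length(logged), 85, 15), 35), 1),
          food = stats::rpois(length(logged), 2) + 1)
        ad <- c(ad, logged)
        aa <- c(aa, rep.int(tp, length(logged)))
        av <- c(av, as.numeric(vals))
        as_ <- c(as_, rep.int("tracker", length(logged)))
      }
    }
    if (stats::runif(1) < cfg$phone_steps_prob) {
      m <- 1L + stats::rpois(1, 15)
      pd <- cal$analysis_start + sample.int(analysis_len, min(m, analysis_len)) - 1L
      ad <- c(ad, pd)
      aa <- c(aa, rep.int("steps", length(pd)))
      av <- c(av, round(stats::rlnorm(length(pd), cfg$steps_lognormal[1],
                                      cfg$steps_lognormal[2])))
      as_ <- c(as_, rep.int("phone", length(pd)))
    }
    if (length(ad)) {
      a_id[[i]] <- rep.int(i, length(ad))
      a_day[[i]] <- ad; a_act[[i]] <- aa; a_val[[i]] <- av; a_src[[i]] <- as_
    }
  }

  epoch <- cal$epoch
  demographics <- data.frame(
    individual_id = seq_len(n), age_years = d_age, sex = d_sex,
    coverage_start = as.character(offset_date(d_cov_start, epoch)),
    coverage_end = as.character(offset_date(d_cov_end, epoch)))

  diagnoses <- data.frame(
    individual_id = as.integer(unlist(x_id)),
    service_date = as.character(offset_date(unlist(x_day), epoch)),
    icd_version = as.integer(unlist(x_ver)),
    code = as.character(unlist(x_code)))

  claims <- data.frame(
    individual_id = as.integer(unlist(c_id)),
    fill_date = as.character(offset_date(unlist(c_day), epoch)),
    days_supply = as.integer(unlist(c_sup)),
    drug_class = as.character(unlist(c_cls)),
    condition = as.character(unlist(c_cnd)))

  activity <- data.frame(
    individual_id = as.integer(unlist(a_id)),
    log_date = as.character(offset_date(unlist(a_day), epoch)),
    activity = as.character(unlist(a_act)),
    value = as.numeric(unlist(a_val)),
    source = as.character(unlist(a_src)))

  truth_df <- data.frame(individual_id = seq_len(n), a = t_a, p = t_p,
                         tracker = t_tracker, true_fixed_pdc = t_pdc,
                         true_adherent = t_adh)
  attr(truth_df, "injected_log_odds") <- cfg$tracker_adherence_log_odds

  structure(list(demographics = demographics, diagnoses = diagnoses,
                 claims = claims, activity = activity, truth = truth_df,
                 config = cfg),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Emits `demographics.csv`, `diagnoses.csv`, `claims.csv`, `activity.csv`
#' and `truth.json` (per-individual ground truth plus a config echo) into a
#' directory, in the schemas that [read_bundle()] reads back losslessly.
#'
#' @param bundle A [simulate_cohort()] result.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
write_bundle <- function(bundle, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", directory)
  }
  files <- c(demographics = "demographics.csv", diagnoses = "diagnoses.csv",
             claims = "claims.csv", activity = "activity.csv")
  for (nm in names(files)) {
    path <- file.path(directory, files[[nm]])
    tryCatch(utils::write.csv(bundle[[nm]], path, row.names = FALSE, quote = FALSE),
             error = function(e) stop("failed writing ", path, ": ",
                                      conditionMessage(e)))
  }
  cfg <- bundle$config
  echo <- cfg[setdiff(names(cfg), "calendar")]
  echo$calendar <- list(
    supply_start = as.character(offset_date(cfg$calendar$supply_start, cfg$calendar$epoch)),
    supply_end = as.character(offset_date(cfg$calendar$supply_end, cfg$calendar$epoch)),
    analysis_start = as.character(offset_date(cfg$calendar$analysis_start, cfg$calendar$epoch)),
    analysis_end = as.character(offset_date(cfg$calendar$analysis_end, cfg$calendar$epoch)))
  tj <- file.path(directory, "truth.json")
  jsonlite::write_json(list(individuals = bundle$truth, config = echo),
                       tj, auto_unbox = TRUE, digits = NA)
  invisible(c(file.path(directory, files), tj))
}
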