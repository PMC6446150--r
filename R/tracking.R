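#' Raw tracking ratio
#'
#' For an individual's activity-log days within the analysis period, the
#' tracking ratio is r = k/n, where k is the number of distinct days with at
#' least one logged activity (any of steps, sleep, weight, food) and n the
#' inclusive span between the first and last log day (last - first + 1). The
#' inclusive span makes a single-day tracker r = 1 with n = 1 rather than
#' dividing by zero, and perturbs long histories negligibly.
#'
#' @param log_days Integer day offsets with at least one log (duplicates fine).
#' @return List `k`, `n`, `r`, or `NULL` when there are no logs.
#' @export
#' @examples
#' tracking_ratio(c(0, 9)) # k = 2, n = 10, r = 0.2
tracking_ratio <- function(log_days) {
  log_days <- unique(as.integer(log_days))
  if (length(log_days) == 0L) return(NULL)
  k <- length(log_days)
  n <- max(log_days) - min(log_days) + 1L
  list(k = k, n = n, r = k / n)
}

#' Shrinkage prior for the adjusted tracking ratio
#'
#' Raw ratios from individuals with few observed days are highly variable, so
#' each ratio is shrunk toward the population mean with a prior worth
#' `strength` (default 10) days of observation. `r_mean` is the unweighted
#' sample mean of raw ratios across all individuals with at least one log.
#'
#' @param raw_ratios Numeric vector of raw tracking ratios.
#' @param strength Prior weight in pseudo-days, > 0.
#' @return List with class `shrinkage_prior`: `r_mean`, `strength`.
#' @export
compute_prior <- function(raw_ratios, strength = 10) {
  raw_ratios <- raw_ratios[!is.na(raw_ratios)]
  if (length(raw_ratios) == 0L) stop("no tracking ratios: cannot form a prior")
  stopifnot(strength > 0)
  structure(list(r_mean = mean(raw_ratios), strength = strength),
            class = "shrinkage_prior")
}

#' Empirical-Bayes adjusted tracking ratio
#'
#' Models the k observed tracking days out of an n-day span as Binomial(n, p)
#' with a Beta prior on p centred on the population mean ratio, and returns a
#' point estimate of p. The canonical form is
#' \deqn{(k + s\,\bar r) / (n + s)}
#' with prior weight s = 10: the maximum a posteriori estimate under a
#' Beta prior with *mode* \eqn{\bar r} and total weight s + 2. The
#' `"map_mean"` variant instead constrains the prior *mean* to \eqn{\bar r}
#' with \eqn{\alpha + \beta - 2 = s}, giving
#' \eqn{(k + (s+2)\bar r - 1)/(n + s)}; the two coincide only at
#' \eqn{\bar r = 0.5}.
#'
#' @param k Days tracked, 0 <= k <= n.
#' @param n Span days, >= 1.
#' @param prior A [compute_prior()] result (or list with `r_mean`, `strength`).
#' @param variant `"canonical"` (default) or `"map_mean"`.
#' @return Adjusted ratio, vectorised over `k`/`n`.
#' @export
#' @examples
#' adjusted_tracking_ratio(5, 10, list(r_mean = 0.5, strength = 10)) # 0.5
adjusted_tracking_ratio <- function(k, n, prior,
                                    variant = c("canonical", "map_mean")) {
  variant <- match.arg(variant)
  if (any(n < 1)) stop("span n must be at least 1")
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
  s <- prior$strength
  rm <- prior$r_mean
  if (variant == "canonical") {
    (k + s * rm) / (n + s)
  } else {
    (k + (s + 2) * rm - 1) / (n + s)
  }
}

#' Steps per week tracked
#'
#' Total steps logged (tracker devices only) divided by the number of distinct
#' Monday-start calendar weeks containing at least one step log. An
#' alternative `"span"` rule divides by `ceiling(span / 7)` where span is the
#' inclusive day span of step logging.
#'
#' @param step_days Integer day offsets of step logs.
#' @param step_values Step counts per log (same length).
#' @param week_rule `"calendar"` (default) or `"span"`.
#' @param epoch Epoch date used for the calendar-week alignment.
#' @return Steps per week, or `NA_real_` when there are no step logs.
#' @export
steps_per_week <- function(step_days, step_values, week_rule = c("calendar", "span"),
                           epoch = as.Date("2015-01-01")) {
  week_rule <- match.arg(week_rule)
  if (length(step_days) == 0L) return(NA_real_)
  if (length(step_days) != length(step_values)) {
    stop("step_days and step_values must have equal length")
  }
  if (any(step_values < 0)) stop("negative step counts are invalid")
  total <- sum(step_values)
  weeks <- if (week_rule == "calendar") {
    length(unique(week_index(step_days, epoch)))
  } else {
    ceiling((max(step_days) - min(step_days) + 1) / 7)
  }
  total / weeks
}

#' Eligibility for the tracking-metrics association models
#'
#' Activity logs are strongly autocorrelated over a few days; requiring two
#' tracking events at least 10 days apart (inclusive) guarantees at least two
#' effectively independent measurements per individual.
#'
#' @param log_days Integer day offsets with at least one log.
#' @return Logical scalar; `FALSE` for empty or single-day histories.
#' @export
metrics_eligible <- function(log_days) {
  log_days <- unique(as.integer(log_days))
  if (length(log_days) < 2L) return(FALSE)
  (max(log_days) - min(log_days)) >= 10L
}

ACTIVITIES <- c("steps", "sleep", "weight", "food")

#' Per-individual tracking metrics table
#'
#' Computes the full tracker summary for every individual in `demographics`
#' from the activity log: ever-tracked flags (overall and per activity), the
#' raw and adjusted tracking ratios, steps per week tracked, and eligibility
#' for the metrics models. Only analysis-period rows from active tracker
#' devices are used; `source == "phone"` rows (passive smartphone counts) are
#' discarded up front.
#'
#' @param activity Activity-log data.frame (`individual_id`, `log_date`,
#'   `activity`, `value`, `source`).
#' @param demographics Demographics data.frame (defines the id universe;
#'   non-trackers get FALSE flags and NA metrics).
#' @param calendar A [study_calendar()].
#' @param prior Optional [compute_prior()]; computed from this table's raw
#'   ratios when NULL.
#' @param week_rule Passed to [steps_per_week()].
#' @return data.frame, one row per individual: `individual_id`,
#'   `ever_tracked_any`, `ever_tracked_steps/sleep/weight/food`, `k`, `n`,
#'   `raw_ratio`, `adjusted_ratio`, `steps_per_week`, `metrics_eligible`.
#'   Carries the prior used as attribute `"prior"`.
#' @export
tracking_metrics <- function(activity, demographics, calendar = study_calendar(),
                             prior = NULL, week_rule = "calendar") {
  check_schema(activity, c("individual_id", "log_date", "activity", "value", "source"),
               "activity")
  epoch <- calendar$epoch
  day <- day_offset(activity$log_date, epoch)
  keep <- activity$source == "tracker" &
    day >= calendar$analysis_start & day < calendar$analysis_end
  act <- activity[keep, , drop = FALSE]
  act$day <- day[keep]

  ids <- sort(unique(demographics$individual_id))
  res <- data.frame(individual_id = ids,
                    ever_tracked_any = FALSE,
                    ever_tracked_steps = FALSE, ever_tracked_sleep = FALSE,
                    ever_tracked_weight = FALSE, ever_tracked_food = FALSE,
                    k = NA_integer_, n = NA_integer_,
                    raw_ratio = NA_real_, adjusted_ratio = NA_real_,
                    steps_per_week = NA_real_, metrics_eligible = FALSE)
  if (nrow(act)) {
    by_id <- split(act, act$individual_id)
    idx <- match(as.integer(names(by_id)), ids)
    for (j in seq_along(by_id)) {
      a <- by_id[[j]]
      i <- idx[j]
      for (tp in ACTIVITIES) {
        res[[paste0("ever_tracked_", tp)]][i] <- tp %in% a$activity
      }
      res$ever_tracked_any[i] <- TRUE
      tr <- tracking_ratio(a$day)
      res$k[i] <- tr$k; res$n[i] <- tr$n; res$raw_ratio[i] <- tr$r
      st <- a[a$activity == "steps", , drop = FALSE]
      res$steps_per_week[i] <- steps_per_week(st$day, st$value,
                                              week_rule = week_rule, epoch = epoch)
      res$metrics_eligible[i] <- metrics_eligible(a$day)
    }
  }
  tracked <- !is.na(res$raw_ratio)
  if (is.null(prior)) {
    prior <- if (any(tracked)) compute_prior(res$raw_ratio[tracked]) else NULL
  }
  if (!is.null(prior) && any(tracked)) {
    res$adjusted_ratio[tracked] <- adjusted_tracking_ratio(
      res$k[tracked], res$n[tracked], prior)
  }
  attr(res, "prior") <- prior
  res
}
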