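#' Days of medication coverage within a window
#'
#' Counts the days inside a half-open window `[start, end)` on which an
#' individual held a supply of one drug class, given the class's prescription
#' fills. Fills of the same class *stockpile*: a refill picked up before the
#' current supply runs out starts counting only when that supply is exhausted,
#' so early refills extend coverage instead of overlapping it. Fills dated
#' before the window (e.g. supply-period fills) enter the same chain, which is
#' how baseline carryover propagates into the analysis window.
#'
#' An alternative `overlap = "union"` policy treats each fill as a literal
#' interval `[fill_day, fill_day + days_supply)` and counts the union; it is
#' provided for sensitivity analyses and never stockpiles.
#'
#' @param fill_day Integer day offsets of the fills (any order).
#' @param days_supply Positive integer days supplied per fill.
#' @param window Length-2 numeric, half-open day interval `c(start, end)`.
#' @param overlap Coverage policy: `"stockpile"` (default) or `"union"`.
#' @return Integer count of covered days, at most `window[2] - window[1]`.
#' @export
#' @examples
#' covered_days(c(0, 20), c(30, 30), c(0, 365)) # 60: second fill shifts to day 30
#' covered_days(-10, 30, c(0, 365))             # 20: carryover tail only
covered_days <- function(fill_day, days_supply, window,
                         overlap = c("stockpile", "union")) {
  overlap <- match.arg(overlap)
  stopifnot(length(window) == 2, window[1] < window[2])
  if (length(fill_day) == 0L) return(0L)
  if (any(days_supply < 1)) stop("days_supply must be a positive number of days")
  if (length(fill_day) != length(days_supply)) {
    stop("fill_day and days_supply must have equal length")
  }
  iv <- coverage_intervals(fill_day, days_supply, overlap)
  lo <- pmax(iv$start, window[1])
  hi <- pmin(iv$end, window[2])
  as.integer(sum(pmax(0, hi - lo)))
}

# Disjoint coverage intervals implied by a fill sequence.
# stockpile: each fill starts at max(fill day, previous coverage end).
# union: literal fill intervals merged where they touch or overlap.
coverage_intervals <- function(fill_day, days_supply, overlap = "stockpile") {
  ord <- order(fill_day)
  fill_day <- as.numeric(fill_day)[ord]
  days_supply <- as.numeric(days_supply)[ord]
  n <- length(fill_day)
  start <- numeric(n)
  end <- numeric(n)
  if (overlap == "stockpile") {
    prev_end <- -Inf
    for (i in seq_len(n)) {
      start[i] <- max(fill_day[i], prev_end)
      end[i] <- start[i] + days_supply[i]
      prev_end <- end[i]
    }
    list(start = start, end = end)
  } else {
    start <- fill_day
    end <- fill_day + days_supply
    # merge overlapping/adjacent intervals
    ms <- start[1]; me <- end[1]
    out_s <- numeric(0); out_e <- numeric(0)
    if (n > 1) {
      for (i in 2:n) {
        if (start[i] <= me) {
          me <- max(me, end[i])
        } else {
          out_s <- c(out_s, ms); out_e <- c(out_e, me)
          ms <- start[i]; me <- end[i]
        }
      }
    }
    list(start = c(out_s, ms), end = c(out_e, me))
  }
}

#' Fixed-denominator proportion of days covered
#'
#' The fixed methodology assumes the individual should be on the medication for
#' the whole analysis period: the denominator is the full analysis-period
#' length (366 days for the default calendar year spanning the 2016 leap day)
#' and the numerator is the number of analysis-period days with supply on
#' hand, including medication carried over from supply-period fills. It is
#' generally a lower bound on true adherence.
#'
#' @param fill_day,days_supply All fills of one drug class (supply and
#'   analysis period together), as day offsets and supplies.
#' @param calendar A [study_calendar()].
#' @param denominator Optional override of the denominator length in days
#'   (e.g. 365); defaults to the exact analysis-window length.
#' @param overlap Coverage policy passed to [covered_days()].
#' @return A list of class `drug_class_pdc` with fields `methodology`,
#'   `covered`, `denominator`, `pdc`, `window_start`, `window_end`; or `NULL`
#'   when there are no fills at all (PDC undefined).
#' @export
fixed_pdc <- function(fill_day, days_supply, calendar = study_calendar(),
                      denominator = NULL, overlap = "stockpile") {
  if (length(fill_day) == 0L) return(NULL)
  win <- c(calendar$analysis_start, calendar$analysis_end)
  cov <- covered_days(fill_day, days_supply, win, overlap = overlap)
  den <- if (is.null(denominator)) win[2] - win[1] else as.integer(denominator)
  stopifnot(den >= 1)
  structure(list(methodology = "fixed", covered = cov, denominator = den,
                 pdc = cov / den, window_start = win[1], window_end = win[2]),
            class = "drug_class_pdc")
}

#' Variable-denominator proportion of days covered
#'
#' The variable methodology assumes the individual should be on the medication
#' only between their first analysis-period fill and the exhaustion of the
#' last refill's (stockpiled) supply, truncated at the analysis-period end.
#' It requires at least two analysis-period fills — with a single fill the
#' window would equal that fill's supply and the PDC would be trivially 1.0 —
#' and is generally an upper bound on true adherence.
#'
#' @inheritParams fixed_pdc
#' @return As [fixed_pdc()], with `methodology = "variable"` and the personal
#'   window recorded; `NULL` when fewer than two analysis-period fills exist
#'   (ineligible, a value rather than an error).
#' @export
variable_pdc <- function(fill_day, days_supply, calendar = study_calendar(),
                         overlap = "stockpile") {
  as_ <- calendar$analysis_start; ae <- calendar$analysis_end
  in_analysis <- fill_day >= as_ & fill_day < ae
  if (sum(in_analysis) < 2L) return(NULL)
  iv <- coverage_intervals(fill_day, days_supply, overlap)
  w_start <- min(fill_day[in_analysis])
  w_end <- min(max(iv$end), ae)
  cov <- covered_days(fill_day, days_supply, c(w_start, w_end), overlap = overlap)
  den <- as.integer(w_end - w_start)
  structure(list(methodology = "variable", covered = cov, denominator = den,
                 pdc = cov / den, window_start = w_start, window_end = w_end),
            class = "drug_class_pdc")
}

#' Condition-level PDC from drug-class results
#'
#' Aggregates per-drug-class PDC values to one condition-level value per
#' individual: an unweighted arithmetic mean under the fixed methodology, and
#' a weighted average under the variable methodology with each class's
#' personal window length as its weight.
#'
#' @param pdc Numeric vector of drug-class PDC values.
#' @param methodology `"fixed"` or `"variable"`.
#' @param window_length Window lengths in days (required for `"variable"`).
#' @return Condition-level PDC in `[0, 1]`.
#' @export
#' @examples
#' condition_pdc(c(0.6, 0.8), "fixed")                      # 0.7
#' condition_pdc(c(0.9, 0.5), "variable", c(300, 100))      # 0.8
condition_pdc <- function(pdc, methodology = c("fixed", "variable"),
                          window_length = NULL) {
  methodology <- match.arg(methodology)
  if (length(pdc) == 0L) stop("no drug-class PDC values to aggregate")
  if (methodology == "fixed") {
    mean(pdc)
  } else {
    if (is.null(window_length) || length(window_length) != length(pdc)) {
      stop("variable-methodology aggregation needs one window length per class")
    }
    sum(pdc * window_length) / sum(window_length)
  }
}

#' Classify adherent status from a condition-level PDC
#'
#' Applies the standard adherence threshold: an individual is adherent for a
#' condition when the condition-level PDC is at least 0.80 (inclusive).
#'
#' @param pdc Condition-level PDC in `[0, 1]` (NA propagates).
#' @param threshold Adherence threshold, default 0.80.
#' @return Logical.
#' @export
classify_adherent <- function(pdc, threshold = 0.80) {
  bad <- !is.na(pdc) & (pdc < 0 | pdc > 1)
  if (any(bad)) stop("PDC values must lie in [0, 1]")
  pdc >= threshold
}

#' Sensitivity-analysis adherence classification
#'
#' Under the sensitivity rule an individual counts as adherent when *any*
#' single drug-class PDC reaches the threshold, rather than the condition-level
#' average.
#'
#' @param class_pdc Numeric vector of drug-class-level PDC values (length >= 1).
#' @param threshold Adherence threshold, default 0.80.
#' @return Logical scalar.
#' @export
classify_adherent_sensitivity <- function(class_pdc, threshold = 0.80) {
  if (length(class_pdc) == 0L) stop("no drug-class PDC values supplied")
  max(class_pdc) >= threshold
}

#' Per-individual, per-condition adherence table for a cohort
#'
#' Runs the full adherence computation for every cohort member: per drug class
#' the fixed PDC (with supply-period carryover) and, where the member has at
#' least two analysis-period fills of that class, the variable PDC; then the
#' condition-level aggregates, the base-case adherent flags and the any-class
#' sensitivity flags.
#'
#' Classes filled only during the supply period still contribute a fixed-PDC
#' term (their carryover coverage into the analysis window may be small but is
#' real); variable aggregation uses only variable-eligible classes and is NA
#' when no class qualifies.
#'
#' @param cohort A cohort data.frame from [build_cohort()] (one row per
#'   individual x condition) with its `fills` attribute, or a list as returned
#'   by that function.
#' @param calendar A [study_calendar()].
#' @param denominator,overlap Passed through to the PDC functions.
#' @return data.frame with one row per (individual, condition):
#'   `individual_id`, `condition`, `n_classes`, `fixed_pdc`, `variable_pdc`,
#'   `fixed_adherent`, `variable_adherent`, `sens_fixed_adherent`,
#'   `sens_variable_adherent`. Variable columns are NA for individuals with no
#'   variable-eligible class.
#' @export
adherence_table <- function(cohort, calendar = study_calendar(),
                            denominator = NULL, overlap = "stockpile") {
  members <- cohort$members
  fills <- cohort$fills
  nm <- nrow(members)
  n_classes <- integer(nm)
  fixed_c <- numeric(nm); var_c <- rep(NA_real_, nm)
  sens_f <- logical(nm); sens_v <- rep(NA, nm)
  for (i in seq_len(nm)) {
    f <- fills[[i]]
    classes <- unique(f$drug_class)
    fx <- numeric(0)
    vb <- numeric(0); vw <- numeric(0)
    for (cl in classes) {
      sel <- f$drug_class == cl
      r <- fixed_pdc(f$fill_day[sel], f$days_supply[sel], calendar,
                     denominator = denominator, overlap = overlap)
      fx <- c(fx, r$pdc)
      v <- variable_pdc(f$fill_day[sel], f$days_supply[sel], calendar,
                        overlap = overlap)
      if (!is.null(v)) {
        vb <- c(vb, v$pdc)
        vw <- c(vw, v$denominator)
      }
    }
    n_classes[i] <- length(classes)
    fixed_c[i] <- condition_pdc(fx, "fixed")
    if (length(vb)) var_c[i] <- condition_pdc(vb, "variable", vw)
    sens_f[i] <- classify_adherent_sensitivity(fx)
    if (length(vb)) sens_v[i] <- classify_adherent_sensitivity(vb)
  }
  data.frame(
    individual_id = members$individual_id,
    condition = members$condition,
    n_classes = n_classes,
    fixed_pdc = fixed_c,
    variable_pdc = var_c,
    fixed_adherent = classify_adherent(fixed_c),
    variable_adherent = ifelse(is.na(var_c), NA, classify_adherent(var_c)),
    sens_fixed_adherent = sens_f,
    sens_variable_adherent = sens_v
  )
}

#' Day-grid reference implementation of coverage counting
#'
#' Marks every covered day on an explicit grid by walking the fill chain one
#' day at a time. Algorithmically independent of the interval arithmetic in
#' [covered_days()]; used to validate it and to compute generation-time ground
#' truth. Linear in window length per fill sequence, so only suitable for
#' study-length windows.
#'
#' @inheritParams covered_days
#' @return Integer count of covered days in the window.
#' @keywords internal
#' @export
covered_days_grid <- function(fill_day, days_supply, window,
                              overlap = c("stockpile", "union")) {
  overlap <- match.arg(overlap)
  if (length(fill_day) == 0L) return(0L)
  ord <- order(fill_day)
  fill_day <- as.numeric(fill_day)[ord]
  days_supply <- as.numeric(days_supply)[ord]
  lo <- min(window[1], min(fill_day))
  hi <- window[2]
  ndays <- as.integer(hi - lo)
  if (ndays <= 0) return(0L)
  covered <- logical(ndays)
  if (overlap == "stockpile") {
    pills <- 0          # days of supply in hand at the start of each day
    queue <- numeric(0) # supplies not yet started (stockpile)
    for (d in seq_len(ndays)) {
      day <- lo + d - 1
      got <- fill_day == day
      if (any(got)) queue <- c(queue, days_supply[got])
      if (pills <= 0 && length(queue)) {
        pills <- queue[1]; queue <- queue[-1]
      }
      if (pills > 0) {
        covered[d] <- TRUE
        pills <- pills - 1
      }
    }
  } else {
    for (i in seq_along(fill_day)) {
      s <- max(fill_day[i], lo); e <- min(fill_day[i] + days_supply[i], hi)
      if (e > s) covered[(s - lo + 1):(e - lo)] <- TRUE
    }
  }
  keep <- (lo + seq_len(ndays) - 1) >= window[1]
  as.integer(sum(covered[keep]))
}
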