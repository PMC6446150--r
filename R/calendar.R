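#' Study calendar
#'
#' The analysis is organised around two pharmacy-claims windows: a baseline
#' *supply period*, used only to establish which individuals filled relevant
#' prescriptions and how much medication they held when the main window opened,
#' and an *analysis period* over which adherence and tracking behaviour are
#' measured. A third, much longer window bounds the diagnosis dates that may
#' qualify an individual for a condition cohort.
#'
#' All dates are handled internally as integer day offsets from a fixed epoch
#' (default 2015-01-01, the supply-period start), and all intervals are
#' half-open `[start, end)`, so interval lengths are plain differences and a
#' day is never double counted.
#'
#' @param supply_start,supply_end Supply period, ISO dates (end exclusive).
#' @param analysis_start,analysis_end Analysis period, ISO dates (end
#'   exclusive). The default spans 2015-06-01 to 2016-06-01, a 366-day year
#'   containing the 2016 leap day.
#' @param diagnosis_start,diagnosis_end Window of qualifying diagnosis dates
#'   (end exclusive; the default admits dates through 2015-09-01).
#' @param epoch Date mapped to day offset 0.
#'
#' @return An object of class `study_calendar`: a list of integer day offsets
#'   `supply_start`, `supply_end`, `analysis_start`, `analysis_end`,
#'   `diagnosis_start`, `diagnosis_end`, plus the `epoch` as a `Date`.
#' @export
#' @examples
#' cal <- study_calendar()
#' cal$analysis_end - cal$analysis_start # 366
study_calendar <- function(supply_start = "2015-01-01",
                           supply_end = "2015-06-01",
                           analysis_start = "2015-06-01",
                           analysis_end = "2016-06-01",
                           diagnosis_start = "2005-01-01",
                           diagnosis_end = "2015-09-02",
                           epoch = as.Date("2015-01-01")) {
  epoch <- as.Date(epoch)
  cal <- list(
    supply_start = day_offset(supply_start, epoch),
    supply_end = day_offset(supply_end, epoch),
    analysis_start = day_offset(analysis_start, epoch),
    analysis_end = day_offset(analysis_end, epoch),
    diagnosis_start = day_offset(diagnosis_start, epoch),
    diagnosis_end = day_offset(diagnosis_end, epoch),
    epoch = epoch
  )
  if (!(cal$supply_start < cal$supply_end &&
        cal$supply_end <= cal$analysis_start &&
        cal$analysis_start < cal$analysis_end)) {
    stop("invalid study calendar: need supply_start < supply_end <= analysis_start < analysis_end")
  }
  if (cal$diagnosis_start >= cal$diagnosis_end || cal$diagnosis_end > cal$analysis_end) {
    stop("invalid diagnosis window: must be non-empty and precede the analysis end")
  }
  class(cal) <- "study_calendar"
  cal
}

#' Convert ISO dates to integer day offsets
#'
#' @param date Date or ISO-8601 string vector.
#' @param epoch Date mapped to offset 0.
#' @return Integer vector of day offsets.
#' @export
day_offset <- function(date, epoch = as.Date("2015-01-01")) {
  as.integer(as.Date(date) - as.Date(epoch))
}

#' Convert day offsets back to dates
#'
#' @param offset Integer day offsets.
#' @param epoch Date mapped to offset 0.
#' @return `Date` vector.
#' @export
offset_date <- function(offset, epoch = as.Date("2015-01-01")) {
  as.Date(epoch) + as.integer(offset)
}

#' @export
print.study_calendar <- function(x, ...) {
  cat("Study calendar (epoch ", format(x$epoch), ")\n", sep = "")
  cat(sprintf("  supply period:   [%s, %s)  %d days\n",
              format(offset_date(x$supply_start, x$epoch)),
              format(offset_date(x$supply_end, x$epoch)),
              x$supply_end - x$supply_start))
  cat(sprintf("  analysis period: [%s, %s)  %d days\n",
              format(offset_date(x$analysis_start, x$epoch)),
              format(offset_date(x$analysis_end, x$epoch)),
              x$analysis_end - x$analysis_start))
  cat(sprintf("  diagnosis window:[%s, %s)\n",
              format(offset_date(x$diagnosis_start, x$epoch)),
              format(offset_date(x$diagnosis_end, x$epoch))))
  invisible(x)
}

# Monday-start calendar week index for a day offset (used by steps-per-week).
# The shift aligns week boundaries to Mondays regardless of the epoch weekday.
week_index <- function(offset, epoch = as.Date("2015-01-01")) {
  wd <- as.POSIXlt(as.Date(epoch))$wday          # 0 = Sunday
  shift <- (wd - 1L) %% 7L                       # days since the preceding Monday
  (as.integer(offset) + shift) %/% 7L
}
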