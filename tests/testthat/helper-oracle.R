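# Brute-force day-grid oracle for medication coverage, written independently
# of the package's interval arithmetic: walk the calendar one day at a time,
# keeping a shelf of unopened supplies and a count of pills in hand.

oracle_mark_days <- function(fill_day, days_supply, until) {
  # returns the sorted vector of covered days from the earliest fill to `until`
  if (length(fill_day) == 0L) return(integer(0))
  ord <- order(fill_day)
  fill_day <- fill_day[ord]; days_supply <- days_supply[ord]
  first <- min(fill_day)
  covered <- integer(0)
  pills <- 0
  shelf <- integer(0)            # unopened supplies, FIFO
  for (day in first:(until - 1L)) {
    new <- which(fill_day == day)
    if (length(new)) shelf <- c(shelf, days_supply[new])
    if (pills == 0 && length(shelf)) {
      pills <- shelf[1]
      shelf <- shelf[-1]
    }
    if (pills > 0) {
      covered <- c(covered, day)
      pills <- pills - 1
    }
  }
  covered
}

oracle_covered_days <- function(fill_day, days_supply, ws, we) {
  d <- oracle_mark_days(fill_day, days_supply, we)
  sum(d >= ws & d < we)
}

oracle_fixed_pdc <- function(fill_day, days_supply, cal) {
  if (length(fill_day) == 0L) return(NULL)
  num <- oracle_covered_days(fill_day, days_supply, cal$analysis_start, cal$analysis_end)
  num / (cal$analysis_end - cal$analysis_start)
}

oracle_variable_pdc <- function(fill_day, days_supply, cal) {
  in_an <- fill_day >= cal$analysis_start & fill_day < cal$analysis_end
  if (sum(in_an) < 2L) return(NULL)
  # end of the stockpiled supply of the final fill = day after the last
  # covered day of the whole chain (never truncated before capping)
  horizon <- max(fill_day) + sum(days_supply) + 1L
  d <- oracle_mark_days(fill_day, days_supply, horizon)
  w_start <- min(fill_day[in_an])
  w_end <- min(max(d) + 1L, cal$analysis_end)
  num <- sum(d >= w_start & d < w_end)
  num / (w_end - w_start)
}

# random fill sequence generator shared by the property tests
random_fill_seq <- function(cal, max_fills = 12L) {
  nf <- sample(0:max_fills, 1L)
  if (nf == 0L) return(list(day = integer(0), supply = integer(0)))
  # mix supply-period (carryover) and analysis-period fills, allow overlap
  day <- sample(cal$supply_start:(cal$analysis_end - 1L), nf, replace = TRUE)
  supply <- sample(c(7L, 14L, 30L, 60L, 90L), nf, replace = TRUE)
  list(day = sort(day), supply = supply)
}
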