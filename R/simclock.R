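#' Half-day calendar utilities
#'
#' The simulator runs at half-day resolution: every calendar day has a
#' morning session (odd index) and an afternoon session (even index).
#' Index 1 is the morning of the simulation start date. All calendar
#' arithmetic uses the proleptic Gregorian calendar via [base::Date], so
#' leap days are handled naturally.
#'
#' @name simclock
NULL

#' Number of half-days spanned by an inclusive date interval
#'
#' @param start_date,end_date `Date` (or coercible) endpoints, inclusive.
#' @return Positive integer: `2 * (inclusive day count)`.
#' @examples
#' half_day_count("2017-10-01", "2021-09-30") # 2922
#' half_day_count("2017-10-01", "2018-02-28") # 302
#' @export
half_day_count <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (end_date < start_date) {
    stop("`end_date` must not precede `start_date`", call. = FALSE)
  }
  2L * (as.integer(end_date - start_date) + 1L)
}

#' Half-day index of a date within a simulation horizon
#'
#' @param date date of interest.
#' @param origin first simulated day (its morning is index 1).
#' @param phase `"morning"` or `"afternoon"`.
#' @return Integer half-day index (morning indices are odd).
#' @export
halfday_index <- function(date, origin, phase = c("morning", "afternoon")) {
  phase <- match.arg(phase)
  date <- as.Date(date)
  origin <- as.Date(origin)
  if (any(date < origin)) stop("`date` precedes `origin`", call. = FALSE)
  2L * as.integer(date - origin) + if (phase == "morning") 1L else 2L
}

# Season month sets: Rabi Oct-Feb, Zaid Mar-May, Kharif Jun-Sep.
.season_names <- c("Rabi", "Zaid", "Kharif")
.season_of_month <- c(
  2L, 2L, 2L, 2L, 2L, # Jan..May -> Jan/Feb are Rabi (1), fixed below
  3L, 3L, 3L, 3L, 1L, 1L, 1L
)
.season_of_month[1:2] <- 1L
.season_of_month[3:5] <- 2L

# Days between marketing trips per season (Rabi, Zaid, Kharif).
.marketing_interval <- c(Rabi = 5L, Zaid = 7L, Kharif = 8L)

#' Cropping season of a calendar date
#'
#' Rabi covers October-February, Zaid March-May and Kharif June-September;
#' the lookup is month-based and year-independent (the leap day 2020-02-29
#' falls in Rabi).
#'
#' @param date date (or coercible).
#' @return Character: `"Rabi"`, `"Zaid"` or `"Kharif"`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  .season_names[.season_of_month[m]]
}

#' Days between marketing trips in a season
#'
#' Farmers market once every five days in Rabi, seven in Zaid and eight in
#' Kharif.
#'
#' @param season season name.
#' @return Integer number of days.
#' @export
marketing_interval_days <- function(season) {
  season <- match.arg(season, .season_names, several.ok = TRUE)
  unname(.marketing_interval[season])
}

#' Fraction of a farmer population marketing on one half-day
#'
#' Independent (non-aggregating) farmers spread their trips over both
#' sessions, so the per-half-day fraction is `1 / (2 * interval)`. Scheme
#' aggregation happens only in the morning, so the whole `1 / interval`
#' daily fraction falls on morning sessions and none on afternoons. Either
#' way the fractions over one full interval sum to 1.
#'
#' @param season season name.
#' @param loop `TRUE` for the aggregation (morning-only) schedule.
#' @param phase `"morning"` or `"afternoon"`.
#' @return Fraction of the population marketing on that half-day.
#' @export
marketing_fraction <- function(season, loop = FALSE,
                               phase = c("morning", "afternoon")) {
  phase <- match.arg(phase)
  interval <- marketing_interval_days(season)
  if (loop) {
    if (phase == "morning") 1 / interval else 0
  } else {
    1 / (2 * interval)
  }
}

#' Build the half-day calendar for a simulation horizon
#'
#' Precomputes, for every half-day index, the calendar date, session phase,
#' season, marketing fractions and season/year start flags used by the
#' simulation loop. Seasons start at the first morning of October, March and
#' June; the model year starts October 1st.
#'
#' @param start,end inclusive horizon dates.
#' @return A `data.frame` with one row per half-day: `index`, `date`,
#'   `morning`, `month`, `season`, `mf_loop`, `mf_nonloop`,
#'   `season_start`, `year_start`, `day` (1-based day number).
#' @export
build_calendar <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (end < start) stop("`end` must not precede `start`", call. = FALSE)
  days <- seq(start, end, by = "day")
  n_days <- length(days)
  date <- rep(days, each = 2L)
  morning <- rep(c(TRUE, FALSE), times = n_days)
  month <- as.integer(format(date, "%m"))
  season_id <- .season_of_month[month]
  season <- .season_names[season_id]
  interval <- unname(.marketing_interval[season_id])
  mf_nonloop <- 1 / (2 * interval)
  mf_loop <- ifelse(morning, 1 / interval, 0)
  first_of_month <- as.integer(format(date, "%d")) == 1L
  season_start <- morning & first_of_month & month %in% c(10L, 3L, 6L)
  year_start <- morning & first_of_month & month == 10L
  data.frame(
    index = seq_len(2L * n_days),
    date = date,
    morning = morning,
    month = month,
    season = season,
    mf_loop = mf_loop,
    mf_nonloop = mf_nonloop,
    season_start = season_start,
    year_start = year_start,
    day = rep(seq_len(n_days), each = 2L)
  )
}
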