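#' Season-definition settings
#'
#' The main pollen season (MPS) is defined by the cumulative-percentage
#' method: it opens on the day the running sum of daily concentrations
#' reaches `start_percent` of the annual total and closes on the day it
#' reaches `end_percent`, so the defaults retain the central 95% of the
#' year's pollen.
#'
#' @param start_percent Fraction of the annual total at which the season
#'   opens (default 0.025).
#' @param end_percent Fraction at which it closes (default 0.975).
#' @param min_day_availability Minimum fraction of a day's sampling
#'   intervals that must be present for the day to yield a concentration
#'   at all (default 0.5); gappier days are marked missing.
#' @return A list of class `season_config`.
#' @export
season_config <- function(start_percent = 0.025, end_percent = 0.975,
                          min_day_availability = 0.5) {
  assert(is.numeric(start_percent) && is.numeric(end_percent) &&
           start_percent > 0 && start_percent < end_percent &&
           end_percent < 1,
         "need 0 < start_percent < end_percent < 1")
  assert(is_probability(min_day_availability),
         "`min_day_availability` must lie in [0, 1]")
  structure(list(start_percent = start_percent, end_percent = end_percent,
                 min_day_availability = min_day_availability),
            class = "season_config")
}

#' Collapse interval records to daily mean concentrations
#'
#' The daily concentration of a taxon is the grains counted over the
#' day's *present* intervals divided by the air volume those intervals
#' actually sampled, so partially sampled days are unbiased rather than
#' deflated. A day's availability is the fraction of its sampling
#' intervals with any record; days below `min_day_availability` are
#' marked missing (`NA`), never zero.
#'
#' @param records Interval-record tibble (`date`, `interval_index`,
#'   `taxon`, `count`, `volume`).
#' @param cfg A [season_config()].
#' @param intervals_per_day Nominal number of intervals per day
#'   (default 8).
#'
#' @return A wide tibble: `date`, `availability`, then one numeric
#'   column per taxon (grains/m^3). Only dates with at least one record
#'   appear; absent dates are implicit missing days.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   device_id = "pomo", date = as.Date("2018-04-01"),
#'   interval_index = 0:7, taxon = "Betula", count = 30L, volume = 3
#' )
#' daily_concentrations(recs) # 240 grains / 24 m^3 = 10 grains/m^3
daily_concentrations <- function(records, cfg = season_config(),
                                 intervals_per_day = 8L) {
  assert(all(c("date", "interval_index", "taxon", "count", "volume") %in%
               names(records)),
         "`records` must have date, interval_index, taxon, count, volume")
  assert(all(records$volume > 0), "record volumes must be positive")
  dup <- records %>%
    dplyr::count(.data$date, .data$interval_index, .data$taxon) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate records for %d (date, interval, taxon) combination(s), first: %s interval %d %s",
      nrow(dup), dup$date[1], dup$interval_index[1], dup$taxon[1]))
  }
  availability <- records %>%
    dplyr::distinct(.data$date, .data$interval_index) %>%
    dplyr::count(.data$date, name = "n_intervals") %>%
    dplyr::mutate(availability = .data$n_intervals / intervals_per_day)
  daily <- records %>%
    dplyr::group_by(.data$date, .data$taxon) %>%
    dplyr::summarise(concentration = sum(.data$count) / sum(.data$volume),
                     .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "taxon",
                       values_from = "concentration") %>%
    dplyr::left_join(availability[c("date", "availability")], by = "date") %>%
    dplyr::relocate("availability", .after = "date") %>%
    dplyr::arrange(.data$date)
  low <- daily$availability < cfg$min_day_availability
  taxa <- taxon_columns(daily)
  daily[low, taxa] <- NA_real_
  daily
}

#' Extract main-pollen-season traits from one taxon-year series
#'
#' Applies the 95% cumulative method to one calendar year of daily
#' concentrations: the season starts on the first day whose inclusive
#' cumulative sum reaches `start_percent` of the Annual Pollen Integral
#' (API, the sum of all daily values) *and* that itself carries pollen,
#' and ends on the first day reaching `end_percent` under the same
#' condition, so zero-pollen days can never open or close a season. The
#' peak is the earliest day of maximum concentration. Missing days count
#' as zero in the cumulation but are tallied in `n_missing_days`. A year
#' with no pollen at all yields `defined = FALSE` and all-`NA` dates.
#'
#' @param dates `Date` vector covering one calendar year (need not be
#'   complete; gaps count as missing days).
#' @param values Daily concentrations aligned with `dates`; `NA` for
#'   missing days.
#' @param cfg A [season_config()].
#' @param taxon Optional taxon label carried into the output.
#'
#' @return A one-row tibble: `taxon`, `year`, `start_date`, `peak_date`,
#'   `end_date`, `duration_days`, `annual_pollen_integral`,
#'   `peak_value`, `n_missing_days`, `defined`.
#' @export
#' @examples
#' d <- as.Date("2018-03-31") + 1:9
#' main_pollen_season(d, c(0, 1, 4, 10, 20, 10, 4, 1, 0))
main_pollen_season <- function(dates, values, cfg = season_config(),
                               taxon = NA_character_) {
  dates <- as.Date(dates)
  assert(length(dates) == length(values),
         "`dates` and `values` must have equal length")
  assert(!anyDuplicated(dates), "duplicate dates in series")
  years <- unique(as.integer(format(dates, "%Y")))
  assert(length(years) == 1L, "series must cover a single calendar year")
  ord <- order(dates)
  dates <- dates[ord]
  values <- values[ord]

  n_missing <- sum(is.na(values))
  v <- ifelse(is.na(values), 0, values)
  assert(all(v >= 0), "concentrations must be non-negative")
  api <- sum(v)
  undefined <- tibble::tibble(
    taxon = taxon, year = years,
    start_date = as.Date(NA), peak_date = as.Date(NA),
    end_date = as.Date(NA), duration_days = NA_integer_,
    annual_pollen_integral = api, peak_value = if (api > 0) max(v) else 0,
    n_missing_days = n_missing, defined = FALSE
  )
  if (api <= 0) return(undefined)

  cum <- cumsum(v)
  # tiny relative slack so threshold attainment is robust to float
  # round-off (e.g. under rescaling of the whole series)
  eps <- api * 1e-12
  start_i <- which(cum >= cfg$start_percent * api - eps & v > 0)[1]
  end_i <- which(cum >= cfg$end_percent * api - eps & v > 0)[1]
  peak_i <- which.max(v) # earliest date on ties
  tibble::tibble(
    taxon = taxon, year = years,
    start_date = dates[start_i], peak_date = dates[peak_i],
    end_date = dates[end_i],
    duration_days = as.integer(dates[end_i] - dates[start_i]) + 1L,
    annual_pollen_integral = api, peak_value = max(v),
    n_missing_days = n_missing, defined = TRUE
  )
}

#' Season traits for every taxon-year in a daily table
#'
#' Splits a wide daily-concentration table by taxon and calendar year,
#' pads each year to its full date range (absent rows count as missing
#' days), and extracts the main-pollen-season traits of each series.
#'
#' @param daily Wide daily table (`date`, optional `availability`, one
#'   column per taxon), e.g. from [daily_concentrations()] or
#'   [simulate_hirst_series()].
#' @param cfg A [season_config()].
#' @return A tibble with one [main_pollen_season()] row per
#'   (taxon, year), ordered by taxon then year.
#' @export
annual_traits <- function(daily, cfg = season_config()) {
  assert("date" %in% names(daily), "`daily` must have a `date` column")
  taxa <- taxon_columns(daily)
  assert(length(taxa) > 0, "`daily` has no taxon columns")
  long <- daily %>%
    dplyr::select(dplyr::all_of(c("date", taxa))) %>%
    tidyr::pivot_longer(dplyr::all_of(taxa), names_to = "taxon",
                        values_to = "value") %>%
    dplyr::mutate(year = as.integer(format(.data$date, "%Y")))
  combos <- long %>%
    dplyr::distinct(.data$taxon, .data$year) %>%
    dplyr::arrange(.data$taxon, .data$year)
  purrr::pmap_dfr(combos, function(taxon, year) {
    series <- long %>%
      dplyr::filter(.data$taxon == !!taxon, .data$year == !!year)
    full <- tibble::tibble(date = period_days(year)) %>%
      dplyr::left_join(series[c("date", "value")], by = "date")
    main_pollen_season(full$date, full$value, cfg = cfg, taxon = taxon)
  })
}
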