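#' Fraction of 3-hourly intervals with data
#'
#' Online data availability is the share of (date, interval) slots in the
#' period for which the device reported at least one record of any taxon.
#' Slots outside the record range simply count as unavailable.
#'
#' @param records Interval-record tibble (see
#'   [simulate_pomo_records()]): needs `date` and `interval_index`.
#' @param period A year (e.g. `2018`) or a length-2 inclusive date range.
#' @param intervals_per_day Number of sampling intervals per day
#'   (default 8).
#'
#' @return A single fraction in \[0, 1\].
#' @export
interval_availability <- function(records, period, intervals_per_day = 8L) {
  days <- period_days(period)
  assert(length(days) > 0, "`period` must be non-empty")
  if (nrow(records) > 0 &&
      (min(records$date) < days[1] || max(records$date) > days[length(days)])) {
    warn("some records fall outside `period`; they are ignored")
  }
  present <- records %>%
    dplyr::filter(.data$date >= days[1],
                  .data$date <= days[length(days)]) %>%
    dplyr::distinct(.data$date, .data$interval_index)
  nrow(present) / (intervals_per_day * length(days))
}

#' Dates on which a device produced no data at all
#'
#' A whole-day failure is a calendar date with zero records across all
#' taxa and intervals — the monitor was down, as opposed to reporting
#' zero pollen.
#'
#' @inheritParams interval_availability
#' @return A `Date` vector (sorted) of failure dates within the period.
#' @export
whole_day_failures <- function(records, period) {
  days <- period_days(period)
  reported <- unique(records$date[records$date >= days[1] &
                                    records$date <= days[length(days)]])
  sort(days[!(days %in% reported)])
}

#' Count whole-day failures inside each taxon's main pollen season
#'
#' Intersects a set of failure dates with each taxon's season window
#' (closed on both ends) and summarises the per-taxon counts by their
#' median (even counts: mean of the central pair). Taxa whose season is
#' undefined are excluded from the median and reported.
#'
#' @param failures `Date` vector of whole-day failures (see
#'   [whole_day_failures()]).
#' @param seasons Season-trait tibble (see [annual_traits()]): needs
#'   `taxon`, `start_date`, `end_date` and, optionally, `defined`.
#'
#' @return A list with `per_taxon` (tibble `taxon`, `gap_days`),
#'   `median_gaps` (numeric) and `excluded_taxa` (character).
#' @export
#' @examples
#' seasons <- tibble::tibble(
#'   taxon = c("Betula", "Poaceae"),
#'   start_date = as.Date(c("2018-04-01", "2018-05-20")),
#'   end_date = as.Date(c("2018-05-05", "2018-07-31"))
#' )
#' failures <- as.Date(c("2018-04-10", "2018-06-01", "2018-06-02"))
#' gaps_within_season(failures, seasons)
gaps_within_season <- function(failures, seasons) {
  needed <- c("taxon", "start_date", "end_date")
  missing <- setdiff(needed, names(seasons))
  assert(length(missing) == 0,
         paste0("`seasons` is missing column(s): ",
                paste(missing, collapse = ", ")))
  defined <- if ("defined" %in% names(seasons)) seasons$defined else
    rep(TRUE, nrow(seasons))
  defined <- defined & !is.na(seasons$start_date) & !is.na(seasons$end_date)
  ok <- seasons[defined, ]
  assert(all(ok$start_date <= ok$end_date),
         "season windows must satisfy start_date <= end_date")
  failures <- as.Date(failures)
  per_taxon <- ok %>%
    dplyr::rowwise() %>%
    dplyr::mutate(gap_days = sum(failures >= .data$start_date &
                                   failures <= .data$end_date)) %>%
    dplyr::ungroup() %>%
    dplyr::select("taxon", "gap_days")
  list(
    per_taxon = per_taxon,
    median_gaps = if (nrow(per_taxon) > 0) median(per_taxon$gap_days)
                  else NA_real_,
    excluded_taxa = seasons$taxon[!defined]
  )
}

#' Full reliability report for one device
#'
#' Bundles overall interval availability, the set of whole-day failures,
#' and the per-taxon failure counts within each main pollen season, as in
#' a device intercomparison's reliability assessment.
#'
#' @inheritParams interval_availability
#' @inheritParams gaps_within_season
#' @param device_id Optional device label; taken from `records` if absent.
#' @return An object of class `gap_report` (a list) with fields
#'   `device_id`, `period`, `interval_availability`,
#'   `whole_day_failures`, `per_taxon_gaps_in_season`, `median_gaps` and
#'   `excluded_taxa`.
#' @export
gap_report <- function(records, period, seasons, device_id = NULL,
                       intervals_per_day = 8L) {
  device_id <- device_id %||%
    (if (nrow(records) > 0) records$device_id[1] else NA_character_)
  failures <- whole_day_failures(records, period)
  in_season <- gaps_within_season(failures, seasons)
  structure(
    list(
      device_id = device_id,
      period = as_period(period),
      interval_availability = interval_availability(records, period,
                                                    intervals_per_day),
      whole_day_failures = failures,
      per_taxon_gaps_in_season = in_season$per_taxon,
      median_gaps = in_season$median_gaps,
      excluded_taxa = in_season$excluded_taxa
    ),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> device %s, %s to %s\n", x$device_id,
              x$period[1], x$period[2]))
  cat(sprintf("  3-hourly availability: %.1f%%\n",
              100 * x$interval_availability))
  cat(sprintf("  whole-day failures: %d\n", length(x$whole_day_failures)))
  cat(sprintf("  median in-season gap days over %d taxa: %s\n",
              nrow(x$per_taxon_gaps_in_season), format(x$median_gaps)))
  if (length(x$excluded_taxa) > 0) {
    cat("  excluded (undefined season):",
        paste(x$excluded_taxa, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy gap_report
#' @export
tidy.gap_report <- function(x, ...) {
  x$per_taxon_gaps_in_season
}

#' @method glance gap_report
#' @export
glance.gap_report <- function(x, ...) {
  tibble::tibble(
    device_id = x$device_id,
    period_start = x$period[1],
    period_end = x$period[2],
    interval_availability = x$interval_availability,
    n_whole_day_failures = length(x$whole_day_failures),
    median_gaps = x$median_gaps,
    n_taxa = nrow(x$per_taxon_gaps_in_season),
    n_excluded_taxa = length(x$excluded_taxa)
  )
}
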