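pomo_required_columns <- c("object_id", "device_id", "date",
                           "interval_index", "predicted")

io_delim <- function(dialect = c("comma", "semicolon")) {
  switch(match.arg(dialect), comma = ",", semicolon = ";")
}

#' Read a particle-object table exported by an automatic monitor
#'
#' Automatic monitors export one CSV row per detected object with the
#' device's predicted label and, after expert review, optionally a manual
#' label. The canonical schema requires `object_id`, `device_id`, `date`
#' (ISO 8601), `interval_index` (0--7 for the 3-h blocks) and
#' `predicted`; a `manual` column and any further metadata columns are
#' preserved as-is.
#'
#' @param path Path to the CSV file.
#' @param dialect Field separator: `"comma"` (default) or `"semicolon"`.
#' @param vocabulary Optional character vector of known labels; predicted
#'   labels outside it are reported via a warning and returned in the
#'   `unknown_labels` attribute, never silently dropped.
#'
#' @return A tibble of labelled objects. Attribute `unknown_labels` holds
#'   any out-of-vocabulary predicted labels (with their counts).
#' @export
read_pomo_object_table <- function(path, dialect = c("comma", "semicolon"),
                                   vocabulary = NULL) {
  assert(file.exists(path), sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = io_delim(dialect),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(pomo_required_columns, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("object table is missing required column(s): %s",
                  paste(sQuote(missing), collapse = ", ")))
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) & !is.na(raw$date))
  if (length(bad) > 0) {
    abort(sprintf("unparseable date %s in row %d of %s",
                  sQuote(raw$date[bad[1]]), bad[1], path))
  }
  out <- raw
  out$date <- dates
  out$interval_index <- as.integer(raw$interval_index)
  unknown <- character()
  if (!is.null(vocabulary)) {
    outside <- !(out$predicted %in% vocabulary) & !is.na(out$predicted)
    if (any(outside)) {
      unknown <- sort(unique(out$predicted[outside]))
      warn(sprintf(
        "%d object(s) carry predicted labels outside the vocabulary: %s",
        sum(outside), paste(unknown, collapse = ", ")))
    }
  }
  attr(out, "unknown_labels") <- unknown
  out
}

#' Write a particle-object table
#'
#' @param objects Tibble of labelled objects (see
#'   [read_pomo_object_table()] for the canonical columns).
#' @param path Output CSV path.
#' @inheritParams read_pomo_object_table
#' @return `path`, invisibly.
#' @export
write_pomo_object_table <- function(objects, path,
                                    dialect = c("comma", "semicolon")) {
  missing <- setdiff(pomo_required_columns, names(objects))
  assert(length(missing) == 0,
         paste0("object table is missing required column(s): ",
                paste(missing, collapse = ", ")))
  readr::write_delim(objects, path, delim = io_delim(dialect), na = "")
  invisible(path)
}

#' Read a daily pollen-concentration table
#'
#' The table holds one ISO-8601 `date` column plus one numeric column per
#' taxon (daily mean grains/m^3). Missing days may be encoded as absent
#' rows or as empty cells; both are preserved as `NA`, which is distinct
#' from a measured zero. Duplicate dates are an error; rows are returned
#' sorted by date.
#'
#' @inheritParams read_pomo_object_table
#' @return A wide tibble: `date` plus numeric taxon columns.
#' @export
read_daily_table <- function(path, dialect = c("comma", "semicolon")) {
  assert(file.exists(path), sprintf("file not found: %s", path))
  out <- readr::read_delim(path, delim = io_delim(dialect), progress = FALSE,
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             date = readr::col_date(),
                             .default = readr::col_double()
                           ))
  assert("date" %in% names(out), "daily table must have a `date` column")
  if (anyDuplicated(out$date)) {
    abort(sprintf("duplicate date(s) in %s: %s", path,
                  paste(unique(out$date[duplicated(out$date)]),
                        collapse = ", ")))
  }
  dplyr::arrange(out, .data$date)
}

#' Write a daily pollen-concentration table
#'
#' Missing values are written as empty cells (never 0), keeping "no data"
#' distinguishable from "no pollen" on the round trip.
#'
#' @param daily Wide daily table (`date` + numeric columns).
#' @param path Output CSV path.
#' @inheritParams read_pomo_object_table
#' @return `path`, invisibly.
#' @export
write_daily_table <- function(daily, path, dialect = c("comma", "semicolon")) {
  assert("date" %in% names(daily), "daily table must have a `date` column")
  assert(!anyDuplicated(daily$date), "duplicate dates in daily table")
  readr::write_delim(daily, path, delim = io_delim(dialect), na = "")
  invisible(path)
}

#' Round-trip a daily table through disk
#'
#' Writes the table to a temporary (or given) file and reads it back;
#' useful to verify that the CSV dialect preserves values and the
#' missingness pattern.
#'
#' @inheritParams write_daily_table
#' @param path File to use; defaults to a temporary file.
#' @return The re-read tibble.
#' @export
round_trip_daily_table <- function(daily, path = tempfile(fileext = ".csv"),
                                   dialect = c("comma", "semicolon")) {
  write_daily_table(daily, path, dialect = dialect)
  read_daily_table(path, dialect = dialect)
}
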