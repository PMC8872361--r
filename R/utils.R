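# internal helpers shared across modules

assert <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' @noRd
#' Deterministically derive a sub-seed from a base seed and a string key,
#' so each device/operation consumes an independent stream while the whole
#' run is controlled by one integer. Kept below 2^31 - 1.
split_seed <- function(seed, key) {
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) + 2654435 * h) %% 2147483629)
}

# Interpret a period as an inclusive date range: either a length-2 vector
# coercible to Date, or a single year (all of that calendar year).
as_period <- function(period) {
  if (length(period) == 1L && is.numeric(period)) {
    year <- as.integer(period)
    return(c(
      as.Date(sprintf("%d-01-01", year)),
      as.Date(sprintf("%d-12-31", year))
    ))
  }
  assert(length(period) == 2L, "`period` must be a year or a length-2 date range")
  range <- as.Date(period)
  assert(!anyNA(range), "`period` contains unparseable dates")
  assert(range[1] <= range[2], "`period` start must not be after its end")
  range
}

period_days <- function(period) {
  range <- as_period(period)
  seq(range[1], range[2], by = "day")
}

# taxon columns of a wide daily-concentration table: everything except the
# reserved `date` and `availability` columns
taxon_columns <- function(daily) {
  setdiff(names(daily), c("date", "availability"))
}
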