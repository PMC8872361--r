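#' Describe one taxon's pollen season
#'
#' A season model is the ground truth the simulator draws from: a unimodal
#' (skew-normal) daily concentration curve for one taxon in one calendar
#' year, scaled so the whole year integrates to a chosen Annual Pollen
#' Integral (API).
#'
#' @param taxon Taxon label, e.g. `"Betula"` or `"Poaceae"`.
#' @param year Calendar year the model applies to.
#' @param peak_day Day of year (1--366) on which the curve peaks.
#' @param spread_days Scale of the curve in days; roughly, the season's
#'   half-width. Must be positive.
#' @param skew Shape parameter of the skew-normal curve; 0 gives a
#'   symmetric season, positive values a long right tail (late-season
#'   stragglers), negative a long left tail.
#' @param annual_integral Target API in pollen day/m^3; the generated
#'   daily series sums to this value exactly after discretisation.
#' @param baseline Constant out-of-season concentration floor in
#'   grains/m^3 (default 0). The whole curve (baseline included) is
#'   rescaled so the annual sum still equals `annual_integral`, so
#'   `baseline * 365` must stay below `annual_integral`.
#'
#' @return A one-row tibble; bind rows of several calls to describe a
#'   multi-taxon year and pass the result to [simulate_true_seasons()].
#' @export
#' @examples
#' season_model("Betula", 2018, peak_day = 105, spread_days = 12,
#'               annual_integral = 4000)
season_model <- function(taxon, year, peak_day, spread_days, skew = 0,
                         annual_integral, baseline = 0) {
  assert(is.character(taxon) && length(taxon) == 1L && nzchar(taxon),
         "`taxon` must be a non-empty string")
  assert(is.numeric(peak_day) && peak_day >= 1 && peak_day <= 366,
         "`peak_day` must be a day of year in 1..366")
  assert(is.numeric(spread_days) && spread_days > 0,
         "`spread_days` must be > 0")
  assert(is.numeric(annual_integral) && annual_integral > 0,
         "`annual_integral` must be > 0")
  assert(is.numeric(baseline) && baseline >= 0, "`baseline` must be >= 0")
  assert(baseline * 365 < annual_integral,
         "`baseline` is too high for the requested `annual_integral`")
  tibble::tibble(
    taxon = taxon, year = as.integer(year), peak_day = as.numeric(peak_day),
    spread_days = as.numeric(spread_days), skew = as.numeric(skew),
    annual_integral = as.numeric(annual_integral),
    baseline = as.numeric(baseline)
  )
}

#' Describe a monitoring device
#'
#' Captures everything the simulator needs to emulate one sampler: its
#' sampling regime (continuous low-volume, like a Hirst-type trap at
#' 0.6 m^3/h, or intermittent high-volume, like an automatic monitor
#' drawing 3 m^3 per 3-h interval), per-taxon capture efficiency, a
#' row-stochastic label confusion matrix, and two-level data-gap
#' probabilities (whole-day breakdowns and isolated missed intervals).
#'
#' @param device_id Label for the device, e.g. `"hirst"` or `"pomo-lfu"`.
#' @param mode `"continuous"` (requires `flow`) or `"intermittent"`
#'   (requires `interval_volume`).
#' @param flow Air flow in m^3/h for continuous devices (Hirst standard:
#'   0.6).
#' @param interval_volume Air volume in m^3 sampled in each interval by
#'   intermittent devices (BAA500 standard: 3, i.e. 24 m^3/day).
#' @param intervals_per_day Number of sampling intervals per day
#'   (default 8, i.e. 3-hourly).
#' @param efficiency Capture-efficiency multiplier relative to the true
#'   concentration; a single number or a named per-taxon vector.
#' @param confusion Row-stochastic matrix mapping true labels (rows) to
#'   predicted labels (columns); columns normally include all taxa plus
#'   `"Varia"` and `"NoPollen"`. Rows must sum to 1 within 1e-9. See
#'   [identity_confusion()].
#' @param dispersion Coefficient of variation of a day-level
#'   multiplicative capture-efficiency fluctuation (gamma with mean 1),
#'   shared by all taxa within a day. 0 (default) means pure Poisson
#'   counting noise; positive values add the day-to-day capture
#'   variability real samplers show, making counts negative-binomial
#'   marginally.
#' @param p_interval_gap Probability that any single interval is lost,
#'   given the day as a whole functioned.
#' @param p_day_gap Probability of a whole-day failure (no data at all).
#' @param seed Integer seed controlling all of this device's randomness;
#'   sub-seeds are derived per operation.
#'
#' @return An object of class `device_model`.
#' @export
#' @examples
#' hirst <- device_model("hirst", "continuous", flow = 0.6)
#' pomo  <- device_model("pomo", "intermittent", interval_volume = 3,
#'                       confusion = identity_confusion(c("Betula", "Poaceae")),
#'                       p_interval_gap = 0.05, p_day_gap = 0.1)
device_model <- function(device_id,
                         mode = c("continuous", "intermittent"),
                         flow = NULL,
                         interval_volume = NULL,
                         intervals_per_day = 8L,
                         efficiency = 1,
                         confusion = NULL,
                         dispersion = 0,
                         p_interval_gap = 0,
                         p_day_gap = 0,
                         seed = 1L) {
  mode <- match.arg(mode)
  assert(is.character(device_id) && length(device_id) == 1L,
         "`device_id` must be a single string")
  if (mode == "continuous") {
    assert(is.numeric(flow) && length(flow) == 1L && flow > 0,
           "continuous mode requires a positive `flow` (m^3/h)")
  } else {
    assert(is.numeric(interval_volume) && length(interval_volume) == 1L &&
             interval_volume > 0,
           "intermittent mode requires a positive `interval_volume` (m^3)")
  }
  assert(is_probability(p_interval_gap),
         "`p_interval_gap` must be a probability in [0, 1]")
  assert(is_probability(p_day_gap),
         "`p_day_gap` must be a probability in [0, 1]")
  assert(all(efficiency >= 0), "`efficiency` multipliers must be >= 0")
  assert(is.numeric(dispersion) && length(dispersion) == 1L &&
           dispersion >= 0, "`dispersion` must be a non-negative CV")
  if (!is.null(confusion)) validate_confusion(confusion)
  structure(
    list(
      device_id = device_id, mode = mode, flow = flow,
      interval_volume = interval_volume,
      intervals_per_day = as.integer(intervals_per_day),
      efficiency = efficiency, confusion = confusion,
      dispersion = dispersion,
      p_interval_gap = p_interval_gap, p_day_gap = p_day_gap,
      seed = as.integer(seed)
    ),
    class = "device_model"
  )
}

#' @export
print.device_model <- function(x, ...) {
  sampling <- if (x$mode == "continuous") {
    sprintf("continuous, %.2g m^3/h", x$flow)
  } else {
    sprintf("intermittent, %g x %.2g m^3/day", x$intervals_per_day,
            x$interval_volume)
  }
  cat(sprintf("<device_model> %s (%s)\n", x$device_id, sampling))
  cat(sprintf("  gaps: p_day = %g, p_interval = %g; seed %d\n",
              x$p_day_gap, x$p_interval_gap, x$seed))
  if (!is.null(x$confusion)) {
    cat(sprintf("  confusion: %d true labels -> %d predicted labels\n",
                nrow(x$confusion), ncol(x$confusion)))
  }
  invisible(x)
}

validate_confusion <- function(confusion) {
  assert(is.matrix(confusion) && is.numeric(confusion),
         "`confusion` must be a numeric matrix")
  assert(!is.null(rownames(confusion)) && !is.null(colnames(confusion)),
         "`confusion` must have true labels as rownames and predicted labels as colnames")
  assert(all(confusion >= 0) && all(confusion <= 1),
         "`confusion` entries must be probabilities in [0, 1]")
  sums <- rowSums(confusion)
  assert(all(abs(sums - 1) <= 1e-9),
         "each `confusion` row must sum to 1 (tolerance 1e-9)")
  invisible(confusion)
}

#' Build an identity (perfect-classifier) confusion matrix
#'
#' @param taxa Character vector of true taxon labels.
#' @param extra Additional predicted-only sink classes appended as
#'   all-zero columns (default `"Varia"` and `"NoPollen"`).
#' @return A row-stochastic matrix suitable for [device_model()].
#' @export
identity_confusion <- function(taxa, extra = c("Varia", "NoPollen")) {
  assert(length(taxa) > 0 && !anyDuplicated(taxa), "`taxa` must be unique labels")
  vocab <- c(taxa, setdiff(extra, taxa))
  m <- matrix(0, nrow = length(taxa), ncol = length(vocab),
              dimnames = list(taxa, vocab))
  m[cbind(taxa, taxa)] <- 1
  m
}

# efficiency multiplier for one taxon (scalar efficiency applies to all)
efficiency_for <- function(dev, taxon) {
  eff <- dev$efficiency
  if (length(eff) == 1L && is.null(names(eff))) return(unname(eff))
  assert(taxon %in% names(eff),
         sprintf("no efficiency given for taxon '%s'", taxon))
  unname(eff[[taxon]])
}
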