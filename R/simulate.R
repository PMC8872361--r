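# Skew-normal density without location/scale applied:
# f(z) = 2 phi(z) Phi(alpha z). Used as the season curve family.
skewnorm_density <- function(x, location = 0, scale = 1, shape = 0) {
  z <- (x - location) / scale
  2 / scale * dnorm(z) * pnorm(shape * z)
}

# Mode of the standardised skew-normal (location 0, scale 1); 0 when
# shape = 0, otherwise found numerically (no closed form exists).
skewnorm_mode <- function(shape) {
  if (shape == 0) return(0)
  optimize(function(z) skewnorm_density(z, shape = shape),
           interval = c(-3, 3), maximum = TRUE,
           tol = 1e-8)$maximum
}

# day-level multiplicative capture fluctuation: gamma with mean 1 and
# the requested coefficient of variation (all 1 when dispersion = 0)
day_capture_factor <- function(n_days, dispersion) {
  if (is.null(dispersion) || dispersion == 0) return(rep(1, n_days))
  shape <- 1 / dispersion^2
  stats::rgamma(n_days, shape = shape, rate = shape)
}

season_curve <- function(doy, peak_day, spread_days, skew, annual_integral,
                         baseline) {
  location <- peak_day - spread_days * skewnorm_mode(skew)
  d <- skewnorm_density(doy, location = location, scale = spread_days,
                        shape = skew)
  n <- length(doy)
  # rescale after discretisation so the annual sum (baseline included)
  # equals the requested integral exactly
  scale_factor <- (annual_integral - baseline * n) / sum(d)
  baseline + scale_factor * d
}

#' Generate true daily pollen concentrations for a set of season models
#'
#' Evaluates each taxon's skew-normal season curve on every day of the
#' calendar year and rescales it so the annual sum equals the model's
#' `annual_integral`. This is the shared ground truth that both simulated
#' devices then observe with their own noise, efficiency and gaps.
#'
#' @param models A tibble of season models, one row per taxon
#'   (see [season_model()]); all rows must refer to `year`.
#' @param year Calendar year to simulate.
#'
#' @return A wide tibble with a `date` column covering the full year and
#'   one non-negative numeric column per taxon (grains/m^3).
#' @export
#' @examples
#' models <- season_model("Betula", 2018, 105, 12, annual_integral = 4000)
#' true <- simulate_true_seasons(models, 2018)
#' sum(true$Betula) # = 4000
simulate_true_seasons <- function(models, year) {
  assert(is.data.frame(models) && nrow(models) > 0,
         "`models` must be a data frame with at least one season model")
  needed <- c("taxon", "year", "peak_day", "spread_days", "skew",
              "annual_integral", "baseline")
  missing <- setdiff(needed, names(models))
  assert(length(missing) == 0,
         paste0("`models` is missing column(s): ",
                paste(missing, collapse = ", ")))
  assert(all(models$year == year),
         "all season models must refer to the requested `year`")
  key <- paste(models$taxon, models$year)
  assert(!anyDuplicated(key),
         "duplicate (taxon, year) season models are not allowed")

  dates <- period_days(year)
  doy <- seq_along(dates)
  out <- tibble::tibble(date = dates)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    out[[m$taxon]] <- season_curve(doy, m$peak_day, m$spread_days, m$skew,
                                   m$annual_integral, m$baseline)
  }
  out
}

#' Simulate daily observations of a continuous (Hirst-type) sampler
#'
#' Each day the device samples `24 * flow` cubic metres; the number of
#' grains captured per taxon is Poisson with mean
#' `true concentration x efficiency x daily volume`, and the reported
#' concentration is that count divided by the daily volume. If the
#' device has a positive `dispersion`, the mean is first multiplied by a
#' day-level gamma fluctuation (mean 1, CV `dispersion`) shared across
#' taxa. All draws are controlled by the device's seed, so repeated
#' calls are identical.
#'
#' @param true Wide tibble of true daily concentrations, as produced by
#'   [simulate_true_seasons()].
#' @param dev A continuous-mode [device_model()].
#'
#' @return A tibble of the same shape as `true` with observed daily
#'   concentrations (grains/m^3).
#' @export
simulate_hirst_series <- function(true, dev) {
  assert(inherits(dev, "device_model"), "`dev` must be a device_model")
  assert(dev$mode == "continuous",
         "`simulate_hirst_series()` requires a continuous-mode device")
  assert(dev$flow > 0, "device `flow` must be positive")
  taxa <- taxon_columns(true)
  daily_volume <- 24 * dev$flow
  out <- tibble::tibble(date = true$date)
  withr::with_seed(split_seed(dev$seed, paste0("hirst/", dev$device_id)), {
    day_factor <- day_capture_factor(nrow(true), dev$dispersion)
    for (tx in taxa) {
      lambda <- true[[tx]] * efficiency_for(dev, tx) * daily_volume *
        day_factor
      obs <- rep(NA_real_, length(lambda))
      ok <- !is.na(lambda)
      obs[ok] <- rpois(sum(ok), lambda[ok]) / daily_volume
      out[[tx]] <- obs
    }
  })
  out
}

#' Simulate interval records of an intermittent (automatic) sampler
#'
#' Emulates a monitor that draws a fixed air volume in each of 8 daily
#' 3-h intervals. For every day a whole-day failure is first drawn with
#' probability `p_day_gap` (all intervals lost); on surviving days each
#' interval is independently lost with probability `p_interval_gap`.
#' Surviving intervals carry Poisson counts with mean
#' `true x efficiency x interval_volume`. Lost intervals produce *no*
#' record (absence, never a zero count), so downstream code can tell
#' "no data" from "no pollen"; every loss is written to the gap log.
#'
#' @param true Wide tibble of true daily concentrations (no missing
#'   values), as from [simulate_true_seasons()].
#' @param dev An intermittent-mode [device_model()].
#'
#' @return A list with `records` (tibble: `device_id`, `date`,
#'   `interval_index` 0--7, `taxon`, `count`, `volume`) and `gap_log`
#'   (tibble: `date`, `interval_index` -- `NA` for whole-day failures --
#'   and `type` `"day"` or `"interval"`).
#' @export
simulate_pomo_records <- function(true, dev) {
  assert(inherits(dev, "device_model"), "`dev` must be a device_model")
  assert(dev$mode == "intermittent",
         "`simulate_pomo_records()` requires an intermittent-mode device")
  assert(is_probability(dev$p_day_gap) && is_probability(dev$p_interval_gap),
         "gap probabilities must lie in [0, 1]")
  taxa <- taxon_columns(true)
  assert(!anyNA(true[taxa]), "`true` concentrations must be complete")
  n_days <- nrow(true)
  ipd <- dev$intervals_per_day
  vol <- dev$interval_volume

  withr::with_seed(split_seed(dev$seed, paste0("pomo/", dev$device_id)), {
    day_gap <- runif(n_days) < dev$p_day_gap
    interval_gap <- matrix(runif(n_days * ipd) < dev$p_interval_gap,
                           nrow = n_days, ncol = ipd)
    day_factor <- day_capture_factor(n_days, dev$dispersion)
    counts <- lapply(taxa, function(tx) {
      lambda <- true[[tx]] * efficiency_for(dev, tx) * vol * day_factor
      matrix(rpois(n_days * ipd, rep(lambda, ipd)), nrow = n_days, ncol = ipd)
    })
  })
  names(counts) <- taxa

  present <- !day_gap & !interval_gap # n_days x ipd
  idx <- which(present, arr.ind = TRUE)
  records <- purrr::map_dfr(taxa, function(tx) {
    tibble::tibble(
      device_id = dev$device_id,
      date = true$date[idx[, 1]],
      interval_index = as.integer(idx[, 2] - 1L),
      taxon = tx,
      count = as.integer(counts[[tx]][idx]),
      volume = vol
    )
  }) %>%
    dplyr::arrange(.data$date, .data$interval_index, .data$taxon)

  int_idx <- which(!day_gap & interval_gap, arr.ind = TRUE)
  gap_log <- dplyr::bind_rows(
    tibble::tibble(
      date = true$date[day_gap],
      interval_index = NA_integer_,
      type = rep("day", sum(day_gap))
    ),
    tibble::tibble(
      date = true$date[int_idx[, 1]],
      interval_index = as.integer(int_idx[, 2] - 1L),
      type = rep("interval", nrow(int_idx))
    )
  ) %>%
    dplyr::arrange(.data$date, .data$interval_index)

  list(records = records, gap_log = gap_log)
}

#' Generate labelled objects with known misclassification
#'
#' For each true label `t`, emits exactly `counts[t]` particle objects
#' whose manual (expert) label is `t` and whose device-predicted label is
#' sampled from row `t` of the device's confusion matrix. This mirrors the
#' manual re-identification of device-flagged objects used to score a
#' classifier, but with the true confusion known.
#'
#' @param counts Named integer vector: number of objects per true label.
#'   Every name must be a row of `dev$confusion`.
#' @param dev A [device_model()] with a confusion matrix.
#' @param dates Date(s) to stamp on the objects, recycled across objects
#'   (default a single mid-season date).
#'
#' @return A tibble of labelled objects: `object_id`, `device_id`,
#'   `date`, `interval_index`, `predicted`, `manual`.
#' @export
generate_labeled_objects <- function(counts, dev,
                                     dates = as.Date("2018-06-15")) {
  assert(inherits(dev, "device_model"), "`dev` must be a device_model")
  assert(!is.null(dev$confusion), "`dev` has no confusion matrix")
  assert(is.numeric(counts), "`counts` must be a named numeric vector")
  if (length(counts) == 0) {
    return(tibble::tibble(
      object_id = character(), device_id = character(),
      date = as.Date(character()), interval_index = integer(),
      predicted = character(), manual = character()
    ))
  }
  assert(!is.null(names(counts)) && all(nzchar(names(counts))),
         "`counts` must be named by true label")
  unknown <- setdiff(names(counts), rownames(dev$confusion))
  assert(length(unknown) == 0,
         paste0("label(s) missing from the confusion matrix: ",
                paste(unknown, collapse = ", ")))
  assert(all(counts >= 0), "`counts` must be non-negative")

  vocab <- colnames(dev$confusion)
  withr::with_seed(split_seed(dev$seed, paste0("objects/", dev$device_id)), {
    predicted <- unlist(lapply(names(counts), function(lab) {
      n <- as.integer(counts[[lab]])
      if (n == 0) return(character())
      sample(vocab, n, replace = TRUE, prob = dev$confusion[lab, ])
    }), use.names = FALSE)
  })
  manual <- rep(names(counts), times = as.integer(counts))
  n_total <- length(manual)
  tibble::tibble(
    object_id = sprintf("%s-%07d", dev$device_id, seq_len(n_total)),
    device_id = dev$device_id,
    date = rep_len(as.Date(dates), n_total),
    interval_index = as.integer((seq_len(n_total) - 1L) %%
                                  dev$intervals_per_day),
    predicted = predicted,
    manual = manual
  )
}
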