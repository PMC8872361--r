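# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities through a different route than
# the package (plain loops, numerical integration) so agreement is
# informative.

# Brute-force main-pollen-season oracle: walks the cumulative sum day by
# day with explicit loops; written before and independently of
# main_pollen_season().
oracle_mps <- function(values, lo = 0.025, hi = 0.975) {
  total <- sum(values)
  if (total <= 0) return(NULL)
  running <- 0
  start <- NA_integer_
  end <- NA_integer_
  for (i in seq_along(values)) {
    running <- running + values[i]
    if (is.na(start) && running >= lo * total && values[i] > 0) start <- i
    if (is.na(end) && running >= hi * total && values[i] > 0) end <- i
  }
  peak <- which(values == max(values))[1]
  list(start = start, peak = peak, end = end,
       duration = end - start + 1, api = total)
}

# Independent skew-normal machinery for quantile-day oracles: own density
# formula, continuous CDF by numerical integration, quantile by root
# finding. The package instead discretises to days and takes cumulative
# sums, so the two routes share no code path.
oracle_sn_density <- function(x, loc, scale, shape) {
  2 / scale * stats::dnorm((x - loc) / scale) *
    stats::pnorm(shape * (x - loc) / scale)
}

oracle_sn_quantile_day <- function(p, peak_day, spread, skew) {
  mode <- if (skew == 0) 0 else {
    stats::optimize(function(z) oracle_sn_density(z, 0, 1, skew),
                    interval = c(-3, 3), maximum = TRUE, tol = 1e-9)$maximum
  }
  loc <- peak_day - spread * mode
  cdf <- function(q) {
    stats::integrate(oracle_sn_density, lower = loc - 12 * spread,
                     upper = q, loc = loc, scale = spread, shape = skew,
                     rel.tol = 1e-10)$value
  }
  stats::uniroot(function(q) cdf(q) - p,
                 lower = loc - 12 * spread, upper = loc + 12 * spread,
                 tol = 1e-8)$root
}

# --- small fixtures -------------------------------------------------------

fx_models <- function(year = 2018) {
  dplyr::bind_rows(
    season_model("Alpha", year, peak_day = 80, spread_days = 10, skew = 0,
                 annual_integral = 3000),
    season_model("Beta", year, peak_day = 140, spread_days = 18, skew = 1,
                 annual_integral = 1200),
    season_model("Gamma", year, peak_day = 200, spread_days = 25, skew = 2,
                 annual_integral = 600)
  )
}

fx_confusion <- function() {
  m <- matrix(
    c(0.85, 0.05, 0.00, 0.08, 0.02,
      0.10, 0.80, 0.02, 0.05, 0.03,
      0.00, 0.04, 0.90, 0.05, 0.01),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("Alpha", "Beta", "Gamma"),
                    c("Alpha", "Beta", "Gamma", "Varia", "NoPollen"))
  )
  m
}

fx_pomo <- function(taxa = c("Alpha", "Beta", "Gamma"), seed = 11,
                    p_interval_gap = 0, p_day_gap = 0, efficiency = 1) {
  device_model("pomo-test", "intermittent", interval_volume = 3,
               efficiency = efficiency,
               confusion = identity_confusion(taxa),
               p_interval_gap = p_interval_gap, p_day_gap = p_day_gap,
               seed = seed)
}

fx_hirst <- function(seed = 12, efficiency = 1, dispersion = 0) {
  device_model("hirst-test", "continuous", flow = 0.6,
               efficiency = efficiency, dispersion = dispersion,
               seed = seed)
}

# interval records for one day from a vector of 8 (or fewer) counts
fx_day_records <- function(counts, date = as.Date("2018-04-01"),
                           taxon = "Alpha", volume = 3) {
  tibble::tibble(
    device_id = "pomo-test", date = date,
    interval_index = seq_along(counts) - 1L,
    taxon = taxon, count = as.integer(counts), volume = volume
  )
}
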