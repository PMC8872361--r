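trait_column <- function(trait) {
  cols <- c(start = "start_date", peak = "peak_date", end = "end_date",
            duration = "duration_days", api = "annual_pollen_integral",
            peak_value = "peak_value")
  assert(trait %in% names(cols),
         paste0("`trait` must be one of: ", paste(names(cols),
                                                  collapse = ", ")))
  cols[[trait]]
}

date_traits <- c("start", "peak", "end")

# day-of-year representation used whenever a date trait enters a
# regression or correlation
as_trait_value <- function(x, trait) {
  if (trait %in% date_traits) as.integer(format(x, "%j")) else as.numeric(x)
}

fit_pair_stats <- function(a, b) {
  n <- length(a)
  if (n < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(tibble::tibble(
      n = n, pearson_r = NA_real_, r_squared = NA_real_,
      slope = NA_real_, intercept = NA_real_, p_value = NA_real_,
      computable = FALSE
    ))
  }
  fit <- lm(a ~ b)
  ct <- suppressWarnings(cor.test(a, b, method = "pearson"))
  tibble::tibble(
    n = n,
    pearson_r = unname(ct$estimate),
    # summary.lm warns on exact fits; those are legitimate here
    # (noise-free device pairs)
    r_squared = suppressWarnings(summary(fit)$r.squared),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p_value = ct$p.value,
    computable = TRUE
  )
}

#' Correlate the daily series of two devices
#'
#' Pairs the two wide daily tables on dates where *both* devices report
#' (missing days never pair with zeros), then computes the Pearson
#' correlation with its two-sided p-value plus a companion OLS fit of
#' device A on device B.
#'
#' @param table_a,table_b Wide daily-concentration tables (`date` +
#'   taxon columns); A is conventionally the automatic monitor and B the
#'   Hirst-type reference.
#' @param taxon A taxon column name, or `"total"` (default) to compare
#'   the summed concentration across all taxa (days missing any taxon
#'   are treated as missing).
#'
#' @return A one-row tibble: `trait`, `n`, `pearson_r`, `r_squared`,
#'   `slope`, `intercept`, `p_value`, `computable`. Fewer than 3 pairs
#'   (or a constant series) gives `computable = FALSE`.
#' @export
correlate_daily <- function(table_a, table_b, taxon = "total") {
  pick <- function(tab) {
    taxa <- taxon_columns(tab)
    if (taxon == "total") {
      tibble::tibble(date = tab$date,
                     value = rowSums(tab[taxa], na.rm = FALSE))
    } else {
      assert(taxon %in% taxa,
             sprintf("taxon '%s' is not a column of the daily table", taxon))
      tibble::tibble(date = tab$date, value = tab[[taxon]])
    }
  }
  pairs <- dplyr::inner_join(pick(table_a), pick(table_b), by = "date",
                             suffix = c("_a", "_b")) %>%
    dplyr::filter(!is.na(.data$value_a), !is.na(.data$value_b))
  dplyr::bind_cols(
    tibble::tibble(trait = paste0("daily_", taxon)),
    fit_pair_stats(pairs$value_a, pairs$value_b)
  )
}

#' Regress one season trait of device A on device B
#'
#' Pairs the two trait tables on (taxon, year) — each point one
#' taxon-year, as in published device intercomparisons — keeping only
#' pairs where both seasons are defined, and fits an ordinary
#' least-squares regression of A on B. Date traits are compared as
#' day-of-year integers. Pairs dropped for undefined seasons are
#' counted, not silently lost.
#'
#' @param traits_a,traits_b Season-trait tables from [annual_traits()];
#'   A is the response, B the predictor (configurable by swapping the
#'   arguments).
#' @param trait One of `"start"`, `"peak"`, `"end"`, `"duration"`,
#'   `"api"`, `"peak_value"`.
#'
#' @return An object of class `trait_comparison` with [tidy()] (pair
#'   listing), [glance()] (fit statistics) and [autoplot()] methods.
#' @export
regress_trait <- function(traits_a, traits_b, trait) {
  col <- trait_column(trait)
  pairs <- dplyr::inner_join(
    traits_a %>% dplyr::select("taxon", "year", dplyr::all_of(col),
                               "defined"),
    traits_b %>% dplyr::select("taxon", "year", dplyr::all_of(col),
                               "defined"),
    by = c("taxon", "year"), suffix = c("_a", "_b")
  )
  n_candidates <- nrow(pairs)
  kept <- pairs %>%
    dplyr::filter(.data$defined_a, .data$defined_b) %>%
    dplyr::transmute(
      .data$taxon, .data$year,
      a = as_trait_value(.data[[paste0(col, "_a")]], trait),
      b = as_trait_value(.data[[paste0(col, "_b")]], trait)
    )
  structure(
    list(
      trait = trait,
      pairs = kept,
      n_pairs = nrow(kept),
      n_dropped = n_candidates - nrow(kept),
      direction = "A (automatic) regressed on B (reference)",
      stats = fit_pair_stats(kept$a, kept$b)
    ),
    class = "trait_comparison"
  )
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat(sprintf("<trait_comparison> %s: %d pairs (%d dropped), %s\n",
              x$trait, x$n_pairs, x$n_dropped, x$direction))
  if (isTRUE(x$stats$computable)) {
    cat(sprintf("  r = %.3f, R^2 = %.3f, slope = %.3f, intercept = %.3f, p = %.3g\n",
                x$stats$pearson_r, x$stats$r_squared, x$stats$slope,
                x$stats$intercept, x$stats$p_value))
  } else {
    cat("  not computable (fewer than 3 pairs or zero variance)\n")
  }
  invisible(x)
}

#' @method tidy trait_comparison
#' @export
tidy.trait_comparison <- function(x, ...) {
  x$pairs
}

#' @method glance trait_comparison
#' @export
glance.trait_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(trait = x$trait),
    x$stats,
    tibble::tibble(n_dropped = x$n_dropped)
  )
}

#' @method autoplot trait_comparison
#' @export
autoplot.trait_comparison <- function(object, ...) {
  assert(object$n_pairs > 0, "no pairs to plot")
  unit <- if (object$trait %in% date_traits) "day of year" else
    object$trait
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$b, .data$a)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "#2166ac",
                         fill = "grey80") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste0("reference device (", unit, ")"),
      y = paste0("automatic device (", unit, ")"),
      title = sprintf("%s: r = %.2f, R^2 = %.2f", object$trait,
                      object$stats$pearson_r, object$stats$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Regression summaries for several traits at once
#'
#' @inheritParams regress_trait
#' @param traits Traits to compare (default all six).
#' @return A tibble with one [glance()] row per trait.
#' @export
compare_traits <- function(traits_a, traits_b,
                           traits = c("start", "peak", "end", "duration",
                                      "api", "peak_value")) {
  purrr::map_dfr(traits,
                 function(tr) glance(regress_trait(traits_a, traits_b, tr)))
}

#' Median paired differences in season traits
#'
#' For every (taxon, year) defined in both devices, takes the difference
#' A minus B of each season trait — start/peak/end dates in days,
#' peak concentration in grains/m^3, API in pollen day/m^3 — and
#' reports the medians. Positive date offsets mean device A's season is
#' later.
#'
#' @inheritParams regress_trait
#' @return A one-row tibble: `n_pairs`, `median_start_offset_days`,
#'   `median_peak_offset_days`, `median_end_offset_days`,
#'   `median_duration_diff_days`, `median_peak_value_diff`,
#'   `median_api_diff`.
#' @export
median_trait_differences <- function(traits_a, traits_b) {
  pairs <- dplyr::inner_join(traits_a, traits_b, by = c("taxon", "year"),
                             suffix = c("_a", "_b")) %>%
    dplyr::filter(.data$defined_a, .data$defined_b)
  assert(nrow(pairs) > 0, "no (taxon, year) pairs defined in both devices")
  tibble::tibble(
    n_pairs = nrow(pairs),
    median_start_offset_days =
      median(as.numeric(pairs$start_date_a - pairs$start_date_b)),
    median_peak_offset_days =
      median(as.numeric(pairs$peak_date_a - pairs$peak_date_b)),
    median_end_offset_days =
      median(as.numeric(pairs$end_date_a - pairs$end_date_b)),
    median_duration_diff_days =
      median(as.numeric(pairs$duration_days_a - pairs$duration_days_b)),
    median_peak_value_diff =
      median(pairs$peak_value_a - pairs$peak_value_b),
    median_api_diff =
      median(pairs$annual_pollen_integral_a - pairs$annual_pollen_integral_b)
  )
}
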