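fx_traits <- function(daily) annual_traits(daily)

shift_traits <- function(traits, days = 0, scale = 1) {
  traits %>%
    dplyr::mutate(
      start_date = .data$start_date + days,
      peak_date = .data$peak_date + days,
      end_date = .data$end_date + days,
      annual_pollen_integral = scale * .data$annual_pollen_integral,
      peak_value = scale * .data$peak_value
    )
}

test_that("identical daily series correlate perfectly", {
  true <- simulate_true_seasons(fx_models(), 2018)
  res <- correlate_daily(true, true, "total")
  expect_equal(res$pearson_r, 1.0)
  expect_equal(res$slope, 1.0)
  expect_true(res$computable)
  expect_equal(res$n, 365)

  # doubling one series leaves r at 1 and doubles the slope of A on B
  doubled <- dplyr::mutate(true, dplyr::across(-date, ~ 2 * .x))
  res <- correlate_daily(doubled, true, "Alpha")
  expect_equal(res$pearson_r, 1.0)
  expect_equal(res$slope, 2.0)
})

test_that("r is invariant under positive affine rescaling of either series", {
  true <- simulate_true_seasons(fx_models(), 2018)
  noisy <- simulate_hirst_series(true, fx_hirst(seed = 71))
  base <- correlate_daily(noisy, true, "Beta")
  rescaled <- dplyr::mutate(true, Beta = 3.7 * Beta + 11)
  expect_equal(correlate_daily(noisy, rescaled, "Beta")$pearson_r,
               base$pearson_r, tolerance = 1e-12)
})

test_that("daily pairing skips days either device misses", {
  a <- tibble::tibble(date = as.Date("2018-06-01") + 0:4,
                      Tx = c(1, NA, 3, 4, 5))
  b <- tibble::tibble(date = as.Date("2018-06-01") + 0:4,
                      Tx = c(2, 2, NA, 8, 10))
  res <- correlate_daily(a, b, "Tx")
  expect_equal(res$n, 3)

  # fewer than 3 shared days -> flagged not computable
  short <- correlate_daily(a[1:3, ], b[1:3, ], "Tx")
  expect_false(short$computable)
  expect_true(is.na(short$pearson_r))
})

test_that("noisy paired samplers correlate as a Monte-Carlo oracle predicts", {
  true <- simulate_true_seasons(
    season_model("Tx", 2018, 150, 20, annual_integral = 400), 2018)
  obs_r <- correlate_daily(
    simulate_hirst_series(true, fx_hirst(seed = 81)),
    simulate_hirst_series(true, fx_hirst(seed = 82)),
    "Tx")$pearson_r

  # brute-force re-simulation of the same generative process with plain
  # rpois, outside the package's code path
  withr::local_seed(83)
  vol <- 24 * 0.6
  lambda <- true$Tx * vol
  rs <- replicate(1000, {
    cor(rpois(365, lambda) / vol, rpois(365, lambda) / vol)
  })
  expect_gte(obs_r, quantile(rs, 0.005))
  expect_lte(obs_r, quantile(rs, 0.995))
})

test_that("identical and shifted trait vectors regress as expected", {
  true <- simulate_true_seasons(fx_models(), 2018)
  traits <- fx_traits(true)

  same <- regress_trait(traits, traits, "peak")
  g <- glance(same)
  expect_equal(g$slope, 1.0, tolerance = 1e-8)
  expect_equal(g$intercept, 0.0, tolerance = 1e-6)
  expect_equal(g$r_squared, 1.0, tolerance = 1e-10)

  # A = B + 5 days -> slope 1, intercept 5
  later <- shift_traits(traits, days = 5)
  g <- glance(regress_trait(later, traits, "start"))
  expect_equal(g$slope, 1.0, tolerance = 1e-8)
  expect_equal(g$intercept, 5.0, tolerance = 1e-6)

  # r^2 equals r squared for simple OLS
  noisy <- simulate_hirst_series(true, fx_hirst(seed = 84))
  g <- glance(regress_trait(fx_traits(noisy), traits, "api"))
  expect_equal(g$r_squared, g$pearson_r^2, tolerance = 1e-12)
})

test_that("undefined seasons are dropped from pairing and accounted for", {
  true <- simulate_true_seasons(fx_models(), 2018)
  traits <- fx_traits(true)
  broken <- traits
  broken$defined[2] <- FALSE
  rt <- regress_trait(broken, traits, "peak")
  expect_equal(rt$n_pairs, 2)
  expect_equal(rt$n_dropped, 1)
  expect_equal(rt$n_pairs + rt$n_dropped, nrow(traits))
  expect_false(glance(rt)$computable) # 2 pairs is below the n >= 3 floor
})

test_that("a known slope is inside its 95% CI at the nominal rate", {
  withr::local_seed(85)
  coverage <- mean(replicate(1000, {
    b <- runif(15, 50, 150)
    a <- 5 + 1.2 * b + stats::rnorm(15, 0, 8)
    ta <- tibble::tibble(taxon = paste0("t", 1:15), year = 2018L,
                         duration_days = a, defined = TRUE)
    tb <- tibble::tibble(taxon = paste0("t", 1:15), year = 2018L,
                         duration_days = b, defined = TRUE)
    rt <- regress_trait(ta, tb, "duration")
    ci <- stats::confint(lm(a ~ b, data = tidy(rt)))["b", ]
    ci[1] <= 1.2 && 1.2 <= ci[2]
  }))
  expect_gte(coverage, 0.93)
})

test_that("median trait offsets are zero for identical devices and track shifts", {
  true <- simulate_true_seasons(fx_models(), 2018)
  traits <- fx_traits(true)
  off <- median_trait_differences(traits, traits)
  expect_equal(off$median_start_offset_days, 0)
  expect_equal(off$median_peak_offset_days, 0)
  expect_equal(off$median_end_offset_days, 0)
  expect_equal(off$median_api_diff, 0)

  shifted <- shift_traits(traits, days = 5)
  off <- median_trait_differences(shifted, traits)
  expect_equal(off$median_start_offset_days, 5)
  expect_equal(off$median_peak_offset_days, 5)
  expect_equal(off$median_end_offset_days, 5)
  expect_equal(off$median_api_diff, 0)
})

test_that("swapping device order negates offsets and inverts noise-free slopes", {
  true <- simulate_true_seasons(fx_models(), 2018)
  traits <- fx_traits(true)
  scaled <- shift_traits(traits, days = 3, scale = 2)

  fwd <- median_trait_differences(scaled, traits)
  rev <- median_trait_differences(traits, scaled)
  expect_equal(fwd$median_start_offset_days, -rev$median_start_offset_days)
  expect_equal(fwd$median_api_diff, -rev$median_api_diff)

  s_fwd <- glance(regress_trait(scaled, traits, "api"))$slope
  s_rev <- glance(regress_trait(traits, scaled, "api"))$slope
  expect_equal(s_fwd, 1 / s_rev, tolerance = 1e-8)

  # no overlapping defined pairs -> error
  none <- dplyr::mutate(traits, defined = FALSE)
  expect_error(median_trait_differences(none, traits), "no .*pairs")
})

test_that("an injected efficiency ratio shows up in the median API difference", {
  models <- fx_models()
  true <- simulate_true_seasons(models, 2018)
  reps <- 30
  diffs <- purrr::map_dbl(seq_len(reps), function(i) {
    a <- simulate_hirst_series(true, fx_hirst(seed = 1000 + i,
                                              efficiency = 2))
    b <- simulate_hirst_series(true, fx_hirst(seed = 2000 + i))
    median_trait_differences(fx_traits(a), fx_traits(b))$median_api_diff
  })
  # expected median API difference = median of per-taxon (2-1) x API
  expected <- median(models$annual_integral)
  se <- stats::sd(diffs) / sqrt(reps)
  expect_lt(abs(mean(diffs) - expected), 3 * se + 0.02 * expected)
})

test_that("compare_traits emits one computable summary row per trait", {
  true <- simulate_true_seasons(fx_models(), 2018)
  noisy <- simulate_hirst_series(true, fx_hirst(seed = 91))
  out <- compare_traits(fx_traits(noisy), fx_traits(true))
  expect_equal(out$trait, c("start", "peak", "end", "duration", "api",
                            "peak_value"))
  expect_true(all(out$n == 3))
  expect_true(all(out$computable))
})
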