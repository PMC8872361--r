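test_that("true season curves integrate to the annual pollen integral", {
  models <- season_model("Solo", 2018, peak_day = 100, spread_days = 12,
                         annual_integral = 1000)
  true <- simulate_true_seasons(models, 2018)
  expect_gte(sum(true$Solo), 995)
  expect_lte(sum(true$Solo), 1005)
  expect_true(all(true$Solo >= 0))

  # with a baseline the annual sum is still the integral
  with_base <- simulate_true_seasons(
    season_model("Base", 2018, 100, 12, annual_integral = 1000,
                 baseline = 0.5), 2018)
  expect_equal(sum(with_base$Base), 1000, tolerance = 1e-9)
})

test_that("a vanishing spread concentrates the season on the peak days", {
  models <- season_model("Spike", 2018, peak_day = 100, spread_days = 0.1,
                         annual_integral = 1000)
  true <- simulate_true_seasons(models, 2018)
  expect_gte(sum(true$Spike[99:101]), 0.99 * sum(true$Spike))
})

test_that("the daily series peaks on the requested day", {
  for (skew in c(0, 1.5, -1)) {
    models <- season_model("Tx", 2018, peak_day = 100, spread_days = 10,
                           skew = skew, annual_integral = 5000)
    true <- simulate_true_seasons(models, 2018)
    expect_equal(which.max(true$Tx), 100)
    # unimodal: non-decreasing up to the peak, non-increasing after
    expect_true(all(diff(true$Tx[1:100]) >= 0))
    expect_true(all(diff(true$Tx[100:365]) <= 0))
  }
})

test_that("duplicate (taxon, year) season models are rejected", {
  models <- dplyr::bind_rows(
    season_model("Dup", 2018, 100, 10, annual_integral = 100),
    season_model("Dup", 2018, 150, 10, annual_integral = 200)
  )
  expect_error(simulate_true_seasons(models, 2018), "duplicate")
  expect_error(
    simulate_true_seasons(season_model("A", 2017, 100, 10,
                                       annual_integral = 10), 2018),
    "year")
})

test_that("a zero-efficiency continuous sampler records nothing", {
  true <- simulate_true_seasons(fx_models(), 2018)
  obs <- simulate_hirst_series(true, fx_hirst(efficiency = 0))
  expect_true(all(obs$Alpha == 0) && all(obs$Beta == 0) &&
                all(obs$Gamma == 0))
})

test_that("continuous-sampler concentrations are unbiased for the truth", {
  n_days <- 10000
  true <- tibble::tibble(
    date = as.Date("2000-01-01") + seq_len(n_days) - 1,
    Tx = 10
  )
  obs <- simulate_hirst_series(true, fx_hirst(seed = 5))
  daily_volume <- 24 * 0.6
  se <- sqrt(10 / daily_volume / n_days) # Poisson var of conc = lambda/vol^2
  expect_lt(abs(mean(obs$Tx) - 10), 2 * se)
})

test_that("simulators are deterministic under a fixed device seed", {
  true <- simulate_true_seasons(fx_models(), 2018)
  expect_identical(simulate_hirst_series(true, fx_hirst(seed = 99)),
                   simulate_hirst_series(true, fx_hirst(seed = 99)))
  a <- simulate_pomo_records(true, fx_pomo(seed = 7, p_day_gap = 0.2,
                                           p_interval_gap = 0.1))
  b <- simulate_pomo_records(true, fx_pomo(seed = 7, p_day_gap = 0.2,
                                           p_interval_gap = 0.1))
  expect_identical(a, b)
  dev <- fx_pomo(seed = 3)
  dev$confusion <- fx_confusion()
  expect_identical(generate_labeled_objects(c(Alpha = 500), dev),
                   generate_labeled_objects(c(Alpha = 500), dev))
})

test_that("certain whole-day failure leaves no records and a full gap log", {
  true <- simulate_true_seasons(fx_models(), 2018)
  res <- simulate_pomo_records(true, fx_pomo(p_day_gap = 1))
  expect_equal(nrow(res$records), 0)
  expect_equal(nrow(res$gap_log), 365)
  expect_true(all(res$gap_log$type == "day"))
  expect_true(all(is.na(res$gap_log$interval_index)))
})

test_that("a gapless intermittent device reports 8 intervals per day per taxon", {
  true <- simulate_true_seasons(fx_models(), 2018)
  res <- simulate_pomo_records(true, fx_pomo())
  per_day <- dplyr::count(res$records, date, taxon)
  expect_true(all(per_day$n == 8))
  expect_equal(nrow(res$records), 365 * 8 * 3)
  expect_equal(nrow(res$gap_log), 0)
  # volume bookkeeping: a full day samples 8 x 3 = 24 m^3
  day_vol <- res$records %>%
    dplyr::filter(taxon == "Alpha") %>%
    dplyr::group_by(date) %>%
    dplyr::summarise(v = sum(volume))
  expect_true(all(day_vol$v == 24))
})

test_that("invalid gap probabilities are rejected at construction", {
  expect_error(fx_pomo(p_day_gap = 1.2), "probability")
  expect_error(fx_pomo(p_interval_gap = -0.1), "probability")
})

test_that("labelled objects follow the confusion row and conserve counts", {
  dev <- fx_pomo(seed = 21)
  dev$confusion <- fx_confusion()

  # empty request -> empty, typed result
  empty <- generate_labeled_objects(setNames(integer(), character()), dev)
  expect_equal(nrow(empty), 0)

  # identity confusion -> perfect agreement
  ident <- fx_pomo(seed = 22)
  obj <- generate_labeled_objects(c(Alpha = 100, Beta = 50), ident)
  expect_equal(nrow(obj), 150)
  expect_true(all(obj$predicted == obj$manual))

  # binomial recovery of one confusion entry
  n <- 10000
  obj <- generate_labeled_objects(c(Alpha = n), dev)
  expect_equal(nrow(obj), n) # exact conservation
  frac <- mean(obj$predicted == "Alpha")
  # 3 s.e.: the draw is frozen by the seed, so allow the usual slack a
  # deterministic binomial check needs
  expect_lt(abs(frac - 0.85), 3 * sqrt(0.85 * 0.15 / n))

  # unknown label rejected
  expect_error(generate_labeled_objects(c(Delta = 10), dev),
               "missing from the confusion")
})

test_that("the empirical confusion matrix converges to the generator's", {
  dev <- fx_pomo(seed = 31)
  dev$confusion <- fx_confusion()
  n <- 20000
  obj <- generate_labeled_objects(
    setNames(rep(n, 3), rownames(fx_confusion())), dev)
  emp <- with(obj, table(manual, predicted)) # may miss empty columns
  emp <- emp / rowSums(emp)
  for (r in rownames(fx_confusion())) {
    for (p in colnames(emp)) {
      expect_lt(abs(emp[r, p] - fx_confusion()[r, p]), 0.02)
    }
  }
})
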