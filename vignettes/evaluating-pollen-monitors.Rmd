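---
title: "Evaluating automatic pollen monitors against Hirst-type reference traps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating automatic pollen monitors against Hirst-type reference traps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(aeroeval)
library(dplyr)
```

## The problem

Aerobiological monitoring networks still largely rely on Hirst-type
volumetric traps: a continuous 0.6 m³/h air stream deposits particles on
an adhesive surface that an expert later counts under the microscope.
The method is the de facto gold standard but is slow (results arrive
with about a week's delay) and labour-intensive. Automatic image-based
monitors such as the BAA500 instead draw a large air volume in 3-hourly
batches (3 m³ per interval, 24 m³/day), photograph each deposited
particle and classify it algorithmically, delivering near-real-time
concentrations.

Before an automatic monitor can replace or complement a Hirst trap, four
questions must be answered quantitatively:

1. **Reliability** — what fraction of 3-hourly sampling slots actually
   produced data, and how many whole days were lost, especially inside
   each taxon's main pollen season?
2. **Classification performance** — when experts manually re-identify
   the particles the device photographed, how often was the automatic
   label right? Per class this is summarised by sensitivity
   ($\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$) and positive predictive
   value ($\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$).
3. **Season comparability** — do the two devices agree on the timing
   (start, peak, end, duration) and magnitude (Annual Pollen Integral,
   peak concentration) of each taxon's season?
4. **Non-pollen particles** — what does the device throw away as
   "NoPollen" or "Spores", and how much of it is actually pollen?

`aeroeval` implements this whole evaluation as composable,
tibble-in/tibble-out functions, and adds a synthetic dual-device
simulator so that every statistic can be validated against known truth
without access to any (typically proprietary) monitoring campaign data.

## The synthetic ground truth

`season_model()` describes one taxon-year as a skew-normal daily
concentration curve

$$f(d) \propto \frac{2}{\omega}\,
  \phi\!\left(\frac{d-\xi}{\omega}\right)
  \Phi\!\left(\alpha\,\frac{d-\xi}{\omega}\right),$$

parameterised by the **peak day** (the location $\xi$ is shifted so the
mode lands exactly on `peak_day`), a **spread** $\omega$ in days, a
**skew** $\alpha$ (positive for the long right tails late-season
stragglers produce), and the target **Annual Pollen Integral** (API,
pollen·day/m³). After discretisation to calendar days the curve
(including any constant `baseline`) is rescaled so the annual sum equals
the API exactly; unimodality and the peak location are therefore
preserved while the integral contract holds to machine precision. The
skew-normal family was chosen because it is the simplest unimodal family
that can represent both symmetric seasons and the skewed shapes real
pollen calendars show; published intercomparisons display such curves
but do not parameterise them.

What the generator deliberately does **not** emulate: intra-day (diurnal)
pollen rhythms — each 3-h interval sees the daily mean concentration —
multi-modal seasons (e.g. bimodal Poaceae years), spatial transport, or
year-to-year phenological autocorrelation. Tests passing on this
generator therefore validate the *evaluation arithmetic*, not the
meteorological realism of any particular campaign.

## The device observation model

`device_model()` captures a sampler as:

* a sampling regime — *continuous* (daily volume $24 \times$ `flow`;
  Hirst standard 0.6 m³/h, i.e. 14.4 m³/day) or *intermittent*
  (`intervals_per_day` × `interval_volume`; BAA500 standard 8 × 3 m³);
* a per-taxon capture **efficiency** multiplier;
* **counting noise**: grains captured in a slot are Poisson with mean
  `concentration × efficiency × volume`. Poisson is the natural minimal
  model for counting a homogeneous particle stream; no published noise
  model exists for either device;
* optional **day-to-day capture variability** (`dispersion`): a
  day-level gamma multiplier with mean 1 and the given CV, shared by all
  taxa of that day, making counts negative-binomial marginally. With
  `dispersion = 0` (the default) two co-located simulated devices
  correlate almost perfectly day by day, because they share the same
  truth and Poisson noise is negligible at seasonal concentrations; real
  paired deployments show daily correlations nearer 0.5, and this term
  is the minimal mechanism that reproduces that regime (for two devices
  with CV $c$ each, $r \approx 1/(1+c^2)$ when seasonal variance
  dominates);
* a **two-level gap process**: each day fails completely with
  `p_day_gap`; surviving days lose each interval independently with
  `p_interval_gap`. Two levels are needed because whole-day breakdowns
  and isolated interval losses are reported separately in practice.
  A lost interval produces *no record* — never a zero count — so "no
  data" and "no pollen" stay distinguishable downstream; every loss is
  written to a gap log that reliability statistics can be checked
  against exactly;
* a row-stochastic **confusion matrix** from true labels to predicted
  labels (all taxa plus the `Varia` unknown-pollen sink and
  `NoPollen`); `generate_labeled_objects()` emits exactly the requested
  number of objects per true class with predictions sampled from the
  corresponding row.

One master seed controls everything; per-device, per-operation sub-seeds
are derived deterministically, so whole pipeline runs are reproducible
byte for byte.

## Main pollen season definition

`main_pollen_season()` implements the cumulative-percentage method that
retains the central 95% of the annual pollen sum: the season starts on
the first day whose inclusive cumulative sum reaches 2.5% of the API and
ends on the first day reaching 97.5% (both configurable via
`season_config()`). Numerical conventions, chosen where the method
leaves room:

* *Threshold attainment* is inclusive ("the day on which the percentage
  was recorded"), with a relative tolerance of $10^{-12}$ so rescaling a
  series cannot flip a threshold day through float round-off.
* A threshold day must itself carry pollen (`value > 0`), so zero-pollen
  days can never open or close a season.
* *Peak ties* break to the earliest date.
* *Missing days count as zero* in the cumulation — the convention
  long-running Hirst datasets use — but are tallied per season
  (`n_missing_days`) so gappy estimates are flagged rather than hidden.
* Seasons are windowed by calendar year; cross-winter seasons are not
  split or merged. For very early-flowering taxa (hazel, alder) whose
  seasons may begin in December this truncates the left tail — a known
  limitation shared with the evaluation this package models.
* A year with API 0 yields `defined = FALSE` with `NA` dates rather
  than an error, and undefined seasons are excluded (and counted) by
  every downstream pairing.

Daily concentrations from interval records divide the grains counted in
the *present* intervals by the volume those intervals actually sampled
(`daily_concentrations()`), not by the nominal 24 m³ — so a half-sampled
day is an unbiased, if noisier, estimate instead of a systematically
deflated one. Days with fewer than `min_day_availability` (default 50%)
of their intervals are treated as missing outright.

## Classification scoring

`build_confusion_matrix()` cross-tabulates manual (rows) against
predicted (columns) labels over a fixed vocabulary; objects without a
manual label, or labelled outside the vocabulary, are excluded *and
counted*. `Varia` is a genuine class: a true taxon predicted `Varia` is
a false negative for that taxon, and a predicted `Varia` that is really
a taxon is a false positive for `Varia`.

Published per-class "accuracy" figures for image-based monitors are
usually column-conditioned (among objects the device called *Betula*,
how many were?), which coincides with PPV for a square matrix, while
"sensitivity" is row-conditioned. Because the two are easily conflated,
`performance_scores()` reports both explicitly, flags undefined ratios
(zero denominators) as `NA` rather than coercing them to 0 or 1, and
`glance()` on the matrix reports overall accuracy in both senses: micro
(trace over total, every object weighted equally) and macro (unweighted
mean over classes). Micro is the default headline number; published
"overall" accuracies around 85% are consistent with either reading,
which is why both are always printed.

`particle_breakdown()` audits the discarded classes: restricted to
objects predicted `NoPollen` or `Spores`, it reports the manual
composition with all pollen taxa folded into one `Pollen` bucket — the
measure of how much genuine pollen the device throws away.

## Device comparison

`regress_trait()` fits ordinary least squares of device A's trait on
device B's, pairing taxon-years defined in both tables; date traits are
compared as day-of-year integers. OLS with Gaussian identity is exactly
the "general linear model" such intercomparisons report ($r$, $R^2$,
slope, intercept, two-sided $p$); no link functions are involved and no
multiple-testing correction is applied (none is customary here; the
$p$-values are labelled raw). The direction — automatic monitor as
response, reference trap as predictor — matches the convention of
published scatter plots and is changed by swapping the arguments. Fits
with fewer than 3 pairs or zero variance are flagged `computable =
FALSE` instead of returning spurious coefficients.
`median_trait_differences()` reports the median paired offsets (A − B):
days for start/peak/end, concentration units for peak value and API.
`correlate_daily()` pairs only the days *both* devices report — a
missing day never pairs with a zero.

## The demonstration configuration

`demo_config()` assembles a qualitatively realistic paired deployment,
with every number chosen once, on first principles, and documented here:

* 15 dominant central-European taxa with peak days from mid-February
  (*Alnus*, *Corylus*) to late July (Urticaceae), spreads giving 95%
  season windows of roughly 60–100 days, and APIs from 250
  (*Tilia*) to 4200 (*Betula*) pollen·day/m³;
* reference trap: continuous 0.6 m³/h, efficiency 1;
* automatic monitor: 8 × 3 m³ intermittent sampling with capture
  efficiency 2 — the "at least two-fold higher concentrations" regime
  reported for such monitors;
* `p_day_gap = 0.25` (automatic monitors have been online ~75% of days
  in multi-year deployments) and `p_interval_gap = 0.05` (5–10%
  3-hourly interruptions), which together put the median number of
  whole-day failures inside a season window in the 15–20 day range;
* `dispersion = 0.9` for both devices, from the $r \approx 1/(1+c^2)$
  argument above and the ~0.5 daily correlations reported for paired
  deployments;
* a confusion matrix with 2% `Varia` leakage for every taxon, heavier
  and taxon-specific losses for the classes image recognition is known
  to struggle with (*Populus* → *Betula*/*Quercus*, *Salix* →
  *Betula*, *Tilia* → `Varia`), and a true `Varia` class whose objects
  mostly resolve, under manual review, into common taxa.

None of these values is fitted to any dataset; they set a plausible
stage on which the pipeline's statistics can be exercised end to end.

```{r demo, eval = FALSE}
cfg <- demo_config(seed = 42)
res <- run_pipeline(cfg, "demo-run")
res$gap_report
res$overall
res$median_offsets
autoplot(res$confusion)
plot_seasonality(res$pomo_daily, res$hirst_daily, taxa = "Betula")
```

## Validation strategy and problem sizes

The test suite checks every statistic against an *independent* route:

* the season definition against a brute-force cumulative-sum oracle
  (an explicit day-by-day loop) on a hand-worked 9-day series and on
  random series;
* recovered season start/end dates against the analytic 2.5%/97.5%
  quantile days of the generating skew-normal curve, computed by
  numerical integration and root finding (tolerance ±1 day, with APIs
  of 1.5–3 × 10⁵ so counting noise is negligible);
* the empirical confusion matrix against the generator's row-stochastic
  truth (10⁵ objects per class, max deviation < 0.02 per cell;
  sensitivity and PPV within binomial standard errors of their analytic
  values);
* gap detection against the simulator's own gap log (exact equality),
  and the mean number of detected whole-day failures over 1,000 seeded
  runs of a 365-day year against the binomial expectation;
* trait regressions on noise-free device pairs against the exact
  identity (slope 1, intercept 0, $R^2$ 1), and CI coverage of a known
  slope over 1,000 simulated regressions;
* full pipeline runs for byte-identical reproducibility of the output
  bundle under a fixed configuration.

These sizes keep the whole suite under a minute on one core while
leaving the stochastic checks' standard errors far below the asserted
tolerances.

## Known limitations

* The simulator validates arithmetic, not atmospheric realism: no
  diurnal cycles, no bimodal seasons, no weather-driven day-to-day
  autocorrelation (the dispersion term is i.i.d. across days).
* Calendar-year season windows truncate cross-winter seasons.
* Daily-series comparisons support per-taxon series and the summed
  total; there is no pooled-across-taxa correlation mode, since pooling
  conflates between-taxon abundance differences with within-season
  agreement.
* The one-vs-rest TN count is taken over all objects in the confusion
  matrix, including the sink classes; other conventions (e.g. excluding
  `Varia` from the reference set) would shift specificity-type numbers
  but none reported here.
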