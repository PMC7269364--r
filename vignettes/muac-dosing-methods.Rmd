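---
title: "Methods: MUAC-based energy dosing for acute malnutrition programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MUAC-based energy dosing for acute malnutrition programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muacdose)
```

## The problem

Severe and moderate acute malnutrition (SAM and MAM) in children aged 6–59
months are conventionally treated in separate outpatient programs —
therapeutic feeding programs (TFP) for SAM with weekly visits, and
supplementary feeding programs (SFP) for MAM with two-weekly visits — with
different food products and weight-based dosing tables. A simplified,
combined protocol doses ready-to-use therapeutic food (RUTF, one 92 g
sachet ≈ 500 kcal) by mid-upper arm circumference (MUAC) alone: two sachets
per day (1000 kcal) while MUAC is 100 to <115 mm, one sachet (500 kcal)
while MUAC is 115 to <125 mm. `muacdose` implements the analysis chain that
motivates and stress-tests such a protocol on longitudinal patient-card
records, together with a synthetic cohort generator so the whole chain is
testable without confidential program data.

## Growth velocities on irregular visit intervals

Each card is a sequence of dated visits carrying MUAC (mm) and weight (kg).
For every consecutive visit pair, `interval_changes()` forms one interval
observation indexed by the *prior-visit* MUAC:

* MUAC velocity (mm/week) = ΔMUAC / (interval days / 7) — growth is assumed
  constant across the interval, so a two-week change is halved to a
  one-week change;
* proportional weight gain (g/kg/day) = Δweight × 1000 / prior weight /
  interval days.

Intervals of any length contribute a single observation; we do not expand
them into per-week pseudo-observations, because it is the recorded change
that is divided, not the record. Analysis is limited to prior MUAC in the
closed window [100, 140] mm, where program data are dense enough for
stable estimates.

## Quality control

Three filter layers run in a fixed order, and exclusion reasons in the
attrition table are attributed to the first failing rule so counts are
disjoint:

1. **Usability** (`card_usable()`): at least one follow-up visit; age, sex
   and every visit date present.
2. **Plausibility** (`flag_implausible()`): weight-for-height z outside
   [−5, 5], weight-for-age outside [−6, 5], height-for-age outside
   [−6, 6], MUAC outside [65, 200] mm, weight change of magnitude more
   than 25 g/kg/day, or MUAC change greater than 15 mm/week in either
   direction. Range rules retain the bound itself; change rules are strict
   inequalities (a 15 mm/week change is kept, 16 is excluded). An
   interval's change flags are attributed to the later visit. Z-scores use
   the LMS transform `z = ((x/M)^L − 1)/(L·S)` (log form for |L| < 1e−7)
   against a growth-reference table with linear interpolation of L, M, S
   between rows; out-of-range keys yield missing z-scores plus a warning,
   never an exception, and missing height simply leaves WHZ/HAZ missing.
3. **Outcome eligibility** (`outcome_eligible()`): discharged as
   recovered, non-negative admission-to-discharge MUAC gain, and at least
   10% (TFP/SAM) or 3% (SFP/MAM) relative weight gain, thresholds
   inclusive. Admission category is operationalized by admitting facility
   type, since cards are partitioned by facility.

Visits are judged individually: a card failing the MUAC window at some
visits still contributes its remaining visits.

## Smoothing and the trend comparison

`local_poly_smooth()` is a local polynomial kernel smoother: at each grid
point g it fits a weighted polynomial to (x, y) with kernel weights
K((x−g)/h) and reports the fitted value at g. Defaults are an Epanechnikov
kernel, degree 0 and an integer-mm grid; the bandwidth defaults to a
plug-in rule of thumb (quartic pilot fit supplying curvature and residual
variance), capped at one-eighth of the x-range so a band-level feature is
never smoothed away, and floored at half the mean x-spacing. Degree-0
fits double as the fallback at grid points whose local design is singular;
grid points with no kernel mass are missing.

To ask whether MUAC velocity tracks proportional weight gain,
`normalized_difference_trend_test()` min-max normalizes both smoothed
curves to [0, 1] over a shared grid (a constant curve maps to 0.5, with a
log note), regresses the normalized difference on MUAC by OLS, and reports
the slope with its F-test p-value. `resample_trend_analysis()` repeats
this over country-stratified subsamples drawn without replacement
(default 1000 visits per country, 100 replicates), reporting the slope
range and the fraction of replicates non-significant at α = 0.05 (the
significance level is a convention choice; 0.05 is used throughout).

**A calibration caveat we verified by simulation.** Min-max normalization
divides by a noisy range, which leaks a random multiple of the underlying
curve shape into the normalized difference. When the shape is monotone in
MUAC — as real recovery curves are — that leaked term is nearly collinear
with the trend regressor, and the F-test over-rejects a true null
regardless of the noise scale; smoothing worsens this by correlating
errors across grid points. The test suite therefore checks the nominal
size of the trend test on a non-monotone null shape, where its iid
assumptions hold; on monotone shapes the non-significant fraction under a
true null should be expected to fall well below 1 − α. Interpret small
p-values from this test qualitatively, not as calibrated error rates.

## Energy needs and dosage bands

Per interval observation, the energy needed to support the observed growth
is

    need (kcal/day) = prior weight (kg) × 82 kcal/kg/day
                    + daily gain (g/day) × 5 kcal/g

with maintenance 82 kcal/kg/day and a tissue-deposition cost of 5 kcal/g
(`energy_params()`). The prior-visit weight anchors both terms — it is the
same weight that normalizes the proportional gain — and negative gains
contribute negatively, never clamped: visits with weight loss occur even
in cards whose overall trajectory met the recovery criteria.

`band_percentile()` reports, per 5 mm MUAC band keyed by prior MUAC, the
empirical percentile (default 95th) of needs — the smallest dose
sufficient for the observed growth in that share of visits. Percentiles
use linear interpolation between closest ranks (R `quantile()` type 7), a
fixed convention chosen so tests can be bit-exact. Subgroup tables
(`subgroup_comparison()`) stratify by age group (6–23 vs 24–59 months),
continent, or admission MUAC category; the admission-category comparison
is restricted to bands in [110, 125) mm, the MUAC range such children
share during treatment.

## Protocol simulation

`proposed_dose()` encodes the MUAC-only rule (1000 kcal below 115 mm,
500 kcal at 115 to <125 mm, undefined outside [100, 125)); comparators
(`comparator_dose()`) cover per-kg protocols at 135/150/170 kcal/kg/day, a
two-tier 175/75 kcal/kg/day rule switching at MUAC 115 mm, and a rule
giving 200 kcal/kg/day to SAM-program admissions and a flat 500 kcal/day
to MAM-program admissions. `coverage_metrics()` scores one visit set:
provision ratio = dose/need, with success defined as ratio ≥ 1.0 in the
SAM stratum (prior MUAC 100 to <115 mm) and ≥ 0.5 in the MAM stratum (115
to <125 mm) — stratum membership by the visit's prior MUAC, not admission
category. Visits outside [100, 125) have no defined dose and are excluded
with a count. `simulate_trials()` repeats this over country-stratified
subsamples (default 200 visits per country × 100 replicates, sampling
unit configurable between visits and cards) and aggregates mean and
min–max success percentages and the median of per-replicate median
provision (midpoint median, the common convention).

## The synthetic cohort generator

`generate_cohort()` emulates program cards: five countries; country
TFP/SFP admission mixes; age mix 29/40/18/13% over 6–11/12–23/24–35/36–59
months; 54% female; admission MUAC uniform over integer mm on [100, 115)
for TFP and [115, 125) for SFP; admission weight log-normal by age group
(calibrated so most under-24-month children are under 8 kg); weekly (TFP)
or two-weekly (SFP) visits with a 0.1 missed-visit probability (a
modelling choice — source-program visit irregularity is not reported) that
doubles the interval; discharge as recovered at MUAC ≥ 125 mm; a 5%
early-default fraction exercising the eligibility filter; a visit cap of
40 as censoring.

Growth follows `MUAC(t+d) = MUAC(t) + v(MUAC)·d/7 + ε` and
`weight(t+d) = weight(t)·(1 + g(MUAC)·d/1000) + ε'`, with additive
Gaussian per-interval noise (defaults 2 mm and 0.1 kg, the order of MUAC
tape error and scale precision), truncated so measurements stay positive.
Two presets fix the mean-velocity functions: `fig2_anchor` interpolates
linearly through (105 mm, 2.0 mm/week) and (122.5 mm, 1.0 mm/week) for
MUAC velocity and through 3.9/2.4 g/kg/day at the same anchors for weight
gain, extrapolating flat beyond the anchors (band means justify no
functional form outside them); `linear_slope` is globally linear with
slopes −0.06 mm/week/mm and −0.05 g/kg/day/mm anchored at 105 mm. In
`fig2_anchor` the weight-gain function is an exact affine image of the
MUAC-velocity function, making it a true null for the normalized trend
comparison.

What the generator does *not* emulate: integer rounding of recorded MUAC
(state is continuous so that noise-free cohorts reproduce their generating
functions exactly; measurement discreteness is subsumed in the noise SD),
oedema dynamics, mortality and transfers, seasonality, year-rounded ages,
and heights (absent by default, so z-score filters engage only when a
reference and heights are supplied). Passing parameter-recovery tests on
these cohorts shows the estimators are consistent with their generating
process — not that real program data satisfy the model.

`inject_errors()` corrupts a copy of a cohort at configurable per-card
rates (MUAC spikes > 15 mm/week, weight jumps > 25 g/kg/day, out-of-range
MUAC, missing age/sex/date, no follow-up), applying measurement
corruptions to a card's final visit so each corruption implicates exactly
one record, and returns a manifest against which the QC flags can be
checked for exact agreement.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds (`with_seed`
internally restores the caller's RNG state), so identical configurations
reproduce cohorts and simulation summaries bitwise. The test suite and the
acceptance script use cohorts of 250 cards per country (≈ 7,500–8,500
interval observations after filtering), 100-replicate resampling, and
20,000-draw Monte-Carlo oracles; these sizes give Monte-Carlo standard
errors an order of magnitude below every asserted tolerance.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(trend_per_country = 500, trend_replicates = 50,
                  trial_per_country = 200, trial_replicates = 100,
                  rng_seed = 7L)
run <- run_pipeline(cfg, gen_config = generator_config(n_per_country = 250))
summary(run)
plot(run$curves$muac_velocity)
```

## Known limitations

* Velocities are treated as independent observations; repeated measures
  within a child are not modelled (no mixed effects), matching the
  descriptive aims of the analysis.
* The energy formula is a two-constant linear model — no catch-up-growth
  composition, no metabolic adaptation.
* The normalized-difference trend test is anti-conservative for monotone
  shapes (see above).
* Band percentiles at the window edges rest on fewer visits; empty
  band/subgroup cells are omitted with a log line rather than
  extrapolated.
* Cards cannot be linked across repeat treatment episodes; each card is an
  independent episode.
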