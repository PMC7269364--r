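# muacdose

Tools for designing and stress-testing simplified, MUAC-based energy
dosing protocols for the outpatient treatment of child acute malnutrition.

## The problem

Children aged 6–59 months with severe acute malnutrition (SAM, MUAC
< 115 mm) and moderate acute malnutrition (MAM, MUAC 115 to < 125 mm) are
usually treated in separate feeding programs — therapeutic feeding
programs (TFP, weekly visits) and supplementary feeding programs (SFP,
two-weekly visits) — with weight-based dosing tables for ready-to-use
therapeutic food (RUTF; one 92 g sachet ≈ 500 kcal). A combined protocol
doses by MUAC alone: **two sachets/day (1000 kcal) while MUAC is 100 to
< 115 mm, one sachet/day (500 kcal) while MUAC is 115 to < 125 mm**,
intending to cover 100% and 50% of energy needs respectively.

`muacdose` is aimed at nutrition analysts and biostatisticians evaluating
such protocols against longitudinal feeding-program visit records — or,
since such records are confidential, against synthetic cohorts with known
generating parameters.

## What it computes

For each consecutive visit pair on a patient card, indexed by the
prior-visit MUAC `m` and interval length `d` days:

* MUAC velocity `v = ΔMUAC / (d/7)` (mm/week) and proportional weight
  gain `g = Δw · 1000 / w_prior / d` (g/kg/day), assuming constant change
  within the interval;
* the energy needed to support the observed growth,

  ```
  need (kcal/day) = w_prior × 82 kcal/kg/day + daily gain (g/day) × 5 kcal/g
  ```

  (maintenance plus tissue-deposition cost);
* local polynomial kernel smooths of `v` and `g` against `m`
  (Epanechnikov, degree 0, plug-in bandwidth), and an OLS trend test on
  the min-max-normalized difference of the two curves over
  country-stratified subsamples;
* per 5 mm MUAC band, the 95th percentile of energy needs (the smallest
  dose sufficient in 95% of visits), overall and by age group, continent
  and admission MUAC category;
* simulated protocol performance: over 100 country-stratified subsamples,
  the share of visits whose needs the protocol covers (target ratio ≥ 1.0
  at MUAC 100 to < 115 mm, ≥ 0.5 at 115 to < 125 mm), against comparator
  protocols dosing 135/150/170 kcal/kg/day, 175/75 kcal/kg/day switching
  at 115 mm, or 200 kcal/kg/day (SAM program) / flat 500 kcal (MAM
  program).

Records pass usability filters (follow-up visit; age, sex, dates
present), biological-plausibility filters (LMS z-score bounds, MUAC
65–200 mm, |Δweight| ≤ 25 g/kg/day, |ΔMUAC| ≤ 15 mm/week) and outcome
eligibility (recovered, non-negative MUAC gain, ≥ 10%/3% weight gain for
SAM/MAM admissions) before analysis, which is restricted to prior MUAC
100–140 mm.

## Worked example

```r
library(muacdose)
cfg <- run_config(trend_per_country = 500, trend_replicates = 50,
                  trial_per_country = 200, trial_replicates = 100,
                  rng_seed = 7L)
run <- run_pipeline(cfg, gen_config = generator_config(n_per_country = 250))
summary(run)
```

prints (abridged):

```
MUAC dosing analysis run (seed 7)
Attrition:
                                                             step                  unit kept dropped
                                                            input                 cards 1250       0
               unusable (no follow-up / missing age, sex or date)                 cards 1250       0
                                        implausible visit records                visits 9460       0
 ineligible outcome (not recovered / MUAC loss / low weight gain)                 cards 1144     106
                               prior MUAC outside analysis window interval observations 7982      20

Normalized-difference trend test over MUAC [100, 125): 50 replicates
  slope mean 0.00219 (range -0.009194 to 0.01089)
  non-significant at level 0.05 in 68% of replicates

Energy dosage bands (95th percentile):
      band band_lo band_hi group    n level     kcal
 [100,105)     100     105   all  369  0.95 1110.309
 [105,110)     105     110   all  732  0.95 1107.548
 [110,115)     110     115   all 1338  0.95 1180.972
 [115,120)     115     120   all 2367  0.95 1219.214
 [120,125)     120     125   all 3176  0.95 1232.460

Protocol performance (total rows):
 stratum factor level mean_n min_n max_n median_provision_pct mean_success_pct
     mam  total   all 728.74   691   759             66.55094         84.48767
     sam  total   all 271.26   241   309            138.80135         87.60331
```

Reading this: of 1250 synthetic cards, 106 failed outcome eligibility
(the generator defaults 5% of cards and adds measurement noise), leaving
7982 interval observations in the 100–140 mm window. The trend-test slope
of the normalized MUAC-velocity vs weight-gain difference is near zero
(the generator links the two by an exact affine map). Band 95th-percentile
needs rise from ≈ 1110 to ≈ 1230 kcal/day across MUAC bands — band
percentiles sit well above *median* needs by construction. In the
simulated trials the proposed protocol provides a median 139% of need in
the SAM stratum and 67% in the MAM stratum (target 50%). Note the
trend-test non-significant fraction is well below 95%: the min-max
normalization makes this F-test anti-conservative for monotone curves
(see the methods vignette).

See `vignettes/muac-dosing-methods.Rmd` for the full model description,
parameter rationale and limitations.

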