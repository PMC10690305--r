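# backtraj

Backward-looking trajectories of laboratory values and vital signs in the
hours before life-threatening mass effect after large middle cerebral
artery (MCA) stroke.

## What this package is for

Space-occupying cerebral edema is an early, often fatal complication of
large MCA stroke.  Clinicians monitor labs, vitals and serial imaging,
but conventional plots from admission rarely reveal whether anything
drifts *before* deterioration, because patients deteriorate at very
different times.  `backtraj` implements the event-aligned alternative for
three deterioration outcomes — first midline shift (MLS) ≥ 5 mm, first
pineal gland shift (PGS) > 4 mm, and decompressive hemicraniectomy
(DHC) — over a 192-hour (8-day) horizon:

* **Backward-looking estimation.**  Patients with an observed outcome are
  aligned at the outcome time, and for each lag *s* ∈ [0, 72] h the
  marker's mean and 25th/50th/75th percentiles are estimated with
  inverse-probability-of-censoring weights
  *w<sub>i</sub>* = 1 / *Ĝ*(*X<sub>i</sub>*⁻), where *Ĝ* is the
  Kaplan–Meier estimate of the censoring-time survival.  Censored
  patients inform *Ĝ*; weights are renormalized per lag over the cases
  with data there; lags with fewer than 5 contributing cases are masked.
  Without censoring the estimator reduces exactly to the plain case-only
  statistics.
* **Competing-risk incidence.**  Aalen–Johansen cumulative incidence of
  each outcome with death as a competing risk, with complementary
  log-log confidence intervals.
* **Data preparation.**  Tidy cohort CSV schemas with validation; outcome
  adjudication (including censoring of radiographic crossings that occur
  after surgery); erroneous-measurement flagging (|Z| ≥ 3 pooled-cohort
  rule OR ≥ 25% change from the preceding value); binning of irregular
  measurements to variable-specific grids and hourly piecewise-linear /
  midpoint interpolation with no extrapolation.
* **Synthetic cohorts.**  A seeded joint longitudinal–survival generator
  (`simulate_cohort()`) that emulates the study's data structure —
  irregular per-variable sampling cadences, competing death/discharge,
  latent radiographic severity with threshold-crossing outcomes, and
  event-anchored marker signatures — and exports its ground truth for
  estimator validation.  No patient data ship with the package.

## Worked example

```r
library(backtraj)

sim <- simulate_cohort(default_sim_config(n_patients = 635, seed = 42))
ch <- sim$cohort
ch
#> <cohort> 635 patients, 88667 measurements (9 variables), 64 procedures

rec <- adjudicate_outcomes(ch, "mls5")
sum(rec$status == 1)
#> [1] 242        # 38.1% of patients reach MLS >= 5 mm within 192 h

aj <- aalen_johansen(rec)
cif_at(aj, c(24, 48, 72))
#>   time    cif ci_lo  ci_hi
#> 1   24 0.0678 0.050 0.0892
#> 2   48 0.1881 0.159 0.2195
#> 3   72 0.2859 0.251 0.3216
```

The cumulative incidence accounts for death as a competing risk: about
7% of patients cross the 5 mm threshold by 24 h, 19% by 48 h and 29% by
72 h.  Now the backward-looking temperature trajectory before the same
outcome:

```r
specs <- default_sim_config()$variable_specs
h <- hourly_series(ch$measurements[ch$measurements$variable == "temperature", ],
                   specs, records = rec)
w <- ipcw_weights(rec, censoring_km(rec))
est <- backward_estimate(align_backward(h, rec, "temperature"), w)
est[est$lag_h %in% c(0, 6, 12, 24, 48), ]
#>   lag_h n_eff  mean   q25   q50   q75 masked
#> 1     0     8 99.13 98.66 99.26 99.31  FALSE
#> 2     6    68 98.90 98.60 98.93 99.19  FALSE
#> 3    12    68 98.75 98.44 98.75 99.13  FALSE
#> 4    24    54 98.65 98.29 98.67 99.07  FALSE
#> 5    48    32 98.51 98.16 98.54 98.86  FALSE
```

Read right-to-left (48 h out to the event): the median temperature climbs
from 98.5 °F to well above 99 °F, with the steepest rise in the final
24 h — the generator's configured half-degree pre-event signature,
recovered by the estimator.  `n_eff` counts contributing cases per lag
(only a 26% subset of patients is vitals-monitored); a lag with
`n_eff < 5` would be masked rather than reported.

The whole analysis — cleaning, adjudication, regularization, incidence,
backward estimation and figures — runs as one pipeline:

```r
res <- run_pipeline(pipeline_config(), "out/")   # writes CSVs + figures + run log
```

A thin command-line front end is included at `inst/cli/backtraj.R`
(`Rscript inst/cli/backtraj.R run --config config.yaml --outdir out`).

See `vignettes/backward-trajectories.Rmd` for the model, its assumptions,
the generator's design and the validation strategy.

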