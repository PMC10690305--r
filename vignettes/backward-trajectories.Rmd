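---
title: "Backward-looking biomarker trajectories before life-threatening mass effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backward-looking biomarker trajectories before life-threatening mass effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backtraj)
```

## The problem

After a large middle cerebral artery (MCA) stroke, cerebral edema and
hemorrhagic transformation can produce life-threatening, space-occupying
mass effect within the first week.  Three observable markers of that
deterioration are used throughout this package as outcomes: the first
midline shift (MLS) of at least 5 mm on imaging, the first pineal gland
shift (PGS) of more than 4 mm, and decompressive hemicraniectomy (DHC).
The scientific question is whether routinely collected laboratory values
and vital signs drift in a recognizable way during the hours *before*
these outcomes.

Ordinary "forward-looking" plots from admission answer a different
question: they mix patients whose outcomes occur at very different times,
so a consistent pre-event drift is smeared out.  The package's central
tool is therefore a *backward-looking* estimator: patients are aligned at
the time of their outcome and the distribution of each marker is
estimated as a function of the lag $s$ before it, for $s$ from 0 to 72
hours.

## The estimand and the estimator

Write $T$ for the outcome time, $Y(t)$ for the hourly marker value, and
$X = \min(T, C)$ for the observed time, where $C$ is the censoring time
(discharge, the 192-hour follow-up horizon, or -- under the package's
default convention -- death; for radiographic outcomes, surgery also
censors, since a first crossing occurring after DHC is never coded as an
outcome).  The estimand at lag $s$ is

$$\mu(s) = \mathrm{E}\left[\,Y(T - s)\;\middle|\;T \le 192\,\mathrm{h}\right],$$

together with the corresponding 25th/50th/75th percentiles.  Only
patients with an observed outcome contribute values, but censored
patients carry information about *which* cases are over-represented:
cases with late outcomes are observed only when censoring happens to come
later still.  The estimator corrects this selection with
inverse-probability-of-censoring weights (IPCW).  With
$\hat G(t) = \Pr(C > t)$ the Kaplan-Meier estimate of the censoring
survival (censoring treated as the event, outcomes as censored
observations), each case $i$ receives

$$w_i = \frac{1}{\hat G(X_i^-)},$$

normalized to sum to one.  At each lag the weights are renormalized over
the cases whose aligned value exists at that lag, and the weighted mean
and weighted quantiles (left-continuous inverse of the weighted CDF) are
reported.  Without censoring every $\hat G(X_i^-) = 1$ and the estimator
reduces exactly to the plain case-only mean and quantiles -- a reduction
the test suite checks against an independent brute-force implementation
at machine precision.

Three design points deserve emphasis:

* **Alignment origin.**  Cases are aligned at `floor(X)`, the last
  completed hour at or before the outcome.  Rounding to the *nearest*
  hour would, for half of all continuous event times, point at an hour
  after the event -- an hour that either does not exist in the truncated
  series or would use post-event information.
* **Death.**  Death is a competing event for cumulative incidence, but
  for the weight denominator $\hat G$ it is pooled with discharge: the
  longitudinal record ends at death exactly as it does at discharge, and
  the estimand then conditions on surviving to the outcome.  Both
  conventions are available (`censoring_km(..., death = )`); the
  pipeline logs the one in force.  The conditioning is a real limitation:
  patients who die before their outcome contribute no case rows.
* **Masking.**  A lag supported by fewer than `min_n = 5` contributing
  cases is reported as missing, never as a value.  Quantiles on a handful
  of points are unstable, and a masked lag must not be plotted as if it
  were zero.

Lags are evaluated at every integer hour for all variables, since the
hourly interpolation (below) defines values at every hour of the observed
span; a `lag_step_h` argument allows coarser reporting for sparsely
sampled variables.

## From irregular measurements to hourly series

Clinical sampling is irregular, and the backward alignment needs equally
spaced values.  Two steps bridge the gap:

1. **Binning.**  Each variable has a grid step (1 h for blood pressure
   and heart rate, 2 h for temperature, 6 h for glucose and sodium, 12 h
   for creatinine and the radiographic series, 24 h for WBC).
   Measurements are collapsed to one node per non-empty half-open bin
   $[k\,\mathrm{step}, (k+1)\,\mathrm{step})$, placed at the bin's left
   edge, with the in-bin mean (continuous) or the last in-bin value
   (dichotomous).
2. **Interpolation.**  Between nodes, continuous variables are piecewise
   linear evaluated at integer hours; dichotomous variables switch at the
   first hour at or past the midpoint between nodes with differing
   values (an integer midpoint switches at that hour itself).  There is
   *no extrapolation*: hours before the first or after the last node are
   missing.  An affine signal sampled at any set of nodes is reproduced
   exactly at every covered integer hour, and no interpolated value can
   escape the range of its bracketing nodes.

When hourly series are built as inputs to the backward analysis, all
measurements after the patient's observed outcome are discarded *before*
binning, so post-event data can never leak into a pre-event value through
an interpolation segment.  A practical consequence of the no-extrapolation
rule is that sparsely sampled variables (WBC most of all) often have no
value in the final hours before the event: their trajectory estimates are
masked near lag 0 and end, on average, around half a sampling gap before
the outcome.  This mirrors the familiar clinical-data caveat that an
outcome's apparent timing depends on when tests happen to be taken.

Binning also attenuates fast features of sparsely sampled series.  For a
variable on a 24-hour grid sampled every ~21 hours, most bins hold a
single measurement whose value is re-timed to the bin's left edge (up to
a full step earlier), empty bins force interpolation across 48-hour
spans, and in-bin means average over the ramp.  A 72-hour linear drift
survives these operations only partially: in simulation, the package
recovers essentially all of a unit ramp for a densely sampled marker
(see the validation section) but a visibly flattened version of the same
ramp at a WBC-like cadence.  Sparse-variable trajectory changes are
therefore read as directions and lower bounds, not amplitudes.

## Competing-risk incidence

When outcomes are timed, death is a competing risk: a patient who dies
cannot later cross an imaging threshold, and $1 - \mathrm{KM}$ would
overstate the incidence.  The package estimates cause-specific cumulative
incidence with the Aalen-Johansen product-limit estimator (computed via
`survival::survfit` on a censor/event/death state factor), with
complementary log-log confidence intervals clipped to $[0,1]$.  Two exact
identities anchor the implementation and are enforced in the tests: with
a single cause the CIF equals $1 - \mathrm{KM}$ at machine precision, and
at every time point the cause-specific incidences and the all-cause
event-free survival sum to one.

## Outcome adjudication

One event record per patient per outcome.  The event time for
radiographic outcomes is the timestamp of the first qualifying scan
(MLS compared inclusively at 5 mm, PGS strictly at 4 mm, exactly as the
thresholds are defined); no interval-censoring correction is attempted,
matching the observed-time character of the analysis.  Death before the
event gives status 2 at the death time; otherwise the patient is censored
at the earliest of surgery (for radiographic outcomes; reason
`dhc_precedence`), discharge, or the 192-hour horizon.  Ties resolve in
favour of the event.  A DHC occurring after 192 h is not an event: the
record is censored at the horizon (the follow-up window is a hard
boundary by design).  The time origin is admission; last-seen-well, where
available, is a baseline covariate rather than an alternative origin.

## Cleaning rules

Chart-entry errors are screened by two rules, combined by *or*: an
absolute Z-score of at least 3 against the variable's pooled full-cohort
distribution, or an absolute change of at least 25% from the immediately
preceding same-variable value within the patient.  Both thresholds are
inclusive.  The 25% rule is deliberately not applied to radiographic
series, whose genuine between-scan changes routinely exceed it.  The
default policy is `flag_only`: in the source data the analogous step was
a manual contextual review, so automatic deletion (`drop_flagged`) is an
explicit opt-in.  The signed-versus-absolute reading of "25% change" is
ambiguous in prose; the package uses absolute change, since implausible
drops are as suspect as implausible jumps.

## The synthetic cohort generator

No patient-level data ship with the package; every analysis and every
test runs on cohorts from `simulate_cohort()`, whose defaults encode the
study conditions the package is validated under:

* **Cohort.**  635 patients, 192-hour horizon.  A latent severity
  process (midline shift) rises linearly from a uniform 0-1.5 mm
  admission value and crosses 5 mm at a latent time $T^*$ drawn from a
  cured log-normal distribution (median 44 h, `sdlog` 0.7, cure fraction
  0.5 -- half the cohort never develops severe mass effect).  Latent PGS
  is proportional (ratio 0.55), so its 4 mm crossing trails the MLS
  crossing.  Death (Weibull, mean ~380 h) and discharge (log-normal,
  median 240 h) are drawn independently.  These choices reproduce a
  crossing incidence of roughly 7%, 21% and 30% by 24/48/72 h, about a
  third of the cohort crossing within follow-up, a quarter crossing the
  PGS threshold, surgery in about one patient in nine, and just under
  40% dying before discharge.
* **Sampling.**  Inter-measurement gaps are i.i.d. log-normal per
  variable, parameterized by the median and interquartile range reported
  for each assay (glucose 5.4 h [2.3, 8.3], sodium 8.9 [6.0, 19.6],
  creatinine 11.3 [6.6, 22.9], WBC 20.9 [9.3, 24.4]; heart rate and
  blood pressure hourly and temperature 2-hourly on a 26% monitored
  subset; imaging 14.5 h [5.7, 23.9]).  The log-normal is a convenience
  matching those summaries, not a mechanistic claim.
* **Signatures.**  Markers follow patient-specific baselines plus a
  flat-then-linear ramp anchored at $T^*$: WBC +1 K/uL over 72 h,
  temperature +0.5 F, sodium +2 mEq/L and heart rate -7 bpm over 24 h,
  plus i.i.d. measurement noise; glucose, creatinine and systolic blood
  pressure are flat.  After $T^*$ the ramp plateaus.  Measurements
  continue to death/discharge/horizon -- raw data cannot stop at a single
  "outcome time" when three outcomes occur at different times -- and the
  per-outcome truncation happens at the regularization step.
* **Surgery and scans.**  A scan is triggered at each latent threshold
  crossing (imaging prompted by deterioration), in addition to the
  scheduled irregular scans; readings add 0.25 mm noise.  28% of
  patients with an observed crossing undergo DHC at an exponential
  (mean 18 h) delay, while alive and in hospital.
* **Ground truth.**  `simulate_cohort()` exports every latent time and
  realized baseline, so estimator validation never has to re-derive
  truth from the generated tables.

What the generator does *not* emulate: treatments and their feedback on
markers (insulin, osmotherapy, antihypertensives), inter-variable
physiology beyond the shared event anchor, non-linear or per-patient
heterogeneous signature shapes, informative censoring, and
measurement-battery correlation (labs drawn together).  Passing tests
therefore demonstrate that the estimators recover what the generator
encodes under independent censoring -- not that real trajectories have
these shapes.

## Validation design

The test suite validates the pipeline at three levels, with problem sizes
chosen as the package's standing validation conditions:

* **Exact identities** (machine precision): product-limit identities on
  random fixtures of up to 50 records against brute-force oracles;
  interpolation exactness on affine signals; the reduction of the
  weighted backward estimator to case-only statistics on an uncensored
  200-patient cohort.
* **Parameter recovery** (Monte Carlo): 200 replicates of a 600-patient
  cohort with a single densely sampled marker (log-normal gaps, median
  2 h) carrying a unit ramp over a 72-hour onset, event times uniform on
  80-188 h so the full look-back window precedes every event, and
  independent discharge censoring at ~30% (and ~50%) of patients.  The
  Monte-Carlo mean of $\hat\mu(0) - \hat\mu(72)$ recovers the unit ramp
  within 5% under ~30% censoring and within 15% under ~50%; with a flat
  null the estimated trajectory stays within 3 Monte-Carlo standard
  errors of baseline at every lag.  Dense sampling is deliberate here:
  it isolates the estimator's selection-correction from sparse-sampling
  interpolation error, which is assessed separately.
* **Incidence calibration**: on exponential competing risks with a
  closed-form sub-distribution, the root-mean-square error of the
  estimate at 72 h shrinks across n = 100, 1 000, 10 000, and the 95%
  intervals cover the truth at the study's n = 635 within binomial
  tolerance over 1 000 replicates.

A final end-to-end check runs the full pipeline twice at the study scale
(n = 635) and requires byte-identical output tables.

## Numerical conventions

Inclusive thresholds throughout (`|Z| >= 3`, `>= 25%` change,
MLS `>= 5` mm; PGS strictly `> 4` mm).  Baseline values take the
measurement closest to admission within -8 h/+36 h, earlier measurement
on distance ties.  Dichotomous midpoint ties switch at the midpoint hour
itself.  Simultaneous event and competing/censoring times resolve to the
event.  A variable with zero pooled SD skips the Z rule with a warning; a
zero preceding value makes the relative-change rule undefined for that
row.  All randomness flows from a single integer seed per configuration;
identical configuration and seed reproduce cohorts, tables and estimates
bit for bit.

## Known limitations

The IPCW construction is the standard estimator for failure-time-anchored
marker distributions, validated here by its exact uncensored reduction
and by simulation; it is not claimed to be formula-identical to any
particular published variant.  The estimand conditions on surviving to
the outcome.  Trajectory shapes near lag 0 are masked for sparsely
sampled variables.  No smoothing, no imputation beyond interpolation, no
multivariable or dynamic risk modelling -- the package estimates
univariable descriptive trajectories and their uncertainty inputs, which
is the foundation such models would build on.
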