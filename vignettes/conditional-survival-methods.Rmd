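---
title: "Methods: conditional survival for ICU cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional survival for ICU cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icusurv)
```

## The estimand and its assumptions

For an admission-level ICU cohort, define the day-`d` conditional survival
as the probability of surviving to *hospital* discharge given that the
patient has already spent at least `d` days in the ICU. The estimator is
the plain binomial proportion over the day-`d` at-risk set — every
admission whose ICU length of stay (LOS) is at least `d`:

$$\widehat{cs}(d) = \frac{\#\{\mathrm{LOS} \ge d,\ \text{survived to discharge}\}}{\#\{\mathrm{LOS} \ge d\}}.$$

Two assumptions make this simple estimator valid:

* **No censoring.** Discharge status is recorded for every included
  admission (records without it are excluded, with accounting), so no
  Kaplan–Meier machinery is needed and none is used.
* **Integer-day at-risk convention.** "Already survived `d` days" is read
  as `LOS >= d` with `d` an integer, so a fractional stay participates up
  to its floor. Day 0 then includes every admission and
  `cs(0)` is exactly the cohort's overall hospital survival probability —
  a useful identity that the tests assert exactly.

The outcome is status at *hospital* discharge, wherever in the
hospitalization death occurred; patients stepped down from the ICU who die
on a ward still count as deaths.

## Confidence intervals

Each point gets an Agresti–Coull binomial interval. With
`z = qnorm((1 + conf)/2)` (the exact quantile, 1.959964 at 95%, not the
`z = 2` shortcut), `ñ = n + z²` and `p̃ = (x + z²/2)/ñ`, the interval is
`p̃ ± z √(p̃(1−p̃)/ñ)`, clipped to [0, 1]. The interval is centred at `p̃`,
so the reported point estimate `x/n` can sit off-centre; the package always
reports `x/n` and uses the adjusted proportion only inside the interval.
A simulation in the test suite (2,000 replicates at n ∈ {50, 200, 1000},
p ∈ {0.5, 0.8, 0.95}) checks that empirical coverage of the nominal 95%
interval never falls below 0.93.

## Truncation

Curves are reported from day 0 up to, and not including, the first day on
which fewer than `min_at_risk` admissions remain at risk (default 50).
Since at-risk sets are nested, the at-risk count is non-increasing and the
retained days are always a leading run. The threshold trades curve length
against interval width; it is configurable, and each age stratum is
truncated independently, so the smaller elderly stratum typically truncates
earlier.

## Inclusion criteria and accounting

Records are filtered sequentially — (1) age < 18 at ICU admission,
(2) not the patient's first ICU admission, (3) missing discharge status,
age, or LOS — so each excluded record is attributed to exactly one
criterion and counts conserve: the report's four categories always sum to
the raw total, which a property test asserts on randomized tables. The
missing-data percentage is reported against the included-plus-missing
denominator, the convention under which 524 missing-status exclusions
against 11,648 included admissions reads as 4.3%. Design choices made
where the contract was open: age exactly 18.0 is included; index admission
means first ICU admission over the whole dataset (not per hospitalization);
when an explicit admission-order column is absent the lexicographically
smallest admission identifier per patient is kept; missing sex never
excludes a record (sex is descriptive only); records with an unconfirmable
admission order (NA in a present column) fall under the missing-data step.

## LOESS smoothing

Figures show a locally weighted quadratic smooth of the per-day estimates
(span 0.5). The smoother is implemented in the package: for each target
day the `q = ceiling(span · N)` nearest points are tricube-weighted,
`w = (1 − (dist/dist_max)³)³`, and a weighted least-squares polynomial is
evaluated at the target. Three deliberate choices, each recorded in the
output metadata because conventions differ between implementations:

* **Degree 2** by default, the common default of reference local-regression
  tools; configurable to 0–2.
* **No robustness (bisquare) iterations** — a single gaussian-family pass.
* **Ties** at the neighbourhood boundary include the lower day first; the
  tricube weight at `dist = dist_max` is zero, so tie handling provably
  cannot change the fit (a symmetry test asserts this).

The tests require exact reproduction (≤ 1e−8) of polynomials up to the fit
degree and ≤ 1e−6 agreement with an independent reference implementation
(`stats::loess` with `surface = "direct"`, gaussian family) on a seeded
fixture. Smoothing is presentation-only: every exported statistic is the
raw proportion, and the smoothed confidence bands exist only for the dashed
lines in figures. Curves with fewer than 4 points are returned unsmoothed
with a warning rather than extrapolated.

## The synthetic cohort model

Restricted clinical databases cannot ship with a package, so validation
rests on a generative model with a computable truth:

* `LOS ~ LogNormal(μ, σ)`; the default `μ = log 2`,
  `σ = log 2 / qnorm(0.75) ≈ 1.028` gives median 2 days and quartiles
  exactly 1 and 4 days, the right-skewed stay distribution typical of
  large ICU databases.
* `age ~ Normal(64, 16)` truncated below at 18, giving a median near 64
  and ≈ 24.6% of admissions aged 75 or over.
* `P(death) = logistic(β₀ + β_LOS · min(LOS, cap) + β_age · 1[age ≥ 75])`
  with defaults `β₀ = −2.7`, `β_LOS = 0.15`/day, `cap = 10` days,
  `β_age = 0.7`. Under these defaults the model's exact day-0 mortality is
  12.1%, admission survival is ≈ 91% / 83% in the younger / elderly strata,
  and the true conditional-survival curve declines from 0.879 to a 0.733
  plateau reached at day 10 — the decline-then-plateau shape, stratum
  ordering, and realistic magnitudes together. These values were fixed once
  from the descriptive targets above and are not tuning knobs.

Death probability depends on the *realized total stay* (capped), not on a
day-by-day hazard process. The estimator only ever observes the pair
(LOS, final status), so this marginal structure is the minimal model that
induces the observable curve shapes, and it admits an exact oracle:

$$cs_{\text{true}}(d) = E\left[1 - \pi(L, A) \mid L \ge d\right]$$

computed by quadrature of the log-normal density conditioned on `L ≥ d`,
mixed over the two age strata with their truncated-normal masses. The
integral is taken in the CDF domain (`u = F(L)`), which bounds the
integrand by 1 and keeps the quadrature robust even for near-point-mass
LOS distributions; the region beyond the cap, where the death probability
is constant, is added in closed form; the tolerance is refined until
successive estimates differ by less than 1e−8. Conditioning on a day with
`P(L ≥ d) < 1e−12` is refused as degenerate. The oracle is checked against
a 5×10⁵-draw Monte-Carlo estimate (agreement within 3 standard errors at
every tested day) and against closed-form special cases: a point-mass LOS
with constant risk, and flat curves when both effects are zero.

What the generator does **not** emulate: inter-hospital transfers,
readmission dynamics, competing risks, time-varying severity, calendar
trends, or the heavier-than-log-normal extreme-stay tail of real ICU data.
Passing recovery tests therefore demonstrates estimator correctness under
a realistic stay/mortality joint distribution, not robustness to every
artefact of real databases.

## Numerical and degenerate-input policies

* At-risk day enumeration stops at the first zero count; `max_day` can cap
  it explicitly.
* A cohort (or stratum) smaller than `min_at_risk` yields an empty curve
  with a warning naming the stratum; the other strata are unaffected.
* Interval bounds are clipped to [0, 1]; `x = 0` and `x = n` are ordinary
  inputs.
* Unparseable vital-status strings become missing, never silently 0/1, and
  are resolved only by the exclusion step.
* All randomness in the generator flows from one seed; the caller's RNG
  state is saved and restored, so generation never perturbs a surrounding
  simulation.

## Problem sizes used in validation

The test suite exercises estimator–oracle recovery at 50,000 and 200,000
synthetic admissions, null-effect coverage at 100,000, brute-force
equivalence on 200 randomized cohorts of ≤ 20 records, and coverage
simulations of 2,000 replicates per condition; these sizes give
standard errors comfortably below the asserted tolerances at the curve
heads while keeping the suite quick to run. At the truncation tail any
fixed absolute tolerance is dominated by binomial noise — with 50 patients
at risk one standard error is ≈ 0.06 — so tail agreement is asserted in
standard-error units rather than as a fixed band.

## Known limitations

* The at-risk convention treats a 23-hour and a 0.1-day stay identically
  on day 0; sub-day resolution is out of scope.
* No plateau-detection algorithm is provided: curves are emitted and the
  plateau is the reader's visual judgement.
* No severity-of-illness adjustment, regression modelling, or
  between-stratum hypothesis testing; the stratified output is
  descriptive.
* LOESS degree and family are conventions, not fitted choices; both are
  echoed in artifact metadata so downstream users can detect a mismatch
  with other tooling.
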