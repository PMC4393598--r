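---
title: "Methods: bottom-up costing of ambulatory HIV care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottom-up costing of ambulatory HIV care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambucost)
```

This vignette documents the models and conventions behind `ambucost`:
what is computed, which parameters matter, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices made where the methodology left them open.

## The costing model

`ambucost` implements bottom-up (micro-) costing of one year of
outpatient HIV care from the service-provider perspective: every
resource used is enumerated and multiplied by its unit cost, in 2012
euros throughout (no inflation adjustment; the horizon is a single year
so nothing is discounted). Three components are costed:

* **Staff** — one cost line per *scheduled* appointment, priced by its
  appointment type. Eight types partition all appointments along three
  binary attributes: attended vs missed (DNA, "did not attend"), the
  clinic (weekly HIV clinic, monthly antenatal-HIV clinic, or a new
  patient's baseline visit), and whether the patient was on HAART on
  the appointment date. Missed appointments still consume
  administrative and pharmacy time and are priced unconditionally, even
  for patients later censored.
* **Diagnostics** — one line per laboratory, radiology or cardiology
  test. Codes that do not resolve in the unit-cost table fall back to
  the "all other tests" weighted-average price with a warning (an error
  in strict mode), mirroring the catch-all rows of the source table;
  the eight routine biochemistry profile names collapse to the pooled
  biochemistry price.
* **Drugs** — months of each HAART regimen dispensed times the monthly
  regimen price, plus prophylactic-antibiotic doses times the per-dose
  price. Months *dispensed* are used rather than coverage days so that
  wastage from regimen switching is captured; drug totals may therefore
  exceed on-treatment patient-months. Months may be fractional.

Out of scope, deliberately: inpatient, emergency-department, obstetric,
vaccine/tuberculin and non-infectious-disease outpatient costs, and the
staff time-and-motion measurement itself — unit costs are inputs.

## Follow-up and the ppm denominator

The headline statistic is the month-weighted average cost per patient
month: total cost over total patient-months, equivalently the
month-weighted mean of patient-level ppm values. Follow-up runs:

* from 1 January for existing patients, and from the first attended
  appointment for patients new to the service (an inpatient-admission
  start date cannot be represented without inpatient data, so the first
  attended appointment is used);
* to 31 December if the patient has any recorded event on or after
  1 July, otherwise to the date of their last scheduled appointment
  (the censoring rule). "Any event" means any appointment or test in
  the provided streams, since out-of-scope services are not recorded;
* a patient-month is 30.4375 days (365.25/12) — the methodology never
  fixes a month length, so the calendar average is used and stated.
  Both endpoint days count, so a patient in care for all of the 2012
  leap year contributes 366/30.4375 = 12.02 months. Denominators are
  kept fractional; only displayed tables round.

Patients with no attended appointment in the year fail the eligibility
rule; they are excluded from the ledger and reported, not costed.

HAART coverage intervals are half-open `[start, stop)` — the start day
counts as on treatment, the stop day as off — except that a stop on the
study end date is read as treatment ongoing through the last day. This
convention is configurable (`stop_inclusive`); the bundled brute-force
day-enumeration tests pin it down exactly. Laboratory tests link to a
same-day attended appointment; radiology and cardiology tests, which
need not fall on the visit date, link to the nearest attended
appointment on or before the test date; unlinked tests are reported and
still costed.

## Uncertainty

The methodology does not state how the printed interval estimates of
this literature are computed, so two options are provided and neither
is privileged:

* `ci_method = "normal"` (default): a normal-approximation interval for
  the weighted mean, using the weighted variance of patient-level ppm
  values with an effective-sample-size correction
  (n_eff = (Σw)²/Σw²);
* `ci_method = "bootstrap"`: a seeded patient-level resampling interval
  (default 2000 resamples).

Single-patient strata get a degenerate (`NA`) interval rather than a
fabricated one. One-way sensitivity analysis rescales staff lines by
±20% and diagnostic lines by ±60% (the published measurement
uncertainty of timed staff input and of diagnostic unit prices); drug
lines are never rescaled, so drug ppm is invariant across scenarios and
total ppm is monotone in each multiplier.

## Cost regressions

Cost data are right-skewed, so GLMs are used without transformation.

* **Family** — the modified Park test: a working GLM (default gamma,
  log link; configurable, e.g. Poisson for count-like responses)
  supplies fitted means μ̂, and the squared raw residuals are regressed
  on log μ̂ in a log-link quasi-Poisson GLM (the Manning–Mullahy form;
  OLS on log squared residuals is available as `method = "ols"`). The
  slope λ̂ estimates the power in Var(y|x) ∝ μ^λ and the family is the
  nearest of 0 (Gaussian), 1 (Poisson), 2 (gamma), 3 (inverse
  Gaussian).
* **Link** — power links g(μ) = μ^λ for λ on a grid (default 0 to 1 in
  steps of 0.1, with λ = 0 denoting the log link, the power-family
  limit) are screened with three diagnostics: the Pearson correlation
  test between raw residuals and predictions (the linear predictor can
  be substituted), the Pregibon link test (refit on the fitted linear
  predictor and its square; the squared term's p-value), and a modified
  Hosmer–Lemeshow test (an F-test that mean raw residuals are zero
  across ten equal-count groups of the predictions; ties broken by a
  stable sort). A link passes when all three p-values exceed α = 0.05.
  Among passing links the one with the largest minimum p-value is
  chosen — the selection rule is not specified in the source
  methodology, and "least evidence of mis-specification" is the natural
  tie-break; if nothing passes, the best-scoring link is returned
  flagged `no_link_passed`.
* **Logistic models** report exponentiated coefficients with Wald
  intervals; single-class outcomes are errors and likely separation is
  flagged per term. Chi-squared homogeneity tests are Pearson without
  continuity correction. "Unknown" categories stay as explicit factor
  levels; there is no imputation.

Two numerical notes. Power-link GLMs can lack valid starting values, so
fits restart from the observed response when the default
initialisation fails, and non-convergence is reported as such rather
than papered over. A family whose mean domain excludes the fitted line
(for instance a gamma GLM with identity link on strongly log-scaled
data) will often simply fail to converge — that failure *is* the
diagnostic outcome, which is why the link-misspecification power
property is demonstrated with a Gaussian family, where the wrong-link
fit exists and the Pregibon term must do the work.

All-categorical designs (the typical cost-regression covariate set)
produce few distinct predictions; the orchestrated pipeline therefore
coarsens the Hosmer–Lemeshow grouping to five groups and falls back to
the log link if no candidate link can be fit on a small cohort.

## The synthetic-cohort generator

`generate_cohort()` exists so every downstream stage is testable
without hospital records. Its defaults are the observed structure of
the reference 2012 cohort and are not tuning knobs:

* 326 patients with the published categorical mix (59% male, 13% aged
  50+, 41% from countries of high HIV prevalence, 92% existing
  patients, and so on), with the structural couplings enforced (only
  patients newly diagnosed in-year carry the `diagnosed_2012` band);
* scheduled appointments per patient: Poisson truncated to ≥ 1 (the
  simplest count model matching the observed mean 1315/326 ≈ 4.0 and
  support 1–15), with a 159/1315 DNA probability, a 44/1315 share of
  antenatal-clinic appointments (women only), and a baseline first
  visit for new patients;
* monitoring tests ride on attended appointments at the published
  per-visit rates (CD4, viral load, full blood count and biochemistry
  each just under once per visit; pooled "other" tests Poisson with
  mean 1262/1156, a fifth of them radiology/cardiology dated up to two
  weeks after the visit);
* HAART dispensing coverage matches the patient's treatment status
  (full-window coverage for patients on HAART throughout, a random
  sub-interval for starters/stoppers, none for untreated patients),
  regimens drawn with the published months-dispensed mix and a 45/304
  switching probability;
* censoring: with probability 0.05 a patient's events stop at a uniform
  date before 1 July, exercising the censoring rule. This probability
  and the antibiotic dispensing model (15% of patients, mean 56 doses)
  are not published quantities; they were fixed once at values that put
  the generated totals near the reference denominators (≈3650
  patient-months, ≈2700 doses) and are documented rather than
  revisited;
* one master seed drives an independent per-patient substream, so
  enlarging a cohort never perturbs already-generated patients, and
  identical configurations are bit-reproducible.

What it does **not** emulate: clinical trajectories (CD4 dynamics,
viral-load rebound), correlations between patient covariates beyond the
enforced structural couplings, seasonality of appointments, or the
patient-month shares by subgroup (matching both patient shares and
month shares simultaneously is under-determined; patient shares are
matched). Passing tests on this generator therefore demonstrate the
correctness of the accounting, linkage, censoring and estimation
machinery — not that real cohorts look like the simulation.

`generate_glm_dataset()` plants known GLM truths (family, power link,
coefficients, dispersion) for recovery tests; inverse-Gaussian deviates
use the Michael–Schucany–Haas transform. Simulation sizes used by the
bundled property tests were chosen to make the statistical checks
sharp at desk scale: n = 2000 per replicate for family and link
recovery (100 and 50 seeded replicates), n = 326 — the cohort scale —
for 500-replicate coefficient-coverage checks, and cohorts of 40–80
patients for the conservation and brute-force-oracle suites.

## Replication mode

`replicate_reference_costing()` runs the whole aggregate analysis from
the packaged fixtures: 23 unit-cost rows (8 appointment types, 5 test
prices, 7 regimen prices, 3 antibiotic prices), the matching resource
counts, and the 3659 patient-month denominator. It reproduces the
reference component ppm figures (staff €62, diagnostics €55, non-drug
€117, drugs €856, total €973; sensitivity €928–€1019; flat-price
benchmark €47) to within rounding of the printed unit costs, which are
themselves rounded to cents — hence the ±1 EUR comparison tolerance
used in the acceptance tests. Printed interval estimates and published
regression coefficients require the underlying patient-level records,
which are not deposited; they are covered instead by the property-based
suites above, with published effect sizes (for example a 0.139 female
effect on a power-0.2 scale) reused as planted truths.

## Known limitations

* The unit-cost table is clinic- and year-specific; transporting it to
  another setting reprices, not re-measures.
* The censoring rule can only see the provided event streams; patients
  whose only second-half-year contact was an out-of-scope service would
  be censored early.
* Weighted-normal intervals undercover when a handful of patients carry
  most of the months; the bootstrap option is preferable for small or
  very skewed strata.
* Park-test selection degrades for heavy-tailed families at large
  dispersion (the inverse-Gaussian recovery suite runs at dispersion
  0.02 for this reason) — with real cost data, inspecting λ̂ and its
  standard error beats trusting the argmin alone.
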