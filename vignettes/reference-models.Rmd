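---
title: "Methods: cohort semantics, reference models, and the synthetic EHR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort semantics, reference models, and the synthetic EHR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records how `ehrconsult`'s methods are defined, the choices
made where the design was genuinely open, and what the test suite does and
does not establish about real data.

## The common data model and code matching

Everything operates on a patients table (`patient_id`, `date_of_birth`,
`sex`) and one event table per domain (`diagnosis`, `procedure`,
`medication`, `observation`), each row a coded fact on a calendar date.
Dates, not date-times: routine coded data rarely carries reliable
within-day ordering, and every downstream rule is defined at day
resolution. Codes are canonicalized to uppercase with dots removed, so
`"M01.2"` and `"m012"` are the same code, and hierarchy filters in ICD-10
and OPCS-4 — chapter `"K"`, category `"M01"` — become prefix tests on the
canonical form. The coverage window (start and end of data capture) is
dataset metadata because it defines administrative censoring for
time-to-event work.

Pseudonyms are a keyed FNV-1a hash (two chained 32-bit passes, 16 hex
characters) of `salt:id`: deterministic for a fixed salt, revocable by
changing it, with collisions checked and rejected at build time. An empty
salt is refused outright.

## Cohort semantics

A cohort definition is an ordered list of criteria. Membership is:

1. **Entry.** Include criteria with role `index_candidate` are
   *alternatives*: the earliest event matching any of them is the member's
   index date. This matches "date of first X procedure" when a definition
   allows several entry events.
2. **Includes.** Every other include criterion must be satisfied under its
   temporal clause (`ever`, `on_or_after_index`, `before_index`), i.e. AND
   semantics across criteria; OR is expressed by listing several code
   prefixes inside one criterion. This covers all four shipped example
   phenotypes without a general boolean algebra.
3. **Excludes.** No exclude criterion may be satisfied under its clause.

Two deliberate conventions: the temporal default is `ever` (an exclusion
like "never transplanted" carries no qualifier), and a "subsequent" event on
the *same day* as the index counts as on-or-after. Day-resolution data
cannot order same-day events, and the conservative reading excludes more —
a cohort named "Transplant Success" should not contain a patient dialysed
on the day of transplant. Both conventions are encoded in the JSON schema
defaults and exercised by fixture tests; the engine itself is verified by
exact equivalence with an independently written brute-force per-patient
filter on hundreds of random instances.

## Suppression

Counts `1..threshold-1` are masked (default threshold 5, a common
disclosure-control floor), together with any percentage derived from a
masked count. Zeros are not masked: zero reveals only absence. Suppression
is idempotent and monotone in the threshold, applied before any
serialization or rendering, and rendered count cells are tagged so a report
can be scanned mechanically for violations. Complementary (secondary)
suppression is out of scope and stated as such.

## Comparative statistics

* **Relative risk.** `rr = (a/n1)/(b/n2)` per 3-character code category
  (patient-level counting), with the Katz log-normal interval. When a cell
  is zero, 0.5 is added to both event counts and 1 to both denominators and
  the estimate is flagged. The interval method is isolated behind one
  function so it can be swapped; coverage of the 95% interval is verified
  by simulation (2,000 tables, true RR 2) to be 95% ± 1.5%. Scan ties are
  broken by narrower interval, then code, so top-k lists are deterministic.
  No multiple-testing correction is applied — the scan is a descriptive,
  hypothesis-generating display, and reports carry a fixed
  associations-not-causation disclaimer.
* **Kruskal–Wallis.** Mid-ranks with the standard tie correction; when every
  value is identical the correction denominator vanishes and `H` is defined
  as 0. Verified against `stats::kruskal.test` to 1e-10.
* **Age at entry.** Ages are decimal years (`days/365.25`). Density curves
  use a Gaussian kernel with the normal-reference bandwidth (`"nrd0"`,
  overridable): the display is purely descriptive, and the location test is
  the rank test, not the density. A cohort reduced below two usable members
  contributes a flat zero curve rather than an error.

## Time to event

Durations run from the index date to the first matching event on or after
it; a same-day event is a time-0 event. Members without the event are
censored at `min(horizon, coverage end − index)`; the default horizon of 28
days matches the four-week operational question the module was designed
around. The product-limit estimator uses the standard convention that
events precede censorings at equal times, and is verified against
`survival::survfit` to 1e-10. Note one subtlety: *adding* a censored record
— even one censored after every event — changes the estimate, because it
enlarges every risk set; what is invariant is the exact value of censoring
times beyond the last event. The tests assert the latter.

## Reference models

The consult engine fits `y ~ family(mu(t), sigma(t), nu, tau)` over `t` =
days since cohort entry.

* **Families.** The sinh-arcsinh law in its standard four-parameter form,
  `F(y) = Phi(sinh(tau * asinh((y−mu)/sigma) − nu))`: location `mu`
  (observation units), scale `sigma > 0`, skewness `nu` (positive = right
  skew), tail weight `tau > 0` (below 1 = heavier tails); `nu = 0, tau = 1`
  is exactly the normal. The Logistic family (location/scale) serves for
  sparse single-patient trajectories. Comparator cohorts default to SHASH,
  the patient to Logistic.
* **Smooths.** `mu(t)` (identity link) and `log sigma(t)` are cubic
  B-splines with equally spaced knots and an order-2 difference penalty —
  20 basis functions by default, enough that the penalty, not the basis,
  controls smoothness; the order-2 penalty leaves linear trends unshrunk.
  `nu` and `tau` are constant scalars by default: they are weakly
  identified from moderate samples, and time-varying shape is rarely
  supported by a few hundred observations.
* **Optimization.** Cyclic per-block ascent on the penalized log-likelihood:
  BFGS with analytic score vectors for the two spline blocks (the log-scale
  block bounded, via the partition of unity, to keep `sigma` in
  `[~1e-6·sd(y), ~1e4·sd(y)]`), golden-section search on `nu ∈ [−8, 8]` and
  `log tau ∈ log[0.05, 20]`, up to 200 cycles, relative tolerance 1e-6 on
  the penalized objective. Initialization is deterministic (penalized least
  squares for `mu`, residual SD for `sigma`, `nu = 0`, `tau = 1`), inputs
  are sorted internally, so fits are exactly reproducible and
  order-invariant. Non-convergence sets a flag rather than throwing.
* **Smoothing parameter.** A single `lambda` shared by the two smooths,
  chosen by GAIC (AIC penalty) over the grid `10^{−2, 0, 2, 4, 6}` with warm
  starts, unless fixed by the caller. The effective dimension used in GAIC
  comes from Gaussian-approximation weights; it ranks candidates, it is not
  a rigorous degrees-of-freedom claim.
* **Guard rails.** SHASH with fewer than 50 observations falls back to the
  normal limit (`nu = 0, tau = 1` fixed) with a warning; fewer observations
  than spline coefficients is an error. Predictions outside the fitted time
  range are evaluated at the nearest boundary and flagged `extrapolated`,
  never refused: a consult must still score an out-of-window value, but the
  flag travels with it. Centiles are clamped to `[1e−12, 1−1e−12]` so
  extreme observations get finite z-scores.
* **Scoring.** The centile of an observation is the model CDF at the fitted
  parameters for its time; the z-score is its probit. The default consult
  window is 7–730 days post-index, excluding the immediate perioperative
  period and bounding follow-up at two years.

Recovery is tested on data generated from a known SHASH process (linear
location over `t ∈ [0, 3]`, `sigma = 5`, `nu = 0.5`, `tau = 1`, n = 500):
fitted median-curve RMSE at most 1.0 and 75th-centile training coverage
within 75% ± 4%; a patient constructed exactly on the 90th centile of the
generating law scores a median centile in [0.85, 0.95] against a model
fitted to roughly a thousand reference draws.

## The synthetic EHR generator

The generator emulates the *statistical structure* the analytics assume:
latent patient groups with lognormal-mixture ages at entry, per-code
Bernoulli prevalences, waiting-time laws (exponential or Weibull) for
follow-up events with natural administrative censoring at the coverage end,
homogeneous-Poisson visit processes, and SHASH observation trajectories
with time-varying location and scale. Each patient draws from a substream
derived from the master seed, so output is identical across runs and stable
under reordering. It does **not** emulate clinically plausible code
co-occurrence, coding variability, missingness mechanisms, or within-patient
correlation of observations — so green tests demonstrate correctness of the
machinery on data satisfying the model's assumptions, not robustness to
real-world coding noise.

Scenario parameters are fixed, documented choices, not calibrated fits
(the source distributions behind the motivating analyses are not public):

* `dialysis_meds` medication prevalences (0.96, 0.90, 0.89, 0.84, 0.81 for
  the top five generics, with a tail of lower-prevalence drugs and a
  therapeutic-class panel) reproduce the headline frequency pattern of a
  paediatric dialysis cohort.
* `effusion_rr` uses two groups with different comorbidity prevalences,
  including rare codes at roughly 27× and 23× risk, one moderate code at a
  true risk ratio of 3, and bimodal age mixtures with density modes at 1 and
  15 years; the effusion group is predominantly the younger mode.
* `echo_tte` waiting times are Weibull with shape
  `k = log(log 375 / log 2) / log(14/3) ≈ 1.39` and scale
  `3 / (log 2)^{1/k} ≈ 3.90`, the unique Weibull with median 3 days and
  ~1/375 probability beyond 14 days — i.e. half of patients scanned within
  three days and essentially all within two weeks. An exponential cannot
  satisfy both facts at once.
* `transplant_consult` creatinine declines exponentially towards a stable
  level (`mu(t) = 45 + 150·e^{−t/14}` µmol/L) with proportionally shrinking
  scale and right skew (`nu = 0.8`), sampled at ~20 visits over two years.

## Problem sizes and reporting

The shipped tests and the acceptance script use simulation sizes chosen to
make the statistical checks sharp while keeping a full run to a few
minutes on one core: 200-patient datasets for the cohort-engine oracle,
n = 500 for reference-model recovery, 2,000 replicates for interval
coverage, 1,250 patients for the medication-frequency check, 2,200 for the
two-cohort comparison, 375 for the echocardiography scenario.

Reports render to self-contained HTML (the canonical, diff-stable format);
a print-styled variant of the same document is provided for printing to
PDF, and no binary PDF engine is required or bundled. Every report carries
content hashes of the dataset and configuration, the seed, and the package
version, so an archived report is traceable to its inputs.

## Known limitations

Observations are treated as cross-sectionally independent given time — no
within-patient correlation modelling; the cohort language has no value
(threshold) criteria and no general boolean algebra; relative-risk scans
are unadjusted; there is no competing-risks handling or confidence bands on
survival curves; and family choice (SHASH vs Logistic) is a configuration,
not an automated selection.
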