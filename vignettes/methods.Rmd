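---
title: "Cohort design, estimators and the synthetic-EHR generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort design, estimators and the synthetic-EHR generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ishcohort` implements a retrospective cohort design for intentional
self-harm among users of a large health system, with prior traumatic brain
injury (TBI) and posttraumatic stress disorder (PTSD) as the exposure of
interest. This vignette records the design in full: the phenotype and its
assumptions, every tunable parameter with its default and rationale, the
numerical choices, what the synthetic generator does and does not emulate,
and the package's known limitations.

## The design

The unit of analysis is the veteran (patient). Input data are three
encounter-level administrative tables: patients (demographics, service
connection), encounters (one row per patient-date-setting visit) and
diagnoses (ICD-9-CM or ICD-10 codes attached to encounters). All analysis
is organized around a per-patient **index date**:

* A patient is a **case** if any encounter in the study window (default
  2008-01-01 to 2017-12-31) meets the self-harm phenotype; the index date
  is the date of the first such encounter, with same-date ties broken by
  the smallest encounter ID (deterministic and logged in the flag table).
* A **non-case** receives an index date drawn from their own encounter
  dates, such that the calendar distribution of non-case index dates
  matches the empirical distribution of case index dates. Without this
  matching, non-case lookbacks would concentrate wherever encounters are
  densest and utilization comparisons would be biased.

Everything else — exposure, eligibility, utilization, comorbidity — is
measured in the **5-year lookback**, the half-open interval
`[index − 5y, index)`. The index date itself is excluded deliberately: the
index encounter of a condition-C case carries a mental-disorder code, and
including it in the lookback would let the outcome encounter contaminate
the exposure and comorbidity measurements. A visit exactly 5 years before
the index date counts; calendar-year arithmetic clamps Feb 29 to Feb 28.

### The three-condition self-harm phenotype

An encounter is flagged when its codes satisfy any of:

* **A** — any code in the explicit self-harm set;
* **B** — at least one suicidal-ideation code *and* at least one
  injury-or-poisoning code;
* **C** — at least one injury-or-poisoning code *and* at least one
  mental-disorder code.

"Same encounter" means the same encounter record, not the same calendar
day; that is the strictest reading of condition conjunctions and avoids
joining unrelated same-day visits. A single code may satisfy both sides of
a conjunction when it belongs to both sets (set membership, not code-slot
exclusivity, is what the definition states). All satisfied conditions are
recorded, so the flag table doubles as an audit trail.

### Code sets are configuration

All six sets (explicit self-harm, ideation, injury/poisoning, mental
disorder, TBI, PTSD) are loaded from a delimited file with columns
`set_name`, `system`, `prefix`, `description`. Matching is by prefix on
dot-stripped, upper-cased codes, and is system-aware: an ICD-9 prefix
never matches an ICD-10 code. Prefix semantics was chosen because
administrative extracts vary in digit depth; `S06` should match every
`S06.*` code however deeply it is recorded. Range tokens (`800-999`,
`E800-E949`, `S00-T88`) are expanded to fixed-width prefixes at load time,
which keeps V/E/alpha codes out of numeric parsing at match time.

The bundled default file is a **reconstruction** of the claims-based
self-harm algorithm ranges used in this literature (explicit self-harm
E950–E958 / X71–X83 + T14.91 + the intent-encoded poisoning codes;
ideation V62.84 / R45.851; injury or poisoning 800–999 plus accidental
E-codes / S00–T88; mental disorder 290–319 / F01–F99) together with
standard diagnosis-code definitions of TBI and PTSD. The exact published
membership is not verifiable from public sources (e.g. whether late-effect
codes qualify), so the file is shipped as an editable default rather than
a constant, and any audited list can be dropped in without code changes.
The ICD-10 intent-encoded poisoning entries enumerate the common
`Tnn.mX2` filler pattern; categories whose subdivision uses a different
pattern are under-covered, which matters only if real data are run against
the bundled defaults rather than an audited list.

### Index-date matching

Matching uses calendar **monthly bins** (width configurable). For each
non-case, a bin is sampled from the empirical case-index distribution;
one of the patient's own encounter dates inside that bin is then drawn
uniformly. If the patient has no encounter in the sampled bin, the nearest
bin containing one is used, ties resolved toward the earlier bin. Monthly
granularity balances fidelity to the case distribution against the
sparsity of individual encounter histories. With no cases at all the
procedure degrades to uniform sampling over the patient's encounters, with
a message. Assignment is a pure function of the inputs and the seed.

### Eligibility and utilization

Eligibility requires **at least two distinct visit dates in the 5-year
lookback**. Two candidate rules coexist in this design space — two visits
in the 10-year window versus two in the lookback — and the package uses
the lookback rule as operative (the window rule is expressible by
configuration), because utilization is defined over the lookback and a
patient with fewer than two lookback visits has no meaningful utilization
denominator.

Utilization is distinct lookback visit dates divided by 5. Strata use the
at-or-below convention: LOW ≤ p50, MEDIUM ≤ p75, HIGH above. Defaults are
the reference cut points 6.6 and 15.6 visits/year; `thresholds =
"empirical"` recomputes them as type-1 (inverse-ECDF) quantiles of the
eligible cohort, which keeps "50th percentile and below" literally true in
the presence of ties.

### Covariates and comorbidity

Covariates are binned at the index date: age <30 / 30–44 / 45–69 / ≥70
(completed years), sex M/F, race with an `Other` catch-all, ethnicity
Hispanic / not, marital status with an explicit `Unknown` level (retained
in models — complete-case dropping would silently change denominators),
service connection None / <50% / ≥50% (a missing percentage is None; 50%
exactly is ≥50%).

The Charlson Comorbidity Index uses a bundled Quan-style
administrative-claims mapping over the 17 conditions with the original
1/2/3/6 weights, scored on lookback diagnoses from all settings. Each
condition counts once regardless of code repetition; the three standard
hierarchies apply (complicated diabetes over uncomplicated, metastatic
solid tumour over any malignancy, moderate/severe over mild liver
disease). Bands are half-open — LOW < 5, MEDIUM 5–15, HIGH > 15 — which
resolves an ambiguity between "<5" and "≤5" phrasings in favour of
non-overlapping intervals. No age points are added to the score: age is
its own covariate in the adjusted models and double-adjustment is worse
than a plain index. The scoring window equals the exposure lookback by
default (configurable), since no separate comorbidity window is part of
the design.

## Estimators

Per stratum (analyses are run independently inside LOW / MEDIUM / HIGH,
which is the informed-presence control):

* **Prevalence** per exposure group, reported half-up at 2 decimals, with
  the unrounded value retained on the object.
* **Bivariable odds ratios** from the 2×2 cells against the NEITHER group:
  point estimate ad/bc and the Woolf (log-normal) interval
  `exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`. A zero cell switches to the
  Haldane–Anscombe +0.5 correction and flags the method. Woolf was chosen
  because it is the standard closed form and agrees with the Wald interval
  of a saturated logistic fit, making the two routes mutually checkable.
* **Adjusted models**: minimally adjusted (age, sex, race) and fully
  adjusted (plus ethnicity, marital status, service connection, CCI band)
  logistic regressions, exposure group entered with NEITHER forced as the
  reference and other factors referenced to their largest observed
  category (all reference levels are recorded on the fit and in the run
  manifest). The constant 1.96 is used literally throughout rather than
  the 0.975 normal quantile, so closed-form and model intervals agree
  exactly.

The IRLS fit declares convergence when the maximum absolute score falls
below 1e-8, caps at 50 iterations (a capped fit warns and is flagged, not
silently returned), errors on rank-deficient designs naming the aliased
columns, drops single-level factors with a message (a fixture cohort can
have a constant CCI band), and flags quasi-separation when any coefficient
passes 15 on the log-odds scale. Weights are floored at 1e-12 to keep the
information matrix invertible near fitted probabilities of 0 or 1.

## The synthetic generator

The generator emits the three input tables plus a truth table, under one
seed, byte-identically reproducible. Its defaults encode the study
conditions: a 10-year window (2008-01-01..2017-12-31), ICD-9 before and
ICD-10 after the 2015-10-01 coding transition (so both dialects are
exercised in every full-window run), utilization bands positioned against
the 6.6 / 15.6 visits-per-year cut points, exposure-group and covariate
margins emulating the reference cohort's composition (about 50/25/25
across strata; 1.4% TBI only, 13.3% PTSD only, 1.5% comorbid; 93% male;
three quarters White; a third service-connected ≥50%).

**Fixture mode** takes an exact cell-count table (stratum × exposure
group × outcome) and constructs patients so the pipeline recovers every
cell with zero error:

* *Cases* draw an index date uniformly over the window, their target
  number of distinct visit dates uniformly inside the stratum's count
  band, placed by without-replacement sampling strictly inside the
  lookback, exposure codes on their two earliest lookback visits, and the
  qualifying self-harm codes (rotating conditions A/B/C) on the index
  encounter only. The pipeline's case index therefore equals the
  generation index exactly, and exposure codes cannot leak outside the
  lookback (a tested invariant).
* *Non-cases* pose a subtler problem: the pipeline itself re-draws their
  index dates, so any construction that pins exposure or utilization to
  one specific lookback would be misclassified whenever the pipeline
  samples a different admissible index. Non-case histories are therefore
  **stationary**: a regular visit grid with step `g` spanning the window
  plus a 5.5-year margin, with `g` chosen so that every possible 5-year
  window contains a within-band number of grid dates (both 1826- and
  1827-day lookbacks are checked when admitting `g`), and exposure codes
  re-attached at 750–1520-day cadence so every possible lookback contains
  them. Classification is then invariant over *every* admissible index
  date — a stronger, tested replacement for per-index code containment,
  and the property that makes the fixture round trip exact for arbitrary
  seeds. Visit-count bands are kept two counts clear of the 33/78 band
  edges so grid jitter cannot cross a threshold.

**Stochastic mode** draws outcomes per patient from
`P(outcome) = logistic(intercept + group effect + covariate effects)`,
then materializes tables with the same machinery. For estimator-level
simulation studies, `simulate_cohort_rows()` skips table materialization
and produces analysis-ready rows directly; `simulate_recovery()` uses it
to run planted-effect coverage experiments. The bivariable design plants
the high-utilization reference effects (log-odds ln 2.81 / ln 3.21 /
ln 6.72 on a 1.9% baseline); the full design plants ln 2.44 / ln 2.90 /
ln 4.26 under genuine confounding — exposure-group probabilities depend
on age band while age and the other covariates also shift the outcome —
so only the adjusted model is expected to recover the planted values.
Replicates use independently scattered RNG streams (drawn from a seeded
master stream); arithmetic seed progressions produced visibly correlated
replicate outcomes.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: no disease trajectories or code co-occurrence
structure (coded events are planted, not emergent); visit processes are a
regular grid or uniform draws, not clustered around illness episodes;
covariates are sampled independently of exposure in fixture mode, so
fixture AORs approximately equal crude ORs; no mortality or censoring; no
out-of-system care; coding practice is clean (real extracts have digit
truncation, miscoded systems, duplicate claims). Fixture-mode non-case
tables also contain pre-window encounters (the stationary margin), which
the pipeline handles because lookbacks are defined relative to index
dates, not clamped to the window.

## Validation sizes and determinism

The shipped validation uses: the full reference cell counts for the
arithmetic checks; a 1/100-scale fixture (about 67,000 patients, 10
million encounter rows) for the end-to-end round trip; 50 random tables
for the saturated-model identity at 1e-6; 100 replicates of n = 50,000
for each recovery design; and 10,000 random code bags against a
brute-force evaluator for the phenotype. These sizes give stable
pass/fail behaviour at interactive runtimes; the round trip is exact by
construction at any scale, and coverage at these sizes sits at 94–97 out
of 100 across seeds against the ≥93 acceptance bar.

Every stochastic step threads an explicit seed (generator config, index
assignment, recovery replicates), callers' RNG state is restored, and the
run manifest records seed, thresholds, reference levels and code-file
checksums, so a manifest suffices to reproduce a bundle bit-for-bit.

## Limitations

Bivariable odds ratios recomputed from the reference cell counts
reproduce the published high-utilization values exactly but differ by
roughly 0.01–0.16 in the low and medium strata (e.g. 9.12 recomputed vs
9.05 printed); the source of that discrepancy is not identifiable from
the published material, so only the high stratum is treated as exactly
reproducible and the low/medium values are validated by construction
(fixture round trip) instead. Published *adjusted* ORs are not
desk-reproducible at all without the original microdata; the package
validates its adjusted models by planted-effect recovery. The bundled
code lists are reconstructions, as discussed; results on real data depend
on substituting audited lists. The design estimates association, not
causation: no severity measures, no time-to-event structure, and exposure
misclassification from care received outside the system all remain.
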