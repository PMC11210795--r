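---
title: "Study-specific data quality assessment: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Study-specific data quality assessment: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package does

`ehrdq` implements study-specific data quality assessment (SSDQA) for
multi-site EHR studies staged in a simplified PCORnet-style common data
model. Generic network curation asks whether data conform to a model;
study-specific assessment asks whether the data can support one study's
analytic plan — here, a pediatric chronic kidney disease (CKD) cohort study
whose eligibility hinges on estimated glomerular filtration rate (eGFR), and
whose exposures are blood pressure and antihypertensive medication. The
package provides:

1. a six-domain relational data model (patients, visits, vitals, labs,
   medications, procedures) with CSV readers/writers and conformance
   validation;
2. a multi-site synthetic EHR generator with injectable data-quality faults
   and a ground-truth plant registry;
3. pediatric eGFR and an eleven-step sequential cohort attrition pipeline;
4. a catalog-driven check engine with two execution modes — aggregate-only
   (distributed, DQ1) and row-level (centralized, DQ2);
5. rule-based issue detection, prioritization, theme assignment, and
   cross-round improvement tracking;
6. anonymized cross-site reporting and a command-line interface.

## The data model and its conformance rules

The six domains carry exactly the fields the checks exercise. Coded fields
have closed value sets (ethnicity, geocode granularity, visit type, vital
measure, lab, drug class, procedure code group). Units are stored verbatim;
a lab record's `mapped_unit` flag is defined as "unit present and in the
lab's allowed set", so unit mapping is a conformance *check*, not a
conversion service — a deliberate choice, since silent unit conversion would
hide exactly the extraction errors the framework is meant to surface.
`validate_conformance()` reports one finding per violated invariant (bad
code, unmapped unit, duplicate patient id, in-person flag inconsistent with
visit type, non-positive quantitative value) with the affected site and
record count.

Dates are ISO-8601 calendar dates and every interval is closed on both ends:
"within 90 days" means |Δdays| ≤ 90. Writers sort rows canonically
(site, patient, date, domain key) so repeated writes are byte-identical and
`load(write(d))` is an identity.

## Pediatric eGFR and the attrition pipeline

eGFR uses the bedside Schwartz estimator,

  eGFR = 0.413 × height(cm) / SCr(mg/dL)  [mL/min/1.73m²],

the standard pediatric form when only height and serum creatinine are
available. Cystatin-C-based estimation is excluded from the pipeline: in
this framework serum cystatin C is itself a monitored variable with known
capture problems, and creatinine is the primary kidney-function input.

Each serum creatinine drawn at age 1–18 (fractional years, closed window) is
paired with the nearest-in-time height within ±90 days; on an exact tie the
earlier height wins (deterministic and auditable), and when several heights
share the chosen day the smallest value is used. Creatinines with no
eligible height yield no eGFR.

The attrition pipeline applies eleven sequential filters: any encounter in
the 2009–2021 study interval; any in-person visit; ≥1 serum creatinine; age
1–18 at measurement; height within 90 days; ≥1 eGFR in [30, 90); two
additional in-range eGFRs each ≥90 days after the first; no intervening
normal (≥90) eGFR between the first and each additional qualifying value; an
in-person nephrology visit; and no chronic dialysis or kidney transplant
codes strictly before cohort entry. A patient counted at step k satisfies
steps 0..k, so per-site counts are non-increasing by construction.

Three points were genuinely open and are fixed here as package policy:

* the eligibility interval is [30, 90) — the definition of "normal" as ≥90
  forces the upper bound open, and 30 is inclusive;
* the cohort entry date (CED) is the date of the *first* eGFR of the
  earliest sequence satisfying the qualifying steps;
* "90 days apart" is measured from the first qualifying eGFR to each
  additional one (first-vs-each rule), and qualifying values are counted on
  distinct calendar days.

The pipeline is verified against a brute-force oracle that tests each
patient against each criterion with exhaustive loops, on hundreds of
randomized small datasets.

## The synthetic network

`generate_network()` emulates a 15-site pediatric network observed 2009–2021
(1,000 patients per site by default, about 30% with CKD — a referral-center
case mix, not population prevalence). Heights follow a piecewise-linear
median growth curve (75 cm at age 1, 140 cm at age 12, 170 cm at age 18)
plus a patient-level offset: only ordinal plausibility matters for the
checks, not anthropometric fidelity. CKD patients carry a linear eGFR
trajectory — anchor value uniform on (30, 90) at a uniform age 3–10, decline
normal with mean −3 and SD 0.5 mL/min/1.73m² per year, floored at 5 — and
serum creatinine is back-computed by inverting the Schwartz relation at the
patient's height, with a height vital recorded on every creatinine date. The
truth registry therefore stores the eGFR *implied by the stored records*
(0.413·height/SCr at generation time), which the pipeline must recover with
zero median absolute error; the implied value agrees with the simulation
target to floating-point round-off (~1e-16 relative), which is asserted
separately, because a divide-then-multiply round trip is not always exact in
binary floating point.

Blood pressures are bivariate normal (means 105/65 mmHg, SDs 12/9) with a
configurable correlation (default 0.6); only the correlation check consumes
the distribution, so no claim of clinical realism is made beyond it.
Medication start times place roughly 20% of first antihypertensives before
cohort entry, so that a site where the *majority* start before entry is
anomalous. Chronic dialysis codes begin when a trajectory crosses
25 mL/min/1.73m², i.e. after cohort entry, keeping the exclusion steps
nearly lossless on clean data.

What the generator does *not* emulate: coding vocabularies (ICD/CPT),
comorbidity structure, demographic realism, visit-type practice variation
beyond random assignment, or inter-site case-mix differences. Passing tests
on this data therefore demonstrate that the detection machinery finds the
engineered fault classes at their default magnitudes against homogeneous
background variation — not that it would achieve the same recall or
specificity against real inter-institutional heterogeneity, where fences
widen and judgment calls multiply.

### Anomaly kinds and their expected signatures

Eleven injectable fault classes mirror recurrent real-world findings:
nephrology specialty dropped in ETL; duplicate height extraction; heights in
inches stored as centimeters; laboratory results defaulted to 9999;
qualitative urine protein results converted to mass points (60/100/150
mg/dL); a calendar year of a lab missing; a visit-volume spike year;
antihypertensive starts compressed into the weeks before cohort entry;
geocode granularity downgraded; an unmapped ethnicity code; and late data
onset (no records before a cutoff year). Each plant writes a registry entry
with the issue code and data element the pipeline is expected to emit, which
is the acceptance surface for recall. Default magnitudes are set so
detection is unambiguous (the real study does not quantify most of them) and
are configurable.

## The check catalogs and execution modes

The two encoded catalogs reproduce the published structure of the source
framework: 79 aggregate-round checks with per-domain counts
(8 anthropometrics, 8 vital signs, 8 diagnoses/conditions, 16 laboratory,
24 medications, 8 procedures, 4 other eligibility, 1 secular trends,
1 specialty, 1 follow-up) and category tallies 29/14/17/34
(completeness/concordance/conformance/plausibility); and 65 row-level checks
over 13 domains summing to 68 assignments with exactly 3 dual-domain checks
and tallies 26/5/8/9/27 (adding consistency). Category tallies exceed check
counts because one check's output can be post-processed for several
categories; the reconciliation uses 15 and 10 dual-category checks
respectively. The individual check texts are synthesized — the published
per-domain and per-category distributions are the only verifiable surface —
and each entry binds to one of the executor families below or to `unbound`
(diagnosis-domain checks, which the six-domain model cannot execute; the
engine skips them with a message).

Executor families: completeness trend (per-site-per-year proportion of
active patients with a record), same-day systolic/diastolic concordance,
blood-pressure correlation (same-day patient means, Pearson r, ≥3 pairs),
unit-mapped proportion, code utilization (one code per patient per calendar
year; codes under 0.5% pooled prevalence dropped; zero rows preserved),
antihypertensive timing relative to CED (quartiles and fraction negative),
geocode granularity proportions, value distributions (type-7 quartiles, top
exact-value mass, out-of-range fraction against configured physiologic
bounds — urine protein 0–5000 mg/dL, height 60–220 cm), the attrition
funnel, eGFR threshold curves and trajectory medians, and generic yearly
counts, per-patient density and category frequencies.

DQ1 mode computes each site's aggregates from that site's rows in isolation
(the aggregate-only contract of a distributed query: results carry site,
stratum, value, denominator — never a patient identifier); DQ2 computes from
pooled rows. For every dual-mode check the per-site values are bit-identical
between modes. The one cross-site operation — the pooled prevalence filter
of the code-utilization matrix — is deliberately implemented as
coordinating-center post-processing of the collected per-site aggregates, so
the contract holds exactly in both modes. Completeness denominators are
"patients active in the year" (≥1 visit); the encounter trend itself uses
all of a site's patients as denominator over the full study interval, which
is the surface on which late data onset is detected.

## Issue detection, priorities, themes

Detectors are deliberately simple, transparent rules:

* **Missing years.** A site-variable with zero completeness in years
  strictly inside its data span yields a missingness issue listing the
  years; a run of zeros at the start yields a late-onset issue (for the
  encounter trend the element is cohort entry itself); an all-zero span is
  total missingness.
* **Spikes.** Yearly counts (≥4 years) are scored by leave-one-out z-score
  with the SD floored at 5% of the leave-one-out mean; |z| > 2 is a
  high/low spike. The floor makes near-constant series testable (a plain SD
  of zero would make any deviation infinite) and is configurable.
* **Cross-site outliers.** Tukey fences (type-7 quartiles, 1.5×IQR) over
  per-site values, with a guard requiring at least 20% relative deviation
  from the cross-site median. The guard exists because with 15 sites and
  ~100 fence evaluations per round, pure fences on near-identical binomial
  proportions flag sampling noise at a rate that would swamp the catalog;
  "differs significantly from most institutions" is read as requiring a
  material difference. Fewer than 5 sites yields no result.
* **Value anomalies.** Top exact-value mass above 10% is an atypical numeric
  distribution; any out-of-range fraction is outlier values; an expected-
  positive correlation below 0.2 is discordant values; a majority of a
  site's cohort starting antihypertensives before entry is an event-
  sequencing anomaly.
* **Conformance findings** become mapping-error (or discordant/outlier)
  issues directly.

Priorities come from a decision table calibrated to the thirteen published
site-summary rows, which it reproduces row-for-row (2 urgent, 1 high, 7
medium, 3 low): attrition-step count anomalies and out-of-range values on
eligibility-tier elements are urgent, as is total missingness of an
eligibility element; interior-year missingness is high for
eligibility/exposure tiers and medium otherwise; expected-sparse elements
(serum cystatin C, urine creatinine, dialysis and transplant codes) and
medication count anomalies are low; late onset, secondary-cohort counts,
spikes and the remaining distributional anomalies are medium. The variable
tier map ranks eligibility > exposures/outcomes > covariates; blood pressure
is the exposure surface dense enough for year-coverage expectations, while
medication orders are not (a pediatric site can legitimately have an
antihypertensive-free calendar year), so medication elements sit in the
covariate tier for missingness purposes. Themes are a many-to-one lookup
into the eleven published theme labels; an issue can carry several and
always gets at least one.

Round comparison re-runs detection on the later round's results: an issue is
resolved exactly when its (site, element, issue-code) signature no longer
triggers, in which case its status becomes "improvement"; an issue whose
metric moved but still triggers stays unresolved with both metrics reported.

## Problem sizes and numerical choices

The validation suite uses the full default simulation (15 sites × 1,000
patients, ~600k visits and ~1.5M vitals) for recall, specificity and
parameter-recovery checks, a 5-site × 200-patient network for
mode-equivalence, and 200 randomized ≤50-patient datasets for the attrition
oracle. Parameter recovery is measured as: every per-site blood-pressure
correlation within ±0.05 of the generated 0.6 (≥10,000 pooled pairs), and
the slope of pooled post-entry trajectory medians (year offsets 0–6) within
±1 of the generated −3 mL/min/1.73m²/yr. Offsets are restricted to the
post-entry range because the pre-entry medians sit in the normal-eGFR regime
(patients are sampled into the cohort at their first low value), so a fit
across the entry discontinuity measures the case mix, not the decline rate;
the 0–6 window keeps every offset populated by essentially the same patient
composition. Quantiles are type-7 throughout (R's default, and what the
fence calibration assumes). Empty inputs are legal everywhere: an empty
cohort, a site without records of a lab, or fewer sites than the fence
minimum produce empty results, not errors.

## Known limitations

The framework detects the anomaly classes it models; it does not attribute
root causes (ETL versus source data is an annotation, not an inference), and
the issue catalog's resolution statuses other than "improvement" are
human-assigned labels. The diagnosis-domain checks of the encoded catalogs
are structural placeholders without executors, since the simplified data
model carries no diagnosis table. Spike detection on strongly trending
series can flag trend endpoints as medium-priority issues; that is accepted
noise at default thresholds rather than a calibration target. Synthetic
specificity (no urgent/high issues at unplanted sites) is a property of the
homogeneous generator and should not be extrapolated to real networks.
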