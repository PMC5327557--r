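---
title: "Validating cancer case-ascertainment algorithms against a registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating cancer case-ascertainment algorithms against a registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseval)
```

## The problem

Statutory population-based cancer registries are the accepted gold standard
for identifying incident cancer cases, but their quality-assurance cycle
means records are released years after diagnosis.  Hospital admission
collections, emergency presentations, medical and pharmaceutical claims and
death records are far more current, and people with cancers such as
colorectal or lung cancer almost always leave traces in them: a discharge
diagnosis code, a resection procedure, a chemotherapy supply, a cause of
death.  The question this package operationalises is *how far can such
surrogate indicators stand in for the registry*, and it answers it the way
validation studies in this field do: define code-list indicators over each
source, match the people they flag against registry diagnoses inside a
temporal window, and summarise agreement as sensitivity, specificity and
positive predictive value (PPV).

Throughout, the *person*, not the event, is the unit of analysis, and one
cancer type is evaluated at a time.

## Temporal model

Registries typically release the month and year of diagnosis but not the
day.  All matching in this package therefore happens on a linear month
index, `12 * year + (month - 1)`; days, where a source supplies them, are
used only to order events *within* a month when choosing the first
occurrence (dated events before undated ones, then day, then slot order —
a deterministic total order, so reruns are reproducible).  An indicator's
ascertainment date is the *first* matching event's date: the admission
date rather than the discharge date for hospital episodes, the
presentation date for emergency records, the service or supply date for
claims, the date of death for death records.

A person is a **true positive** for an indicator, cancer type and matching
half-width $W$ (months) when they have both a registry diagnosis inside
the evaluation window and a first ascertainment within $W$ months either
side of the diagnosis month.  A registry case that is flagged only
*outside* the window is deliberately given a dual label, `FN_and_FP`: it
counts as a miss for sensitivity (the indicator did not find the case when
it mattered) *and* as a false alarm for PPV (the flagged person is not a
window-matched case).  This is the only reading under which the usual
sensitivity and PPV contracts — sensitivity = TP / registry cases, PPV =
TP / identified — stay simultaneously consistent.  Specificity is TN /
non-cases, where non-cases are persons with no in-window registry record
of the evaluated type; it does not depend on $W$, because whether a
*non-case* is flagged has nothing to do with matching.

The default half-widths are 12 months (primary) and 3 months
(sensitivity analysis): a year either side absorbs the reporting lag
between clinical contact and registry notification, while the 3-month
window shows how much of the agreement is near-contemporaneous.

## Indicators and their algebra

An indicator is declarative: a source, a slot role (diagnosis, procedure,
claims item, cause of death), a coding system, and a code set whose
entries are exact codes or prefix patterns.  Matching is performed on
dot-stripped upper-case codes, so the three-character ICD-10 category
`C18` covers `C18.0`–`C18.9`; a secondary-site code (`C78.5`) never
matches a primary-site set.  The shipped defaults are the ICD-10 category
sets colorectal = {C18, C19, C20} and lung = {C34}, history-of-malignancy
codes Z85.0/Z85.1, and C77–C79 as the secondary/metastatic categories;
procedure and claims item lists are jurisdiction-specific and always
user-configurable (the package ships the synthetic generator's own
vocabularies as placeholders).  Codes only ever match within one coding
system: emergency collections mixing ICD-9 and SNOMED need an explicit
recode upstream, because silent cross-system matching is exactly the kind
of behaviour a validation study is meant to expose.

Composites combine indicators with `OR` and `AND` (AND binds tighter;
parentheses allowed).  An `OR` takes the union of persons with the
elementwise-earliest date, ties within a month resolved by input order.
An `AND` takes the intersection and is dated by its *anchor* leaf — by
default the first leaf, conventionally the cancer-diagnosis indicator.
The design question here was genuinely open: an AND-composite could be
dated by the earliest or latest component instead.  We date by the anchor
because composites of the form "hospital diagnosis *and* surgery" read as
"diagnosis cases who also had treatment", and the diagnosis admission is
the clinically meaningful ascertainment date; dating by the treatment
would systematically shift lags without changing membership.  A
consequence worth knowing: with first-occurrence dating, *metric*
dominance of combinations (OR sensitivity at least each component's) is
guaranteed only when no component fires far before diagnosis; membership
dominance (OR flags a superset, AND a subset) holds unconditionally, and
the test suite distinguishes the two.

## Reported quantities beyond the 2-by-2 table

* **Lag profile** — cumulative sensitivity and PPV counting true
  positives first identified 0, 1, …, $W$ months after the diagnosis
  month; cases identified *before* the diagnosis month are reported
  separately as the negative-lag fraction, so the profile at $W$ plus
  that fraction reconstructs overall sensitivity exactly.
* **Mismatch characterisation** — registry cases the indicator matched
  versus missed, compared on spread of disease at diagnosis, remoteness,
  share in the two most disadvantaged SES quintiles, residence near a
  state border, age at diagnosis (median, IQR) and death shortly after
  diagnosis.  Systematic differences here tell you *who* a surrogate
  under-ascertains — typically people with little health-system contact
  or hospitalised out of state.
* **Death-record discordance triage** — people flagged by a death-record
  indicator with no in-window registry record are assigned, in order:
  prior registry record before the window (prevalent disease), any
  secondary-site code in their linked records (miscertified secondary
  cancer), else other disease of the site.
* **Date-agnostic PPV** — the share of flagged persons with a registry
  record at *any* date.  It always bounds the windowed PPV from above,
  and the gap measures how much apparent false-positive load is prevalent
  disease rather than miscoding.
* **Incremental cases** — the point of the exercise: persons first
  ascertained after the registry's last month with no registry record at
  all, expressed as a percentage of the incident registry base
  (post-baseline diagnoses).

Confidence intervals are Wilson score intervals at 95%: they respect the
[0, 1] range, behave at the boundary (an observed 0/n or n/n still gives
an informative interval) and are the standard choice for proportions near
1, where validity metrics live.  A symmetric normal interval is available
as an option for comparison.  When nothing is identified, PPV is reported
as undefined (`NA` with a flag), never as 0.

## Cohort eligibility

Two exclusion rules run before any evaluation: persons under the minimum
baseline age (default 45 years), and persons with irreconcilable linked
records, operationalised as any administrative event dated strictly after
the person's death at month precision (a same-month admission and death
is accepted, since the admission may precede the death within the month).
Exclusion is idempotent and removes the person's events and registry
records along with them.

## The synthetic cohort generator

Real linked cohorts of this kind are privacy-restricted, so the package
carries its own: `generate_cohort()` draws a cohort whose statistical
structure mirrors a mid-to-older-age cohort linked to inpatient,
emergency, claims, pharmaceutical and death collections plus a registry.
Per cancer type it simulates:

* incident diagnosis at a constant monthly probability over the window
  (defaults 1.45e-4 colorectal, 6.6e-5 lung — roughly the case volumes a
  45+ cohort accrues over five years), with the diagnosis month uniform
  over the window;
* detection: a true case ever receives a matching inpatient code with
  probability `p_code` (defaults 0.97 colorectal, 0.87 lung — colorectal
  cancer is almost always resected in hospital, lung cancer is treated
  out of hospital more often), at a lag drawn from a configurable mass
  function whose support includes one pre-diagnosis month (admissions for
  the workup that precedes registry notification) and a small tail beyond
  12 months (which is what creates `FN_and_FP` cases);
* interstate leakage: border residents (8% by default) have `p_code`
  multiplied by a capture penalty (default 0.5), emulating admissions in
  another state's collection;
* contamination, split into two labelled mechanisms because they behave
  differently: *prevalent re-coding* (people diagnosed before the window
  whose old cancer is re-coded at a later admission — these drive the gap
  between date-agnostic and windowed PPV) and *pure miscoding* (a spurious
  code in a person with no cancer history, at a per-person-month rate);
* mortality: monthly case fatality after diagnosis (0.012 colorectal,
  0.045 lung), death records whose certificate carries the cancer with
  probability `p_death_cause`, secondary-site miscertification of another
  type's death, and rare miscertified deaths in people with no cancer at
  all — the three mechanisms the discordance triage is designed to
  recover;
* treatment and background records (surgery procedures, claims items,
  drug supplies, emergency presentations) so that composite indicators
  have something to combine, including background treatment in
  non-cases, since resections and cytotoxics are not exclusive to one
  cancer.

All draws come from one seeded generator that spawns a sub-seed per
mechanism and source, so identical configurations and seeds give
byte-identical tables and adding a mechanism draws from a fresh stream.
Every emitted event is traceable in the ground truth to exactly one
mechanism.

### Closed forms and what they require

`expected_metrics()` gives exact analytic expectations for the inpatient
diagnosis indicator: sensitivity is the border-marginalised code
probability times the lag mass inside $W$, each lag term attenuated by a
window-truncation factor (a diagnosis near the window edge can push the
admission outside it) and a survival factor (nobody is admitted after
death); specificity and PPV follow from the prevalent-re-code and miscode
probabilities.  Exactness — every empirical metric is conditionally
binomial around its closed form — rests on three deliberate
simplifications: cancer statuses are mutually exclusive across types
within a person (dual primaries within five years are rare), miscoding is
confined to persons with no true cancer history (misclassification among
true cases is dominated by true coding anyway), and repeat admissions are
only emitted after an in-window first admission.  These are modelling
choices, not bugs; they are what make parameter recovery a sharp test:
across simulated cohorts the 95% Wilson interval around each empirical
metric must cover the closed form at its nominal rate.

### What passing tests do and do not show

The generator reproduces the *mechanisms* of the study design — lagged
coding, prevalent contamination, capture loss, death-certificate error —
with independence assumptions real data do not satisfy: no seasonality,
no correlation between deprivation and health-system contact, no
within-hospital coding styles, constant hazards, and demographics
independent of detection except through the border flag.  Green
parameter-recovery tests therefore certify the *pipeline arithmetic*, not
the real-world validity of any particular indicator, which can only come
from a study against a real registry.

## Numerical and interface choices

* Dates are ISO 8601 text (`YYYY-MM` accepted wherever month precision is
  allowed); tables are RFC-4180 CSV in UTF-8; code slots may arrive wide
  (one column per slot, as inpatient extracts usually do) or long, as the
  schema declares.
* Degenerate inputs are defined, not errors: empty ascertainment sets
  classify everything FN/TN, an empty mismatch group is flagged
  degenerate, a zero base makes the incremental percentage undefined.
* The "optimal algorithm" is made explicit as lexicographic
  (sensitivity, then PPV) subject to a configurable PPV floor (default
  0.8), mirroring how such studies pick their headline indicator by
  inspection.
* Evaluation windows must lie inside the relevant source's coverage —
  differing data availability across sources is configuration, not
  something inferred from the data.  When a composite algorithm is
  extended past the registry for incremental counting, the extension uses
  its anchor leaf only, again because the composite's other sources may
  end earlier.
* Reported percentages are rounded to the nearest integer for display;
  machine-precision values are retained in all outputs.
* Test and demonstration problem sizes: unit and property tests run on
  fixtures of up to a few hundred persons where brute-force per-person
  oracles are feasible; parameter-recovery checks use cohorts of 50,000
  persons over 30 seeds, which keeps Monte Carlo error near the width of
  the intervals being checked while the whole suite stays fast.

## Worked example

```{r example, eval = FALSE}
library(caseval)

rc <- run_config(generator_config = cohort_config(n_persons = 50000),
                 seed = 1, outdir = "caseval-out")
bundle <- run_validation(rc)
bundle
subset(bundle$metrics, window_months == 12 & cancer_type == "colorectal",
       c(indicator, n_identified, sensitivity, specificity, ppv, optimal))
bundle$lag_profiles$colorectal
bundle$incremental$colorectal
```

## Limitations

Beyond the generator's independence assumptions: person identity is taken
as already linked (probabilistic linkage error is out of scope); only
same-system code matching is supported; cohort-edge effects are inherent
to the design (someone diagnosed in the registry's last month and
admitted the month after is an unavoidable false negative); and the
shipped procedure/item code lists are placeholders to be replaced with
jurisdiction-specific lists for any real analysis.
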