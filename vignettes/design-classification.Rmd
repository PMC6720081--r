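---
title: "Classifying test accuracy study designs: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying test accuracy study designs: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtadesign)
```

## The classification model

A test accuracy study compares an index test against a reference test
whose results are taken as correct; its accuracy is summarised by a 2×2
cross table of index result against reference result. Which
epidemiological design produced that table determines (a) which clinical
question the study can answer, (b) which measures are estimable from the
table, and (c) where bias can enter. `dtadesign` encodes the
classification as a deterministic rule cascade over structured metadata:

1. **Gate.** Accuracy measures exist only if a 2×2 is derivable: both
   tests allow a binary classification (binary in nature, or dichotomised
   at a stated cut-off), a reference standard exists, the counts are
   derivable from the report, and the study is not a comparative/impact
   study. Comparative studies are rejected with guidance to re-submit
   each single arm in which one test is performed, since such arms can
   individually be test accuracy studies. Studies reporting only relative
   effect measures (e.g. a hazard ratio) fail the gate.

2. **Temporal axis.** Diagnosis classifies a *current* status, so index
   and reference information refer to the same individual-level
   time-point — every diagnostic accuracy study is cross-sectional.
   Prognosis/prediction classifies a *future* status, so the reference
   test necessarily follows the index test — every such study is
   longitudinal. The operative quantity is the interval between index and
   reference test **for an individual participant**, never the time-point
   of data collection for the study: a registry read out on a single day
   can still contain months between a participant's two tests.

3. **Clinical question.** Longitudinal studies subdivide by treatment
   context: the natural, untreated course answers *who needs treatment*
   (prognosis); outcomes under treatment answer *who and how to treat*
   (prediction). Both share the same longitudinal design repertoire, so
   the design labels do not split further; an unclear treatment context
   defaults to prognosis with an explicit warning.

4. **Sampling.** Cohort-type studies recruit on *suspicion* — any
   indication to test: signs, symptoms, risk factors, previous test
   results. Case-control-type studies select on the reference
   status/outcome itself and compare index results of cases against
   controls. Even population screening usually carries a vague indication
   (an age band, a sex); any stated indication is treated as suspicion,
   which resolves deliberately in favour of cohort-type for screening
   programmes.

The four labels combine temporal class and sampling; the deliberately
"contrary-sounding" diagnostic labels (cohort-*selected cross-sectional*)
keep the familiar selection vocabulary while making the cross-sectional
time structure explicit.

```{r}
results <- classify_batch(make_table3_fixtures(), example_policy())
vapply(results, function(r) r$design_label, character(1))
```

## The dual time-interval policy

The same test often serves diagnosis *and* prognosis, so the clinical
question cannot be deduced from the test itself — only the interval
separates them, and its thresholds are clinical judgements. The package
therefore ships **no default policy**; every classification requires four
pre-specified values (all in days, a unit fixed to avoid ambiguity):

| parameter | role |
|---|---|
| `diagnostic_inclusion_max_days` | largest interval still "the same time-point" for review inclusion |
| `diagnostic_low_rob_max_days` | stricter window for a low delayed-verification-risk judgement (≤ the above) |
| `prognostic_inclusion_min_days` | shortest follow-up qualifying for the prognostic question (> the diagnostic maximum) |
| `prognostic_low_rob_min_days` | follow-up floor for a low lead-time-risk judgement (≥ the above) |

Three numerical conventions were genuinely open and are fixed as follows:

* **Inclusive bounds on the qualifying side** (≤ for diagnostic, ≥ for
  prognostic), so a policy reading "up to 30 days" means what it says.
* **Intervals strictly between the two windows are indeterminate**, not
  forced into either question: the passage from delayed verification to
  prognosis is fluent, and a forced choice would hide exactly the cases a
  reviewer must adjudicate. Such records come back `unclassifiable` with
  a `misclassification_interval` note.
* **A slowly progressing condition softens, but never moves, the
  diagnostic window**: with `condition_progression = "slow"` a
  delayed-verification flag is downgraded from concern to note. Whether a
  long delay is acceptable for a given condition is a judgement that
  belongs in the policy, not a rule the classifier applies silently.

An absent individual-level interval is likewise indeterminate, and an
interval marked `interval_basis = "inferred"` carries a confidence
warning. When a review's test can only serve one question, `mode =
"diagnostic_only"` or `"prognostic_only"` restricts the cascade to that
path. The order of index and reference test within a cross-sectional
study is never used for classification (either may come first).

## Design-aware measures

`compute_measures()` evaluates the standard panel over the table cells.
Under case-control selection the reference-positive column proportion is
set by the sampling ratio, not by nature, so PPV, NPV and apparent
prevalence are *withheld* (`invalid_for_design`, no estimate emitted)
rather than computed-and-footnoted — an unusable number that prints is a
number that gets pooled. Sensitivity, specificity, the likelihood ratios
and the DOR are invariant to rescaling the two reference columns by
independent constants, which is precisely why they remain estimable under
case-control sampling; the test suite asserts that invariance directly.

Zero denominators yield an explicit `undefined_zero_denominator` status.
No continuity corrections are applied anywhere: silently adding 0.5 to
cells changes results invisibly, and nothing in the underlying
methodology prescribes a correction. Wilson intervals for proportions and
log-method intervals for ratios are available behind `conf_level`; they
are standard interval methodology layered on top, not part of the
classification model, and are `NA` whenever a needed cell is zero.

```{r}
compute_measures(two_by_two(tp = 90, fp = 20, fn = 10, tn = 80),
                 "case_control")
```

## Risk-of-bias pre-screening flags

Flags are advisory and never feed back into the design label, keeping
classification and quality appraisal orthogonal:

* `delayed_verification` (diagnostic path only): interval exceeds the
  low-risk maximum — the status may have changed before verification.
* `lead_time` (prognostic path only): follow-up below the low-risk floor
  with unblinded (concern) or unclear (note) index results —
  index-positive participants tend to be verified earlier.
* `non_consecutive_sampling`: convenience or unreported sampling; a
  consecutive or random sample gives the least biased estimates.
* `misclassification_interval` / `artificial_prevalence`: emitted by the
  classifier for between-window intervals and case-control designs.

The two-level severity vocabulary (note/concern) is intentional: the
underlying judgements are low/moderate-risk statements, not a full
grading scale, and no complete quality-appraisal instrument exists for
prognostic accuracy studies — these flags pre-screen, they do not
appraise.

## What the synthetic generators emulate

`generate_matched_case_control()` reproduces the structural signature of
case-control selection: exactly `n_cases` reference-positives and
`round(n_cases * control_ratio)` reference-negatives, so the apparent
prevalence is `1/(1 + ratio)` *by construction* (50% under 1:1 matching)
for every dataset — the artefact that motivates withholding predictive
values. `generate_cohort_participants()` draws reference status
Bernoulli(prevalence) and index results per status with the stated
sensitivity and specificity, so cell frequencies converge to the product
model and known parameters are recoverable at large n. Each call seeds
its own scoped random source and leaves the caller's RNG state untouched.

What they do **not** emulate — and hence what passing tests cannot show
about real data: time-to-event outcomes and censoring, covariate-driven
or differential verification, spectrum effects, correlated index and
reference errors, and imperfect reference standards. The generators
validate the arithmetic and the design-gating logic, not the
epidemiology of any particular test.

Worked-example transcription constants: prose timings become days at
365 days/year ("5 years" → 1825; "mean 7.1 years" → 2591.5), and "directly
referred"/"same visit" becomes 0 days. The fourth example's 540 cases and
1034 controls give a non-integer per-case ratio, so its `matching_ratio`
is left absent and the raw counts live in the free-text description.

## Verification set-up and problem sizes

The suite cross-checks `classify_study()` against an independent
brute-force truth table — a nested if/else transcription of the decision
cascade sharing no code with the implementation — over the full
discretized input grid (every enum combination × eight interval strata
including both window boundaries and an absent interval; 3,456 cases).
Property tests cover temporal monotonicity (raising the interval never
moves a study back towards cross-sectional), the exhaustive five-way
partition of the label space, flag/path exclusivity, DOR = LR⁺/LR⁻ to
1e−12, column-rescaling invariance, and exactness of the matched
generator's prevalence. Parameter recovery uses 10,000 synthetic cohort
participants (three binomial standard errors); the predictive-value
prohibition is checked over 120 random case-control specifications.
These sizes were chosen so every property is exercised well past its
asymptotics while the whole suite stays interactive.

## Known limitations

* The tool consumes already-extracted structured metadata; it does not
  read abstracts, and garbage metadata yields confidently wrong labels —
  the decision path is printed precisely so a human can audit each step.
* Test calibration, test reliability, comparative accuracy and impact
  studies are out of scope by construction, as are exposure studies with
  only relative effect measures and any meta-analytic pooling.
* A single representative interval per study (median, if a range is
  reported) flattens within-study timing variation; differential
  verification timing between index-positive and index-negative groups is
  modelled only through the blinding proxy.
* `data_source` is deliberately inert: retrospective/prospective is not a
  design axis here, and nothing downstream may depend on it.
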