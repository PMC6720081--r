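# dtadesign

Classify test accuracy study designs for systematic reviews, and compute
the accuracy measures each design can legitimately support.

## The problem

A test accuracy study compares an **index test** (the test under
evaluation) against a **reference test** whose results are taken as
correct, summarised in the standard 2×2 cross table:

|                    | reference + | reference − |
|--------------------|-------------|-------------|
| **index positive** | TP          | FP          |
| **index negative** | FN          | TN          |

from which sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
PPV = TP/(TP+FP), NPV = TN/(TN+FN), LR⁺ = sens/(1−spec),
LR⁻ = (1−sens)/spec and DOR = LR⁺/LR⁻ follow.

Such studies are notoriously mislabelled in the literature — diagnostic vs
prognostic vs predictive, cohort vs case-control, "retrospective" vs
"prospective" — and the label matters: it decides review eligibility, which
risk-of-bias tool applies, which studies may be pooled, and **which
measures are estimable at all** (under case-control selection the
reference-positive column proportion is fixed by the sampling ratio, so
predictive values and apparent prevalence are artefacts of the design).

`dtadesign` makes the classification executable for review teams. From
structured, already-extracted study metadata it runs a deterministic rule
engine:

1. **Gate** — is a 2×2 cross-tabulation derivable at all? (Both tests
   binary-classifiable, a reference standard present, counts derivable,
   not a comparative/impact study — whose single arms may be re-submitted
   individually.)
2. **Temporal axis** — the *individual-level* interval between index and
   reference test, judged against a pre-specified dual time-interval
   policy, separates the diagnostic question (current status;
   cross-sectional) from the prognostic/predictive question (future
   status; longitudinal). Intervals falling between the two windows are
   explicitly indeterminate.
3. **Clinical question** — longitudinal studies split into prognosis
   (natural, untreated course) and prediction (outcome under treatment).
4. **Sampling** — recruitment on suspicion (signs, symptoms, risk
   factors, previous tests) is cohort-type; selection on reference
   status/outcome is case-control-type.

The composition yields one of four design labels —
`diagnostic_cohort_cross_sectional`,
`diagnostic_case_control_cross_sectional`, `prognostic_cohort`,
`prognostic_case_control` — or an explicit `unclassifiable`, always with
the full decision path and risk-of-bias pre-screening flags (delayed
verification, lead time, sampling quality) attached.

## Worked example

The package bundles four published example studies, one per design. The
fourth (PSA levels from stored blood draws vs later biopsy-confirmed
prostate cancer, mean 7.1 years of follow-up, 540 cases with 1034 matched
controls):

```r
library(dtadesign)
rec <- make_table3_fixtures()[[4]]
classify_study(rec, example_policy())
#> <classification_result> example-4-psa-prostate
#>   design: prognostic_case_control
#>   (temporal=longitudinal, question=prognosis, sampling=case_control)
#>   1. test_accuracy_gate index=prostate-specific antigen from blood draw; ... -> test accuracy study
#>   2. temporal_axis      2591.5 days (reported) -> longitudinal
#>   3. clinical_question  temporal=longitudinal; treatment=untreated_natural_course -> prognosis
#>   4. sampling           outcome_status -> case_control
#>   5. design_label       longitudinal + case_control -> prognostic_case_control
#>   flag [note] non_consecutive_sampling
#>   flag [note] artificial_prevalence
```

The 2591.5-day follow-up clears the policy's one-year prognostic floor
(longitudinal), participants were untreated (prognosis), and selection on
the outcome makes it case-control — hence a prognostic case-control
design, flagged that its prevalence is an artefact of matching.

Measures from a 2×2 table under cohort sampling:

```r
compute_measures(two_by_two(tp = 90, fp = 20, fn = 10, tn = 80), "cohort")
#> <measure_panel> sampling_type = cohort
#>                measure estimate lower upper validity note
#>            sensitivity   0.9000    NA    NA    valid
#>            specificity   0.8000    NA    NA    valid
#>                    ppv   0.8182    NA    NA    valid
#>                    npv   0.8889    NA    NA    valid
#>    apparent_prevalence   0.5000    NA    NA    valid
#>            lr_positive   4.5000    NA    NA    valid
#>            lr_negative   0.1250    NA    NA    valid
#>  diagnostic_odds_ratio  36.0000    NA    NA    valid
#>               accuracy   0.8500    NA    NA    valid
```

With `"case_control"` instead, `ppv`, `npv` and `apparent_prevalence` are
withheld (`invalid_for_design`); sensitivity, specificity, LRs and DOR —
which are invariant to rescaling the two reference columns — survive.

A thin command-line wrapper covers batch use:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dtadesign.R", package = "dtadesign"))')
Rscript "$CLI" classify \
  --input inst/extdata/table3_fixtures.json \
  --policy inst/extdata/example_policy.yaml \
  --output report.csv
Rscript "$CLI" measures --tp 90 --fp 20 --fn 10 --tn 80 --design cohort
Rscript "$CLI" generate case-control --n-cases 200 --ratio 1 \
  --sens 0.8 --spec 0.9 --seed 7 --output participants.csv
```

No default time-interval policy is shipped — thresholds need clinical and
methodological judgement — so every classification takes an explicit
policy file; `example_policy()` (30/14/365/365 days) is illustrative only.

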