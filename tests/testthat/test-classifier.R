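test_that("the gate accepts 2x2-derivable studies and cites the first failure", {
  expect_true(is_test_accuracy_study(make_record())$accept)

  g <- is_test_accuracy_study(make_record(crosstab = FALSE))
  expect_false(g$accept)
  expect_match(g$reason, "2x2")

  # only a hazard ratio reported: derivability unknown -> conservative reject
  g <- is_test_accuracy_study(make_record(crosstab = NULL))
  expect_false(g$accept)

  g <- is_test_accuracy_study(make_record(comparative = TRUE))
  expect_false(g$accept)
  expect_match(g$reason, "arm")

  g <- is_test_accuracy_study(make_record(index_classifiable = FALSE))
  expect_false(g$accept)
  expect_match(g$reason, "index")

  g <- is_test_accuracy_study(make_record(ref_present = FALSE))
  expect_false(g$accept)
  expect_match(g$reason, "reference")

  g <- is_test_accuracy_study(make_record(has_ref = FALSE))
  expect_false(g$accept)
  expect_match(g$reason, "reference standard")
})

test_that("temporal axis follows the dual-interval policy with inclusive bounds", {
  pol <- test_policy()
  tc <- function(interval, ...) {
    determine_temporal_class(make_record(interval = interval, ...), pol)
  }
  expect_identical(tc(0)$temporal_class, "cross_sectional")
  expect_identical(tc(30)$temporal_class, "cross_sectional")  # inclusive bound
  expect_identical(tc(365)$temporal_class, "longitudinal")    # inclusive bound
  expect_identical(tc(1825)$temporal_class, "longitudinal")

  between <- tc(100)
  expect_identical(between$temporal_class, "indeterminate")
  expect_match(paste(between$warnings, collapse = " "), "between")

  absent <- tc(NA)
  expect_identical(absent$temporal_class, "indeterminate")
  expect_match(paste(absent$warnings, collapse = " "), "interval_absent")

  inferred <- tc(5, interval_basis = "inferred")
  expect_identical(inferred$temporal_class, "cross_sectional")
  expect_match(paste(inferred$warnings, collapse = " "), "inferred")
})

test_that("single-question modes restrict the algorithm to one path", {
  pol <- test_policy()
  long_rec <- make_record(interval = 400)
  short_rec <- make_record(interval = 10)
  expect_identical(
    determine_temporal_class(long_rec, pol, mode = "diagnostic_only")$temporal_class,
    "indeterminate")
  expect_identical(
    determine_temporal_class(short_rec, pol, mode = "prognostic_only")$temporal_class,
    "indeterminate")
  expect_identical(
    determine_temporal_class(short_rec, pol, mode = "diagnostic_only")$temporal_class,
    "cross_sectional")
  expect_identical(
    classify_study(long_rec, pol, mode = "diagnostic_only")$design_label,
    "unclassifiable")
  expect_identical(
    classify_study(long_rec, pol, mode = "prognostic_only")$design_label,
    "prognostic_cohort")
})

test_that("clinical question splits longitudinal studies by treatment context", {
  rec <- function(treatment) make_record(interval = 400, treatment = treatment)
  expect_identical(
    determine_clinical_question(rec("untreated_natural_course"),
                                "longitudinal")$clinical_question,
    "prognosis")
  expect_identical(
    determine_clinical_question(rec("treated"), "longitudinal")$clinical_question,
    "prediction")
  unclear <- determine_clinical_question(rec("unclear"), "longitudinal")
  expect_identical(unclear$clinical_question, "prognosis")
  expect_match(paste(unclear$warnings, collapse = " "), "assumed")
  # cross-sectional forces diagnosis regardless of treatment context
  for (tc in c("untreated_natural_course", "treated", "unclear")) {
    expect_identical(
      determine_clinical_question(rec(tc), "cross_sectional")$clinical_question,
      "diagnosis")
  }
})

test_that("sampling basis maps to cohort / case-control / unclear", {
  expect_identical(determine_sampling(make_record(sampling = "suspicion")),
                   "cohort")
  expect_identical(determine_sampling(make_record(sampling = "outcome_status")),
                   "case_control")
  expect_identical(determine_sampling(make_record(sampling = "unclear")),
                   "unclear")
})

test_that("classify_study composes the criteria and records the decision path", {
  pol <- test_policy()
  res <- classify_study(make_record(interval = 0, sampling = "suspicion"), pol)
  expect_identical(res$design_label, "diagnostic_cohort_cross_sectional")
  expect_identical(res$decision_path$criterion,
                   c("test_accuracy_gate", "temporal_axis", "clinical_question",
                     "sampling", "design_label"))

  # gate failure exits after the first criterion
  res <- classify_study(make_record(crosstab = FALSE), pol)
  expect_identical(res$design_label, "unclassifiable")
  expect_false(res$is_test_accuracy_study)
  expect_identical(nrow(res$decision_path), 1L)

  # prediction still carries a prognostic design label
  res <- classify_study(make_record(interval = 400, treatment = "treated",
                                    sampling = "outcome_status"), pol)
  expect_identical(res$clinical_question, "prediction")
  expect_identical(res$design_label, "prognostic_case_control")

  # unclear sampling blocks the label but keeps the temporal classification
  res <- classify_study(make_record(interval = 0, sampling = "unclear"), pol)
  expect_identical(res$design_label, "unclassifiable")
  expect_identical(res$temporal_class, "cross_sectional")
})

test_that("classification is total and the labels partition the input grid", {
  pol <- test_policy()
  grid <- oracle_grid()
  results <- lapply(seq_len(nrow(grid)), function(i) {
    classify_study(grid_row_to_record(grid[i, ]), pol)
  })
  labels <- vapply(results, function(r) r$design_label, character(1))
  expect_true(all(vapply(results, inherits, logical(1),
                         "classification_result")))
  expect_true(all(vapply(results, function(r) nrow(r$decision_path),
                         integer(1)) >= 1L))
  # label consistency invariants on every classified (non-unclassifiable) case
  consistent <- vapply(results, function(r) {
    r$design_label == "unclassifiable" ||
      (r$is_test_accuracy_study &&
         r$temporal_class != "indeterminate" &&
         r$sampling_type != "unclear" &&
         identical(startsWith(r$design_label, "diagnostic"),
                   r$temporal_class == "cross_sectional"))
  }, logical(1))
  expect_true(all(consistent))
  expect_setequal(unique(labels),
                  c("diagnostic_cohort_cross_sectional",
                    "diagnostic_case_control_cross_sectional",
                    "prognostic_cohort", "prognostic_case_control",
                    "unclassifiable"))
})

test_that("a brute-force truth table agrees with classify_study on the grid", {
  pol <- test_policy()
  grid <- oracle_grid()
  got <- vapply(seq_len(nrow(grid)), function(i) {
    classify_study(grid_row_to_record(grid[i, ]), pol)$design_label
  }, character(1))
  want <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    oracle_design_label(
      g$index_classifiable, g$ref_classifiable, g$has_ref, g$crosstab,
      g$comparative, g$interval, g$sampling_basis,
      pol$diagnostic_inclusion_max_days, pol$prognostic_inclusion_min_days)
  }, character(1))
  expect_identical(got, want)
})

test_that("increasing the interval never reverts longitudinal to cross-sectional", {
  pol <- test_policy()
  rank <- c(cross_sectional = 0L, indeterminate = 1L, longitudinal = 2L)
  intervals <- c(0, 1, 14, 30, 31, 100, 200, 364, 365, 366, 1825, 10000)
  for (sampling in c("suspicion", "outcome_status")) {
    classes <- vapply(intervals, function(d) {
      determine_temporal_class(make_record(interval = d, sampling = sampling),
                               pol)$temporal_class
    }, character(1))
    expect_true(all(diff(rank[classes]) >= 0),
                info = paste(classes, collapse = " -> "))
  }
})
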