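# The decision algorithm: (1) gate — is a 2x2 cross-tabulation of index
# against reference test derivable at all; (2) temporal axis — the
# individual-level interval between index and reference test places the study
# on the diagnostic (cross-sectional) or prognostic/predictive (longitudinal)
# question; (3) clinical question — natural course vs treated patients;
# (4) sampling — recruitment on suspicion (cohort) vs selection on reference
# status/outcome (case-control). The composition yields one of four design
# labels or an explicit "unclassifiable" with the failing criterion recorded.

TEMPORAL_CLASSES  <- c("cross_sectional", "longitudinal", "indeterminate")
CLINICAL_QUESTIONS <- c("diagnosis", "prognosis", "prediction", "not_applicable")
SAMPLING_TYPES    <- c("cohort", "case_control", "unclear")
DESIGN_LABELS     <- c("diagnostic_cohort_cross_sectional",
                       "diagnostic_case_control_cross_sectional",
                       "prognostic_cohort",
                       "prognostic_case_control",
                       "unclassifiable")
CLASSIFY_MODES    <- c("full", "diagnostic_only", "prognostic_only")

#' Gate: is the study a test accuracy study?
#'
#' A study enters the design algorithm only if accuracy measures are
#' computable at all: both index and reference test allow a binary
#' classification, a reference standard exists, a 2x2 cross-tabulation is
#' derivable from the report, and the study is not a comparative/impact
#' design. Comparative studies are rejected with guidance to re-submit the
#' single arms in which one test is performed, which individually can be
#' test accuracy studies.
#'
#' @param record A validated [study_record][validate_study_record()].
#' @return A list with `accept` (logical) and `reason` (string; cites the
#'   first failing condition, or states that all gate conditions hold).
#' @export
is_test_accuracy_study <- function(record) {
  stopifnot(inherits(record, "study_record"))
  if (!is_binary_classifiable(record$index_test)) {
    return(list(accept = FALSE,
                reason = "index test does not allow a binary classification (no binary scale or cut-off)"))
  }
  if (is.null(record$reference_test) ||
      !is_binary_classifiable(record$reference_test)) {
    return(list(accept = FALSE,
                reason = "reference test absent or does not allow a binary classification"))
  }
  if (!isTRUE(record$has_reference_standard)) {
    return(list(accept = FALSE,
                reason = "no reference standard against which the index test is compared"))
  }
  if (!isTRUE(record$cross_tab_derivable)) {
    return(list(accept = FALSE, reason = "no 2x2 derivable from the report"))
  }
  if (isTRUE(record$comparative_design)) {
    return(list(accept = FALSE,
                reason = paste("comparative/impact design: classify each single arm",
                               "in which one test is performed as its own",
                               "test accuracy study and re-submit arm-level records")))
  }
  list(accept = TRUE, reason = "2x2 cross-tabulation of index vs reference test derivable")
}

#' Temporal axis: diagnostic (cross-sectional) or prognostic (longitudinal)?
#'
#' Diagnosis classifies a current status, so index and reference test refer
#' to the same individual-level time-point; prognosis/prediction classifies
#' a future status, so the reference test follows after a sufficiently long
#' interval. The policy's two inclusion thresholds discretise this:
#' intervals up to `diagnostic_inclusion_max_days` (inclusive) are
#' cross-sectional, intervals of at least `prognostic_inclusion_min_days`
#' (inclusive) are longitudinal, and anything strictly between is
#' indeterminate — the passage from delayed verification to prognosis is
#' fluent, so no forced choice is made. An absent individual-level interval
#' is likewise indeterminate.
#'
#' @param record A validated [study_record][validate_study_record()].
#' @param policy A [time_interval_policy()].
#' @param mode `"full"`, or `"diagnostic_only"`/`"prognostic_only"` to
#'   restrict the algorithm to one question when the review's test can only
#'   serve that question.
#' @return A list with `temporal_class` and `warnings` (character vector).
#' @export
determine_temporal_class <- function(record, policy, mode = "full") {
  stopifnot(inherits(record, "study_record"),
            inherits(policy, "time_interval_policy"))
  mode <- match_enum(mode, CLASSIFY_MODES, "mode")
  interval <- record$individual_interval_days
  warnings <- character()
  if (identical(record$interval_basis, "inferred") && !is.na(interval)) {
    warnings <- c(warnings,
                  "interval_inferred: individual-level interval was inferred, not reported; classification confidence reduced")
  }
  if (is.na(interval)) {
    return(list(temporal_class = "indeterminate",
                warnings = c(warnings,
                             "interval_absent: no individual-level interval between index and reference test")))
  }
  diagnostic_ok <- interval <= policy$diagnostic_inclusion_max_days
  prognostic_ok <- interval >= policy$prognostic_inclusion_min_days
  cls <- if (mode == "diagnostic_only") {
    if (diagnostic_ok) "cross_sectional" else "indeterminate"
  } else if (mode == "prognostic_only") {
    if (prognostic_ok) "longitudinal" else "indeterminate"
  } else if (diagnostic_ok) {
    "cross_sectional"
  } else if (prognostic_ok) {
    "longitudinal"
  } else {
    "indeterminate"
  }
  if (cls == "indeterminate") {
    warnings <- c(warnings, if (mode == "full") {
      sprintf(paste0("interval_between_windows: %g days lies strictly between ",
                     "the diagnostic maximum (%g) and the prognostic minimum ",
                     "(%g); delayed verification shades into prognosis here"),
              interval, policy$diagnostic_inclusion_max_days,
              policy$prognostic_inclusion_min_days)
    } else {
      sprintf("interval_outside_window: %g days does not qualify for the %s question",
              interval, if (mode == "diagnostic_only") "diagnostic" else "prognostic")
    })
  }
  list(temporal_class = cls, warnings = warnings)
}

#' Clinical question: diagnosis, prognosis, or prediction?
#'
#' Cross-sectional studies assess diagnosis (a current status). Longitudinal
#' studies assess prognosis when the natural, untreated course is observed
#' (who needs treatment?) and prediction when the outcome under treatment is
#' classified (who and how should be treated?). Both share the longitudinal
#' design repertoire; an unclear treatment context defaults to prognosis
#' with a warning.
#'
#' @param record A validated [study_record][validate_study_record()].
#' @param temporal_class `"cross_sectional"` or `"longitudinal"` (not
#'   `"indeterminate"`).
#' @return A list with `clinical_question` and `warnings`.
#' @export
determine_clinical_question <- function(record, temporal_class) {
  stopifnot(inherits(record, "study_record"))
  temporal_class <- match_enum(temporal_class,
                               c("cross_sectional", "longitudinal"),
                               "temporal_class")
  if (temporal_class == "cross_sectional") {
    return(list(clinical_question = "diagnosis", warnings = character()))
  }
  switch(record$treatment_context,
    untreated_natural_course = list(clinical_question = "prognosis",
                                    warnings = character()),
    treated = list(clinical_question = "prediction", warnings = character()),
    unclear = list(clinical_question = "prognosis",
                   warnings = "treatment_context_assumed: treatment context unclear; natural course (prognosis) assumed")
  )
}

#' Sampling: cohort-type or case-control-type selection?
#'
#' Cohort-type studies recruit on suspicion — an indication to test, be it
#' signs and symptoms, risk factors, or previous test results; even
#' population screening usually carries at least a vague indication such as
#' age or gender, which this function treats as suspicion. Case-control-type
#' studies select participants on the reference test result/outcome status
#' (cases) and its absence (controls).
#'
#' @param record A validated [study_record][validate_study_record()].
#' @return One of `"cohort"`, `"case_control"`, `"unclear"`.
#' @export
determine_sampling <- function(record) {
  stopifnot(inherits(record, "study_record"))
  switch(record$sampling_basis,
         suspicion = "cohort",
         outcome_status = "case_control",
         unclear = "unclear")
}

path_step <- function(criterion, input, outcome) {
  data.frame(criterion = criterion, input = input, outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Classify one study record into a test accuracy design
#'
#' Runs the full decision algorithm — gate, temporal axis, clinical
#' question, sampling type — in order, records each criterion's input and
#' outcome in `decision_path`, attaches risk-of-bias pre-screening flags,
#' and returns one of the four design labels or `"unclassifiable"` with the
#' failing criterion. Total on valid inputs: never raises.
#'
#' Additional flags emitted here rather than by a dedicated rule: an
#' interval strictly between the two policy windows earns a
#' `misclassification_interval` note, and any case-control design earns an
#' `artificial_prevalence` note (its reference-positive proportion is set by
#' the sampling ratio, so predictive values are off the table downstream).
#'
#' @param record A validated [study_record][validate_study_record()].
#' @param policy A [time_interval_policy()].
#' @param mode `"full"` (default), `"diagnostic_only"`, or
#'   `"prognostic_only"`.
#' @return An object of class `classification_result` with fields
#'   `study_id`, `is_test_accuracy_study`, `temporal_class`,
#'   `clinical_question`, `sampling_type`, `design_label`, `decision_path`
#'   (data frame of criterion/input/outcome), `warnings`, `flags`.
#' @examples
#' rec <- make_table3_fixtures()[[1]]
#' classify_study(rec, example_policy())$design_label
#' @export
classify_study <- function(record, policy, mode = "full") {
  record <- validate_study_record(record)
  stopifnot(inherits(policy, "time_interval_policy"))
  mode <- match_enum(mode, CLASSIFY_MODES, "mode")

  warnings <- character()
  flags <- list()
  add_flag <- function(fl) if (!is.null(fl)) flags[[length(flags) + 1L]] <<- fl

  gate <- is_test_accuracy_study(record)
  path <- path_step("test_accuracy_gate",
                    sprintf("index=%s; reference=%s; 2x2=%s; comparative=%s",
                            record$index_test$name,
                            if (is.null(record$reference_test)) "<absent>"
                            else record$reference_test$name,
                            format(record$cross_tab_derivable),
                            format(record$comparative_design)),
                    if (gate$accept) "test accuracy study" else gate$reason)
  if (!gate$accept) {
    return(new_classification_result(
      record, FALSE, "indeterminate", "not_applicable", "unclear",
      "unclassifiable", path, warnings = gate$reason, flags = list()))
  }

  tmp <- determine_temporal_class(record, policy, mode)
  warnings <- c(warnings, tmp$warnings)
  interval_txt <- if (is.na(record$individual_interval_days)) "absent"
    else sprintf("%g days (%s)", record$individual_interval_days,
                 record$interval_basis)
  path <- rbind(path, path_step("temporal_axis", interval_txt,
                                tmp$temporal_class))
  if (tmp$temporal_class == "indeterminate") {
    if (!is.na(record$individual_interval_days) && mode == "full") {
      add_flag(bias_flag(
        "misclassification_interval", "note",
        sprintf("interval of %g days falls between the diagnostic and prognostic windows; status change between tests cannot be excluded",
                record$individual_interval_days)))
    }
    add_flag(flag_sampling_quality(record))
    return(new_classification_result(
      record, TRUE, "indeterminate", "not_applicable", "unclear",
      "unclassifiable", path, warnings, flags))
  }

  cq <- determine_clinical_question(record, tmp$temporal_class)
  warnings <- c(warnings, cq$warnings)
  path <- rbind(path, path_step("clinical_question",
                                sprintf("temporal=%s; treatment=%s",
                                        tmp$temporal_class,
                                        record$treatment_context),
                                cq$clinical_question))

  sampling <- determine_sampling(record)
  path <- rbind(path, path_step("sampling", record$sampling_basis, sampling))

  if (sampling == "unclear") {
    path <- rbind(path, path_step("design_label", "sampling unclear",
                                  "unclassifiable"))
    warnings <- c(warnings,
                  "sampling_unclear: selection basis (suspicion vs outcome status) not determinable")
    add_flag(flag_sampling_quality(record))
    return(new_classification_result(
      record, TRUE, tmp$temporal_class, cq$clinical_question, "unclear",
      "unclassifiable", path, warnings, flags))
  }

  label <- if (tmp$temporal_class == "cross_sectional") {
    if (sampling == "cohort") "diagnostic_cohort_cross_sectional"
    else "diagnostic_case_control_cross_sectional"
  } else {
    if (sampling == "cohort") "prognostic_cohort" else "prognostic_case_control"
  }
  path <- rbind(path, path_step("design_label",
                                sprintf("%s + %s", tmp$temporal_class, sampling),
                                label))

  if (tmp$temporal_class == "cross_sectional") {
    add_flag(flag_delayed_verification(record, policy))
  } else {
    add_flag(flag_lead_time(record, policy))
  }
  add_flag(flag_sampling_quality(record))
  if (sampling == "case_control") {
    add_flag(bias_flag(
      "artificial_prevalence", "note",
      "case-control selection: the reference-positive column proportion is an artificial result of the design; predictive values are not estimable"))
  }

  new_classification_result(record, TRUE, tmp$temporal_class,
                            cq$clinical_question, sampling, label, path,
                            warnings, flags)
}

new_classification_result <- function(record, is_tas, temporal, question,
                                      sampling, label, path, warnings, flags) {
  structure(list(
    study_id = record$study_id,
    is_test_accuracy_study = is_tas,
    temporal_class = temporal,
    clinical_question = question,
    sampling_type = sampling,
    design_label = label,
    decision_path = path,
    warnings = as.character(warnings),
    flags = flags
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s\n", x$study_id))
  cat(sprintf("  design: %s\n", x$design_label))
  cat(sprintf("  (temporal=%s, question=%s, sampling=%s)\n",
              x$temporal_class, x$clinical_question, x$sampling_type))
  for (i in seq_len(nrow(x$decision_path))) {
    cat(sprintf("  %d. %-18s %s -> %s\n", i, x$decision_path$criterion[i],
                x$decision_path$input[i], x$decision_path$outcome[i]))
  }
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = " | "), "\n")
  for (fl in x$flags) cat(sprintf("  flag [%s] %s\n", fl$severity, fl$code))
  invisible(x)
}

#' Classify a batch of study records
#'
#' @param records List of validated records (or raw mappings; each is passed
#'   through [validate_study_record()]).
#' @param policy A [time_interval_policy()].
#' @param mode Passed to [classify_study()].
#' @return A list of `classification_result` objects, in input order.
#' @export
classify_batch <- function(records, policy, mode = "full") {
  lapply(records, classify_study, policy = policy, mode = mode)
}

#' Tabulate classification results
#'
#' Flattens a list of results into one row per study; the decision path,
#' warnings and flags are serialised as semicolon-joined strings.
#'
#' @param results List of `classification_result` objects.
#' @return A data frame.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      study_id = r$study_id,
      is_test_accuracy_study = r$is_test_accuracy_study,
      temporal_class = r$temporal_class,
      clinical_question = r$clinical_question,
      sampling_type = r$sampling_type,
      design_label = r$design_label,
      decision_path = paste(sprintf("%s[%s->%s]", r$decision_path$criterion,
                                    r$decision_path$input,
                                    r$decision_path$outcome),
                            collapse = "; "),
      warnings = paste(r$warnings, collapse = "; "),
      flags = paste(vapply(r$flags, function(f)
        sprintf("%s(%s)", f$code, f$severity), character(1)), collapse = "; "),
      stringsAsFactors = FALSE
    )
  }))
}
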