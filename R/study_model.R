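# Structured study-metadata schema: every downstream decision (gate, temporal
# axis, sampling type, bias flags) reads only fields defined here.

# Enum vocabularies, shared by the validator, the classifier and the CLI.
RESULT_SCALES   <- c("binary", "categorical_with_cutoff", "continuous_with_cutoff")
INTERVAL_BASES  <- c("reported", "inferred", "absent")
SAMPLING_BASES  <- c("suspicion", "outcome_status", "unclear")
TREATMENT_CTX   <- c("untreated_natural_course", "treated", "unclear")
BLINDING_LEVELS <- c("yes", "no", "unclear")
SAMPLING_MECHS  <- c("consecutive", "random", "convenience", "unclear")
PROGRESSION     <- c("slow", "fast", "unclear")

#' Describe an index or reference test
#'
#' A test only enters the classification algorithm if it allows a binary
#' classification of participants: either it is binary in nature, or a
#' categorical/continuous result is dichotomised at a stated cut-off. The
#' test need not be a laboratory test in the narrow sense; an observation,
#' clinical assessment, or a predefined combination of tests/factors
#' (AND/OR rule or a formal diagnostic/prognostic model) qualifies equally.
#'
#' @param name Free-text test name.
#' @param result_scale One of `"binary"`, `"categorical_with_cutoff"`,
#'   `"continuous_with_cutoff"`.
#' @param cutoff Free-text cut-off description; required (non-empty) for the
#'   test to count as binary-classifiable when `result_scale != "binary"`.
#' @param is_combination `TRUE` when the "test" is a predefined AND/OR
#'   combination of tests or a formal model combining several factors.
#' @return An object of class `test_descriptor`.
#' @examples
#' test_descriptor("faecal immunochemical test", "continuous_with_cutoff",
#'                 cutoff = ">= 10 ug Hb/g")
#' @export
test_descriptor <- function(name,
                            result_scale = "binary",
                            cutoff = NULL,
                            is_combination = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("test_descriptor: 'name' must be a non-empty string", call. = FALSE)
  }
  result_scale <- match_enum(result_scale, RESULT_SCALES, "result_scale")
  if (!is.null(cutoff)) {
    cutoff <- as.character(cutoff)
    if (length(cutoff) != 1L || is.na(cutoff) || !nzchar(cutoff)) cutoff <- NULL
  }
  structure(
    list(name = name, result_scale = result_scale, cutoff = cutoff,
         is_combination = isTRUE(is_combination)),
    class = "test_descriptor"
  )
}

#' Can a test's results be dichotomised?
#'
#' `TRUE` when the result scale is binary, or a cut-off is stated for a
#' categorical/continuous scale. Tests failing this are rejected at the
#' test-accuracy gate, not at record validation.
#'
#' @param test A [test_descriptor()] (or `NULL`, which returns `FALSE`).
#' @return Logical scalar.
#' @export
is_binary_classifiable <- function(test) {
  if (is.null(test)) return(FALSE)
  identical(test$result_scale, "binary") || !is.null(test$cutoff)
}

# match a single value against an enum, with an informative error
match_enum <- function(value, allowed, field) {
  if (length(value) != 1L || is.na(value) || !(value %in% allowed)) {
    stop(sprintf("'%s' must be one of {%s}, got %s", field,
                 paste(allowed, collapse = ", "),
                 if (length(value) == 1L) sQuote(as.character(value)) else "a non-scalar"),
         call. = FALSE)
  }
  as.character(value)
}

#' Validate a raw study-metadata mapping into a study record
#'
#' Takes a flat key-value mapping (e.g. a parsed JSON object or CSV row,
#' with nested test fields either as `test_descriptor` objects, sub-lists,
#' or flattened dot-separated keys such as `index_test.name`) and returns a
#' validated `study_record`. Validation is idempotent: a valid record
#' re-validates to an equal record.
#'
#' Required fields: `study_id`, `index_test` (at least a name), and
#' `sampling_basis`. Missing optional enum fields default to
#' `"unclear"`/`"absent"`; missing optional booleans become `NA` (treated
#' conservatively downstream); unknown fields are dropped with a warning.
#'
#' The field `data_source` is descriptive only and never consulted by any
#' classification decision: retrospective/prospective data-collection labels
#' are deliberately not part of the design taxonomy.
#'
#' @param raw Named list (or `study_record`) of field values.
#' @return A validated object of class `study_record`.
#' @examples
#' rec <- validate_study_record(list(
#'   study_id = "fit-crc",
#'   index_test = list(name = "FIT", result_scale = "continuous_with_cutoff",
#'                     cutoff = ">= 10 ug/g"),
#'   reference_test = list(name = "colonoscopy"),
#'   cross_tab_derivable = TRUE,
#'   individual_interval_days = 0,
#'   sampling_basis = "suspicion"
#' ))
#' rec$sampling_basis
#' @export
validate_study_record <- function(raw) {
  if (inherits(raw, "study_record")) raw <- unclass(raw)
  if (!is.list(raw)) {
    stop("validate_study_record: input must be a named list", call. = FALSE)
  }
  raw <- unflatten_record(raw)

  known <- c("study_id", "index_test", "reference_test",
             "has_reference_standard", "cross_tab_derivable",
             "individual_interval_days", "interval_basis", "sampling_basis",
             "matching_ratio", "treatment_context",
             "index_blinded_during_followup", "sampling_mechanism",
             "comparative_design", "data_source", "condition_progression")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    warning(sprintf("ignoring unknown field(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    raw <- raw[intersect(names(raw), known)]
  }

  for (req in c("study_id", "index_test", "sampling_basis")) {
    if (is.null(raw[[req]]) || (is.atomic(raw[[req]]) && all(is.na(raw[[req]])))) {
      stop(sprintf("missing required field: %s", req), call. = FALSE)
    }
  }
  study_id <- as.character(raw$study_id)
  if (length(study_id) != 1L || !nzchar(study_id)) {
    stop("'study_id' must be a non-empty string", call. = FALSE)
  }

  index_test <- coerce_test(raw$index_test, "index_test")
  reference_test <- if (is.null(raw$reference_test)) NULL else
    coerce_test(raw$reference_test, "reference_test")

  has_ref <- coerce_optional_logical(raw$has_reference_standard,
                                     "has_reference_standard")
  if (is.na(has_ref) && !is.null(reference_test)) has_ref <- TRUE

  interval <- raw$individual_interval_days
  if (!is.null(interval) && !all(is.na(interval))) {
    interval <- suppressWarnings(as.numeric(interval))
    if (length(interval) != 1L || is.na(interval) || interval < 0) {
      stop("'individual_interval_days' must be a single non-negative number",
           call. = FALSE)
    }
  } else {
    interval <- NA_real_
  }

  interval_basis <- raw$interval_basis
  if (is.null(interval_basis) || all(is.na(interval_basis))) {
    interval_basis <- if (is.na(interval)) "absent" else "reported"
  }
  interval_basis <- match_enum(interval_basis, INTERVAL_BASES, "interval_basis")
  if (identical(interval_basis, "absent") && !is.na(interval)) {
    stop("'interval_basis' is \"absent\" but 'individual_interval_days' is present",
         call. = FALSE)
  }

  ratio <- raw$matching_ratio
  if (!is.null(ratio) && !all(is.na(ratio))) {
    ratio <- suppressWarnings(as.numeric(ratio))
    if (length(ratio) != 1L || is.na(ratio) || ratio <= 0) {
      stop("'matching_ratio' must be a single positive number", call. = FALSE)
    }
  } else {
    ratio <- NA_real_
  }

  rec <- structure(list(
    study_id = study_id,
    index_test = index_test,
    reference_test = reference_test,
    has_reference_standard = has_ref,
    cross_tab_derivable = coerce_optional_logical(raw$cross_tab_derivable,
                                                  "cross_tab_derivable"),
    individual_interval_days = interval,
    interval_basis = interval_basis,
    sampling_basis = match_enum(raw$sampling_basis, SAMPLING_BASES,
                                "sampling_basis"),
    matching_ratio = ratio,
    treatment_context = enum_or_default(raw$treatment_context, TREATMENT_CTX,
                                        "treatment_context", "unclear"),
    index_blinded_during_followup =
      enum_or_default(raw$index_blinded_during_followup, BLINDING_LEVELS,
                      "index_blinded_during_followup", "unclear"),
    sampling_mechanism = enum_or_default(raw$sampling_mechanism, SAMPLING_MECHS,
                                         "sampling_mechanism", "unclear"),
    comparative_design = isTRUE(coerce_optional_logical(raw$comparative_design,
                                                        "comparative_design")),
    data_source = if (is.null(raw$data_source) || all(is.na(raw$data_source)))
      "" else as.character(raw$data_source)[1L],
    condition_progression = enum_or_default(raw$condition_progression,
                                            PROGRESSION,
                                            "condition_progression", "unclear")
  ), class = "study_record")
  rec
}

enum_or_default <- function(value, allowed, field, default) {
  if (is.null(value) || all(is.na(value))) return(default)
  match_enum(value, allowed, field)
}

coerce_optional_logical <- function(value, field) {
  if (is.null(value) || all(is.na(value))) return(NA)
  if (is.character(value)) {
    value <- switch(tolower(value[1L]),
                    "true" = TRUE, "yes" = TRUE, "1" = TRUE,
                    "false" = FALSE, "no" = FALSE, "0" = FALSE,
                    NA)
  }
  if (!is.logical(value) || length(value) != 1L) {
    stop(sprintf("'%s' must be TRUE/FALSE", field), call. = FALSE)
  }
  value
}

coerce_test <- function(x, field) {
  if (inherits(x, "test_descriptor")) {
    return(test_descriptor(x$name, x$result_scale, x$cutoff, x$is_combination))
  }
  if (is.character(x) && length(x) == 1L) {
    return(test_descriptor(x))
  }
  if (is.list(x)) {
    if (is.null(x$name)) stop(sprintf("'%s' needs a 'name'", field), call. = FALSE)
    return(test_descriptor(
      name = as.character(x$name),
      result_scale = if (is.null(x$result_scale) || all(is.na(x$result_scale)))
        "binary" else x$result_scale,
      cutoff = x$cutoff,
      is_combination = isTRUE(coerce_optional_logical(x$is_combination,
                                                      "is_combination"))
    ))
  }
  stop(sprintf("'%s' must be a test descriptor, list, or name string", field),
       call. = FALSE)
}

# Re-nest flattened dot-separated keys (index_test.name -> index_test$name),
# the CSV wire format for the two nested test descriptors.
unflatten_record <- function(raw) {
  dotted <- grep("\\.", names(raw), value = TRUE)
  for (key in dotted) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) {
      value <- raw[[key]]
      raw[[key]] <- NULL
      if (!is.null(value) && !all(is.na(value))) {
        if (is.null(raw[[parts[1L]]])) raw[[parts[1L]]] <- list()
        raw[[parts[1L]]][[parts[2L]]] <- value
      }
    }
  }
  raw
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record> %s\n", x$study_id))
  cat(sprintf("  index test:     %s (%s)\n", x$index_test$name,
              x$index_test$result_scale))
  cat(sprintf("  reference test: %s\n",
              if (is.null(x$reference_test)) "<absent>" else x$reference_test$name))
  cat(sprintf("  interval:       %s days (%s)\n",
              if (is.na(x$individual_interval_days)) "NA"
              else format(x$individual_interval_days), x$interval_basis))
  cat(sprintf("  sampling basis: %s; mechanism: %s\n",
              x$sampling_basis, x$sampling_mechanism))
  cat(sprintf("  treatment:      %s\n", x$treatment_context))
  invisible(x)
}

#' Pre-specified dual time-interval policy
#'
#' A systematic review pre-specifies, per clinical question, two interval
#' thresholds between index and reference test: one governing inclusion
#' (does the study address the review's diagnostic or prognostic question
#' at all?) and a stricter one governing low risk-of-bias judgements
#' (delayed verification for diagnosis, insufficient follow-up / lead time
#' for prognosis). No defaults are shipped: choosing thresholds requires
#' clinical and methodological judgement, so an explicit policy is always
#' required.
#'
#' @param diagnostic_inclusion_max_days Largest index-reference interval (days)
#'   still counted as the same time-point for the diagnostic question.
#' @param diagnostic_low_rob_max_days Stricter interval (days) below which
#'   delayed-verification risk is judged low; must be <= the inclusion maximum.
#' @param prognostic_inclusion_min_days Smallest follow-up (days) qualifying a
#'   study for the prognostic/predictive question; must exceed the diagnostic
#'   inclusion maximum (the two questions must not overlap).
#' @param prognostic_low_rob_min_days Follow-up (days) at or above which
#'   lead-time risk from short follow-up is judged low; must be >= the
#'   prognostic inclusion minimum.
#' @return An object of class `time_interval_policy`.
#' @examples
#' time_interval_policy(30, 14, 365, 365)
#' @export
time_interval_policy <- function(diagnostic_inclusion_max_days,
                                 diagnostic_low_rob_max_days,
                                 prognostic_inclusion_min_days,
                                 prognostic_low_rob_min_days) {
  vals <- c(diagnostic_inclusion_max_days = diagnostic_inclusion_max_days,
            diagnostic_low_rob_max_days = diagnostic_low_rob_max_days,
            prognostic_inclusion_min_days = prognostic_inclusion_min_days,
            prognostic_low_rob_min_days = prognostic_low_rob_min_days)
  vals <- vapply(vals, function(v) suppressWarnings(as.numeric(v)), numeric(1))
  if (anyNA(vals) || any(vals <= 0)) {
    stop("all policy intervals must be positive numbers (days)", call. = FALSE)
  }
  if (vals[["diagnostic_low_rob_max_days"]] >
      vals[["diagnostic_inclusion_max_days"]]) {
    stop("diagnostic_low_rob_max_days must not exceed diagnostic_inclusion_max_days ",
         "(the risk-of-bias window is the stricter of the two)", call. = FALSE)
  }
  if (vals[["prognostic_low_rob_min_days"]] <
      vals[["prognostic_inclusion_min_days"]]) {
    stop("prognostic_low_rob_min_days must be at least prognostic_inclusion_min_days ",
         "(the risk-of-bias window is the stricter of the two)", call. = FALSE)
  }
  if (vals[["diagnostic_inclusion_max_days"]] >=
      vals[["prognostic_inclusion_min_days"]]) {
    stop("diagnostic_inclusion_max_days must be strictly below ",
         "prognostic_inclusion_min_days: the diagnostic and prognostic ",
         "windows must not overlap", call. = FALSE)
  }
  structure(as.list(vals), class = "time_interval_policy")
}

#' @export
print.time_interval_policy <- function(x, ...) {
  cat("<time_interval_policy> (days)\n")
  cat(sprintf("  diagnostic:  include <= %g, low-RoB <= %g\n",
              x$diagnostic_inclusion_max_days, x$diagnostic_low_rob_max_days))
  cat(sprintf("  prognostic:  include >= %g, low-RoB >= %g\n",
              x$prognostic_inclusion_min_days, x$prognostic_low_rob_min_days))
  invisible(x)
}

#' Illustrative time-interval policy
#'
#' A policy used throughout the documentation and worked examples: the
#' diagnostic question accepts same-episode testing up to 30 days (low
#' risk of delayed verification up to 14 days) and the prognostic question
#' requires at least one year of follow-up (which is also the low-risk
#' follow-up floor). These numbers are illustrative, not recommendations;
#' a real review must set its own thresholds.
#'
#' @return A [time_interval_policy()].
#' @export
example_policy <- function() {
  time_interval_policy(
    diagnostic_inclusion_max_days = 30,
    diagnostic_low_rob_max_days = 14,
    prognostic_inclusion_min_days = 365,
    prognostic_low_rob_min_days = 365
  )
}
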