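# Risk-of-bias pre-screening flags. Flags are advisory annotations attached to
# a classification result; they never feed back into the design label, keeping
# classification and quality appraisal orthogonal (the inclusion interval and
# the risk-of-bias interval of the policy play separate roles).

FLAG_CODES <- c("delayed_verification", "lead_time", "non_consecutive_sampling",
                "misclassification_interval", "artificial_prevalence")
FLAG_SEVERITIES <- c("note", "concern")

#' Construct a bias flag
#'
#' @param code One of `"delayed_verification"`, `"lead_time"`,
#'   `"non_consecutive_sampling"`, `"misclassification_interval"`,
#'   `"artificial_prevalence"`.
#' @param severity `"note"` or `"concern"` — a deliberately two-level scale
#'   mirroring low/moderate risk judgements.
#' @param rationale Non-empty free text citing the triggering inputs.
#' @return An object of class `bias_flag`.
#' @export
bias_flag <- function(code, severity, rationale) {
  code <- match_enum(code, FLAG_CODES, "code")
  severity <- match_enum(severity, FLAG_SEVERITIES, "severity")
  if (!is.character(rationale) || length(rationale) != 1L || !nzchar(rationale)) {
    stop("bias_flag: 'rationale' must be non-empty text", call. = FALSE)
  }
  structure(list(code = code, severity = severity, rationale = rationale),
            class = "bias_flag")
}

#' @export
print.bias_flag <- function(x, ...) {
  cat(sprintf("[%s] %s: %s\n", x$severity, x$code, x$rationale))
  invisible(x)
}

#' Flag delayed verification risk in a cross-sectional study
#'
#' The patient's status can change between index and reference test, so a
#' diagnostic study with an interval above the policy's low risk-of-bias
#' maximum carries a misclassification (delayed verification) risk. A
#' slowly progressing condition softens the judgement to a note rather
#' than extending any window: whether delay is acceptable for a given
#' condition is a clinical judgement, expressed through the policy.
#'
#' @param record A validated [study_record][validate_study_record()]
#'   classified on the diagnostic (cross-sectional) path.
#' @param policy A [time_interval_policy()].
#' @return A [bias_flag()] or `NULL`.
#' @export
flag_delayed_verification <- function(record, policy) {
  interval <- record$individual_interval_days
  if (is.na(interval) || interval <= policy$diagnostic_low_rob_max_days) {
    return(NULL)
  }
  severity <- if (identical(record$condition_progression, "slow")) "note" else "concern"
  bias_flag(
    "delayed_verification", severity,
    sprintf(paste0("interval of %g days between index and reference test ",
                   "exceeds the low risk-of-bias maximum of %g days",
                   "%s; the participant's status may have changed before ",
                   "verification"),
            interval, policy$diagnostic_low_rob_max_days,
            if (identical(record$condition_progression, "slow"))
              " (softened: slowly progressing condition)" else "")
  )
}

#' Flag lead-time risk in a longitudinal study
#'
#' With unblinded index test results and a follow-up shorter than the
#' policy's low risk-of-bias minimum, index-positive participants tend to
#' be monitored more closely and verified earlier, producing spurious
#' accuracy. Unclear blinding under the same short follow-up yields a note.
#'
#' @inheritParams flag_delayed_verification
#' @param record A validated record classified on the prognostic
#'   (longitudinal) path.
#' @return A [bias_flag()] or `NULL`.
#' @export
flag_lead_time <- function(record, policy) {
  interval <- record$individual_interval_days
  if (is.na(interval) || interval >= policy$prognostic_low_rob_min_days) {
    return(NULL)
  }
  blinding <- record$index_blinded_during_followup
  if (identical(blinding, "yes")) return(NULL)
  severity <- if (identical(blinding, "no")) "concern" else "note"
  bias_flag(
    "lead_time", severity,
    sprintf(paste0("follow-up of %g days is below the low risk-of-bias ",
                   "minimum of %g days and index test results were %s ",
                   "during follow-up; index-positive participants may be ",
                   "verified earlier"),
            interval, policy$prognostic_low_rob_min_days,
            if (identical(blinding, "no")) "not blinded" else "of unclear blinding")
  )
}

#' Flag a non-consecutive, non-random sample
#'
#' Cohort-type studies with a consecutive or random sample provide the
#' least biased accuracy information; convenience or unreported sampling
#' mechanisms earn a note.
#'
#' @param record A validated [study_record][validate_study_record()].
#' @return A [bias_flag()] or `NULL`.
#' @export
flag_sampling_quality <- function(record) {
  if (record$sampling_mechanism %in% c("consecutive", "random")) return(NULL)
  bias_flag(
    "non_consecutive_sampling", "note",
    sprintf("sampling mechanism is '%s'; consecutive or random sampling provides the least biased accuracy estimates",
            record$sampling_mechanism)
  )
}
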