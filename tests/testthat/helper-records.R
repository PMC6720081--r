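# Build a raw study-record mapping with sensible valid defaults; individual
# tests flip the field under scrutiny.
make_raw_record <- function(study_id = "s1",
                            interval = 0,
                            sampling = "suspicion",
                            treatment = "unclear",
                            index_classifiable = TRUE,
                            ref_present = TRUE,
                            ref_classifiable = TRUE,
                            has_ref = NULL,
                            crosstab = TRUE,
                            comparative = FALSE,
                            blinding = "unclear",
                            mechanism = "unclear",
                            progression = "unclear",
                            interval_basis = NULL,
                            matching_ratio = NULL) {
  raw <- list(
    study_id = study_id,
    index_test = if (index_classifiable) {
      list(name = "index test", result_scale = "binary")
    } else {
      list(name = "index test", result_scale = "continuous_with_cutoff")
    },
    sampling_basis = sampling,
    treatment_context = treatment,
    comparative_design = comparative,
    index_blinded_during_followup = blinding,
    sampling_mechanism = mechanism,
    condition_progression = progression
  )
  if (ref_present) {
    raw$reference_test <- if (ref_classifiable) {
      list(name = "reference test", result_scale = "binary")
    } else {
      list(name = "reference test", result_scale = "categorical_with_cutoff")
    }
  }
  if (!is.null(has_ref)) raw$has_reference_standard <- has_ref
  if (!is.null(crosstab)) raw$cross_tab_derivable <- crosstab
  if (!is.null(interval) && !is.na(interval)) {
    raw$individual_interval_days <- interval
  }
  if (!is.null(interval_basis)) raw$interval_basis <- interval_basis
  if (!is.null(matching_ratio)) raw$matching_ratio <- matching_ratio
  raw
}

make_record <- function(...) validate_study_record(make_raw_record(...))

test_policy <- function() time_interval_policy(30, 14, 365, 365)
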