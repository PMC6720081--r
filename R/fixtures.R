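# Worked-example study records (one per design type) and seeded synthetic
# participant generators emulating cohort and matched case-control sampling.
# Transcription constants for the worked examples: prose timings become days
# at 365 d/y ("5 years" -> 1825; "mean 7.1 years" -> 2591.5); "directly
# referred to the reference after the index test" and "same visit" -> 0 days.

DAYS_PER_YEAR <- 365

#' Worked-example study records, one per design type
#'
#' Four published test accuracy studies, transcribed into the structured
#' schema, that exemplify the four designs in order:
#'
#' 1. colorectal cancer screening of kidney transplant recipients (faecal
#'    immunochemical test vs colonoscopy, direct referral) — diagnostic
#'    cohort-type cross-sectional;
#' 2. memory-clinic Alzheimer study (cognitive test vs clinical diagnosis,
#'    three age-matched controls per case, same visit) — diagnostic
#'    case-control-type cross-sectional;
#' 3. osteoporotic fracture risk (prognostic model score vs hip fracture
#'    within 5 years, all patients 50-90 in a payer provider organisation)
#'    — prognostic cohort;
#' 4. prostate cancer (PSA from stored blood draws vs later biopsy
#'    diagnosis, mean 7.1 years, 540 cases and 1034 matched controls) —
#'    prognostic case-control. The per-case matching ratio is non-integer
#'    (~1.9), so `matching_ratio` is left absent and the raw counts live in
#'    the free-text description.
#'
#' @return A list of 4 validated [study_record][validate_study_record()]s.
#' @examples
#' vapply(make_table3_fixtures(), function(r) r$study_id, character(1))
#' @export
make_table3_fixtures <- function() {
  fixtures <- list(
    list(
      study_id = "example-1-fit-colorectal",
      index_test = list(name = "faecal immunochemical testing",
                        result_scale = "continuous_with_cutoff",
                        cutoff = "positivity threshold of the FIT assay"),
      reference_test = list(name = "colonoscopy with histological evaluation"),
      has_reference_standard = TRUE,
      cross_tab_derivable = TRUE,
      individual_interval_days = 0,   # directly referred to reference test
      interval_basis = "reported",
      sampling_basis = "suspicion",   # all kidney transplant recipients >= 50 y
      treatment_context = "unclear",
      sampling_mechanism = "consecutive",
      condition_progression = "slow",
      data_source = "kidney transplant recipients aged >= 50 years; colorectal cancer screening"
    ),
    list(
      study_id = "example-2-cognitive-alzheimer",
      index_test = list(name = "brief cognitive test",
                        result_scale = "categorical_with_cutoff",
                        cutoff = "test-specific impairment threshold"),
      reference_test = list(name = "clinical diagnosis of Alzheimer's disease"),
      has_reference_standard = TRUE,
      cross_tab_derivable = TRUE,
      individual_interval_days = 0,   # both during the memory-clinic visit
      interval_basis = "reported",
      sampling_basis = "outcome_status",  # cases + matched controls
      matching_ratio = 3,             # three age-matched controls per case
      treatment_context = "unclear",
      sampling_mechanism = "convenience",
      condition_progression = "slow", # Alzheimer status cannot have resolved
      data_source = "memory clinic attendees; controls recruited from accompanying relatives"
    ),
    list(
      study_id = "example-3-fracture-model",
      index_test = list(name = "prognostic model score for osteoporotic fracture",
                        result_scale = "continuous_with_cutoff",
                        cutoff = "dichotomised at pre-specified score cut-offs",
                        is_combination = TRUE),
      reference_test = list(name = "hip fracture occurrence"),
      has_reference_standard = TRUE,
      cross_tab_derivable = TRUE,
      individual_interval_days = 5 * DAYS_PER_YEAR,  # 5-year prediction window
      interval_basis = "reported",
      sampling_basis = "suspicion",   # all patients aged 50-90 in the organisation
      treatment_context = "untreated_natural_course",
      sampling_mechanism = "consecutive",
      data_source = "payer provider health organisation, all patients aged 50-90"
    ),
    list(
      study_id = "example-4-psa-prostate",
      index_test = list(name = "prostate-specific antigen from blood draw",
                        result_scale = "continuous_with_cutoff",
                        cutoff = "categorised PSA levels"),
      reference_test = list(name = "prostate cancer diagnosed by biopsy"),
      has_reference_standard = TRUE,
      cross_tab_derivable = TRUE,
      individual_interval_days = 7.1 * DAYS_PER_YEAR,  # mean 7.1 years
      interval_basis = "reported",
      sampling_basis = "outcome_status",
      # 540 cases, 1034 controls matched for age and date of blood draw:
      # per-case ratio is non-integer, so matching_ratio stays absent
      treatment_context = "untreated_natural_course",
      sampling_mechanism = "convenience",
      data_source = "nested in a population-based cohort; 540 cases and 1034 controls matched for age and date of blood draw"
    )
  )
  lapply(fixtures, validate_study_record)
}

check_generator_props <- function(sensitivity, specificity) {
  for (p in list(sensitivity = sensitivity, specificity = specificity)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("sensitivity and specificity must be proportions in [0, 1]",
           call. = FALSE)
    }
  }
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Generate matched case-control participants
#'
#' Emulates case-control selection: `n_cases` reference-positive
#' participants and `round(n_cases * control_ratio)` reference-negative
#' controls. Index results are drawn per group — Bernoulli(`sensitivity`)
#' positive among cases, Bernoulli(`1 - specificity`) positive among
#' controls — from a random source scoped to this call and seeded with
#' `seed`, so results are reproducible and the caller's RNG state is
#' untouched. By construction the apparent prevalence of any generated
#' dataset is exactly `1 / (1 + control_ratio)` (e.g. 50% under 1:1
#' matching), which is what makes predictive values meaningless under this
#' design.
#'
#' @param n_cases Positive integer number of cases.
#' @param control_ratio Positive number of controls per case; a non-integer
#'   expected control count is rounded half away from zero with a warning.
#' @param sensitivity,specificity Index test operating characteristics in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A data frame with columns `index_result`, `reference_result`
#'   (`"pos"`/`"neg"`) and `group` (`"case"`/`"control"`).
#' @examples
#' head(generate_matched_case_control(10, 1, 0.9, 0.8, seed = 1))
#' @export
generate_matched_case_control <- function(n_cases, control_ratio,
                                          sensitivity, specificity, seed) {
  if (!is.numeric(n_cases) || length(n_cases) != 1L || is.na(n_cases) ||
      n_cases < 1 || n_cases != round(n_cases)) {
    stop("'n_cases' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(control_ratio) || length(control_ratio) != 1L ||
      is.na(control_ratio) || control_ratio <= 0) {
    stop("'control_ratio' must be a positive number", call. = FALSE)
  }
  check_generator_props(sensitivity, specificity)
  expected_controls <- n_cases * control_ratio
  n_controls <- round_half_up(expected_controls)
  if (n_controls != expected_controls) {
    warning(sprintf("expected control count %g is not an integer; rounding to %d",
                    expected_controls, n_controls), call. = FALSE)
  }
  withr::with_seed(seed, {
    case_index <- ifelse(stats::runif(n_cases) < sensitivity, "pos", "neg")
    control_index <- ifelse(stats::runif(n_controls) < 1 - specificity,
                            "pos", "neg")
  })
  data.frame(
    index_result = c(case_index, control_index),
    reference_result = rep(c("pos", "neg"), c(n_cases, n_controls)),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    stringsAsFactors = FALSE
  )
}

#' Generate suspicion-based cohort participants
#'
#' Emulates cohort-type selection: each of `n` participants is
#' reference-positive with probability `prevalence`; index results follow
#' Bernoulli(`sensitivity`) among reference-positives and
#' Bernoulli(`1 - specificity`) among reference-negatives. The RNG is
#' scoped to the call and seeded with `seed`. At large `n` the 2x2 cell
#' frequencies converge to the product model
#' (e.g. P(tp) = prevalence * sensitivity), which is what the
#' parameter-recovery tests exploit.
#'
#' @param n Positive integer number of participants.
#' @param prevalence Disease/outcome probability in `[0, 1]`.
#' @param sensitivity,specificity Index test operating characteristics in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A data frame with columns `index_result`, `reference_result`.
#' @examples
#' tab <- build_two_by_two(
#'   generate_cohort_participants(1000, 0.2, 0.9, 0.8, seed = 7))
#' compute_measures(tab, "cohort")
#' @export
generate_cohort_participants <- function(n, prevalence, sensitivity,
                                         specificity, seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence < 0 || prevalence > 1) {
    stop("'prevalence' must be a proportion in [0, 1]", call. = FALSE)
  }
  check_generator_props(sensitivity, specificity)
  withr::with_seed(seed, {
    diseased <- stats::runif(n) < prevalence
    index_pos <- ifelse(diseased,
                        stats::runif(n) < sensitivity,
                        stats::runif(n) < 1 - specificity)
  })
  data.frame(
    index_result = ifelse(index_pos, "pos", "neg"),
    reference_result = ifelse(diseased, "pos", "neg"),
    stringsAsFactors = FALSE
  )
}
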