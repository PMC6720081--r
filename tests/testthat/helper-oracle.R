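# Independent brute-force reimplementation of the decision algorithm as a
# nested truth table over discretized inputs. Written directly from the
# decision diagram, deliberately sharing no code with classify_study(); used
# to cross-check the classifier over the full input grid.
oracle_design_label <- function(index_classifiable, ref_classifiable,
                                has_ref, crosstab, comparative,
                                interval, sampling_basis,
                                diag_max, prog_min) {
  if (!index_classifiable) return("unclassifiable")
  if (!ref_classifiable) return("unclassifiable")
  if (!isTRUE(has_ref)) return("unclassifiable")
  if (!isTRUE(crosstab)) return("unclassifiable")
  if (comparative) return("unclassifiable")
  if (is.na(interval)) return("unclassifiable")
  if (interval <= diag_max) {
    if (sampling_basis == "suspicion") {
      "diagnostic_cohort_cross_sectional"
    } else if (sampling_basis == "outcome_status") {
      "diagnostic_case_control_cross_sectional"
    } else {
      "unclassifiable"
    }
  } else if (interval >= prog_min) {
    if (sampling_basis == "suspicion") {
      "prognostic_cohort"
    } else if (sampling_basis == "outcome_status") {
      "prognostic_case_control"
    } else {
      "unclassifiable"
    }
  } else {
    "unclassifiable"
  }
}

# Full discretized grid of classifier inputs: every enum combination crossed
# with interval strata {0, diagnostic max, between windows, prognostic min,
# far beyond, absent}.
oracle_grid <- function() {
  expand.grid(
    index_classifiable = c(TRUE, FALSE),
    ref_classifiable = c(TRUE, FALSE),
    has_ref = c(TRUE, FALSE),
    crosstab = c(TRUE, FALSE, NA),
    comparative = c(TRUE, FALSE),
    interval = c(0, 14, 30, 31, 100, 365, 2000, NA),
    sampling_basis = c("suspicion", "outcome_status", "unclear"),
    treatment = c("untreated_natural_course", "treated", "unclear"),
    stringsAsFactors = FALSE
  )
}

grid_row_to_record <- function(g) {
  make_record(
    interval = g$interval,
    sampling = g$sampling_basis,
    treatment = g$treatment,
    index_classifiable = g$index_classifiable,
    ref_classifiable = g$ref_classifiable,
    has_ref = g$has_ref,
    crosstab = if (is.na(g$crosstab)) NULL else g$crosstab,
    comparative = g$comparative
  )
}
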