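# 2x2 cross table and accuracy measures, with design-validity gating.
# Orientation is fixed: rows = index test (positive, negative), columns =
# reference test (positive, negative); tp/fp/fn/tn names remove any residual
# ambiguity in serialised form.

MEASURE_NAMES <- c("sensitivity", "specificity", "ppv", "npv",
                   "apparent_prevalence", "lr_positive", "lr_negative",
                   "diagnostic_odds_ratio", "accuracy")

#' Construct a 2x2 cross table
#'
#' @param tp,fp,fn,tn Non-negative integer counts: index-positive/
#'   reference-positive (true positive), index-positive/reference-negative
#'   (false positive), index-negative/reference-positive (false negative),
#'   index-negative/reference-negative (true negative).
#' @return An object of class `two_by_two`.
#' @examples
#' two_by_two(tp = 90, fp = 20, fn = 10, tn = 80)
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  counts <- vapply(counts, function(v) suppressWarnings(as.numeric(v)), numeric(1))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("two_by_two: tp, fp, fn, tn must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(index = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Cross-tabulate participant-level test results
#'
#' @param participants A data frame with columns `index_result` and
#'   `reference_result` (values `"pos"`/`"neg"`), or a list of two-element
#'   vectors `(index_result, reference_result)`.
#' @return A [two_by_two()] whose counts sum to the number of participants.
#' @examples
#' build_two_by_two(data.frame(index_result = c("pos", "neg"),
#'                             reference_result = c("pos", "neg")))
#' @export
build_two_by_two <- function(participants) {
  if (is.list(participants) && !is.data.frame(participants)) {
    participants <- data.frame(
      index_result = vapply(participants, `[[`, character(1), 1L),
      reference_result = vapply(participants, `[[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
  }
  if (!is.data.frame(participants) || nrow(participants) == 0L) {
    stop("build_two_by_two: need a non-empty participant table", call. = FALSE)
  }
  if (!all(c("index_result", "reference_result") %in% names(participants))) {
    stop("build_two_by_two: columns 'index_result' and 'reference_result' required",
         call. = FALSE)
  }
  idx <- as.character(participants$index_result)
  ref <- as.character(participants$reference_result)
  if (!all(idx %in% c("pos", "neg")) || !all(ref %in% c("pos", "neg"))) {
    stop("build_two_by_two: results must be 'pos' or 'neg'", call. = FALSE)
  }
  two_by_two(tp = sum(idx == "pos" & ref == "pos"),
             fp = sum(idx == "pos" & ref == "neg"),
             fn = sum(idx == "neg" & ref == "pos"),
             tn = sum(idx == "neg" & ref == "neg"))
}

# Wilson score interval for a binomial proportion (no continuity correction).
wilson_ci <- function(x, n, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Log-method interval for a ratio (LR+, LR-, DOR); NA when any needed cell
# is zero (no continuity correction is applied anywhere).
log_ratio_ci <- function(est, se_log, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(lower = exp(log(est) - z * se_log), upper = exp(log(est) + z * se_log))
}

measure_row <- function(name, estimate, validity, note = "",
                        lower = NA_real_, upper = NA_real_) {
  data.frame(measure = name, estimate = estimate,
             lower = lower, upper = upper,
             validity = validity, note = note, stringsAsFactors = FALSE)
}

#' Compute accuracy measures from a 2x2 table with design gating
#'
#' Point estimates over the 2x2 cells: sensitivity tp/(tp+fn), specificity
#' tn/(tn+fp), PPV tp/(tp+fp), NPV tn/(tn+fn), apparent prevalence
#' (tp+fn)/total, LR+ = sens/(1-spec), LR- = (1-sens)/spec,
#' DOR = LR+/LR-, accuracy (tp+tn)/total.
#'
#' Under case-control sampling the reference-positive column proportion is
#' fixed by the sampling ratio, not by nature, so PPV and NPV are marked
#' `invalid_for_design` with no estimate emitted and apparent prevalence is
#' marked `invalid_for_design` with the note "artificial result of the
#' design". Zero denominators yield `undefined_zero_denominator` rather
#' than a continuity-corrected estimate: no silent 0.5-cell additions.
#'
#' @param table A [two_by_two()] with total count > 0.
#' @param sampling_type `"cohort"`, `"case_control"`, or `"unknown"` (which
#'   computes everything but annotates the prevalence-dependent measures).
#' @param conf_level Optional confidence level (e.g. `0.95`); when given,
#'   Wilson intervals accompany proportions and log-method intervals
#'   accompany LRs and the DOR — standard interval methodology layered on
#'   top of the point estimates.
#' @return A `measure_panel`: data frame with columns `measure`,
#'   `estimate`, `lower`, `upper`, `validity`
#'   (`valid` / `invalid_for_design` / `undefined_zero_denominator`), `note`.
#' @examples
#' compute_measures(two_by_two(90, 20, 10, 80), "cohort")
#' @export
compute_measures <- function(table, sampling_type = c("cohort", "case_control",
                                                      "unknown"),
                             conf_level = NULL) {
  stopifnot(inherits(table, "two_by_two"))
  sampling_type <- match.arg(sampling_type)
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("compute_measures: empty 2x2 table", call. = FALSE)
  cc <- identical(sampling_type, "case_control")
  unknown_note <- if (identical(sampling_type, "unknown"))
    "sampling type unknown; valid only under cohort-type selection" else ""

  prop <- function(name, num, den, invalid = FALSE, invalid_note = "",
                   note = "") {
    if (invalid) {
      return(measure_row(name, NA_real_, "invalid_for_design", invalid_note))
    }
    if (den == 0) {
      return(measure_row(name, NA_real_, "undefined_zero_denominator",
                         "zero denominator"))
    }
    row <- measure_row(name, num / den, "valid", note)
    if (!is.null(conf_level)) {
      ci <- wilson_ci(num, den, conf_level)
      row$lower <- ci[["lower"]]; row$upper <- ci[["upper"]]
    }
    row
  }

  sens_den <- tp + fn; spec_den <- tn + fp
  sens <- if (sens_den > 0) tp / sens_den else NA_real_
  spec <- if (spec_den > 0) tn / spec_den else NA_real_

  panel <- rbind(
    prop("sensitivity", tp, sens_den),
    prop("specificity", tn, spec_den),
    prop("ppv", tp, tp + fp, invalid = cc,
         invalid_note = "predictive values cannot be calculated under case-control selection",
         note = unknown_note),
    prop("npv", tn, tn + fn, invalid = cc,
         invalid_note = "predictive values cannot be calculated under case-control selection",
         note = unknown_note),
    prop("apparent_prevalence", tp + fn, total, invalid = cc,
         invalid_note = "artificial result of the design",
         note = unknown_note)
  )

  ratio <- function(name, est, se_log, defined, note = "") {
    if (!defined) {
      return(measure_row(name, NA_real_, "undefined_zero_denominator",
                         "zero denominator"))
    }
    row <- measure_row(name, est, "valid", note)
    if (!is.null(conf_level) && is.finite(se_log) && est > 0) {
      ci <- log_ratio_ci(est, se_log, conf_level)
      row$lower <- ci[["lower"]]; row$upper <- ci[["upper"]]
    }
    row
  }

  lrp_def <- sens_den > 0 && spec_den > 0 && (1 - spec) > 0
  lrn_def <- sens_den > 0 && spec_den > 0 && spec > 0
  lrp <- if (lrp_def) sens / (1 - spec) else NA_real_
  lrn <- if (lrn_def) (1 - sens) / spec else NA_real_
  se_lrp <- if (lrp_def && tp > 0 && fp > 0)
    sqrt(1 / tp - 1 / sens_den + 1 / fp - 1 / spec_den) else Inf
  se_lrn <- if (lrn_def && fn > 0 && tn > 0)
    sqrt(1 / fn - 1 / sens_den + 1 / tn - 1 / spec_den) else Inf
  dor_def <- lrp_def && lrn_def && lrn > 0
  se_dor <- if (dor_def && all(c(tp, fp, fn, tn) > 0))
    sqrt(1 / tp + 1 / fp + 1 / fn + 1 / tn) else Inf

  panel <- rbind(
    panel,
    ratio("lr_positive", lrp, se_lrp, lrp_def),
    ratio("lr_negative", lrn, se_lrn, lrn_def),
    ratio("diagnostic_odds_ratio", if (dor_def) lrp / lrn else NA_real_,
          se_dor, dor_def),
    prop("accuracy", tp + tn, total, note = unknown_note)
  )
  rownames(panel) <- NULL
  class(panel) <- c("measure_panel", class(panel))
  attr(panel, "sampling_type") <- sampling_type
  panel
}

#' @export
print.measure_panel <- function(x, ...) {
  cat(sprintf("<measure_panel> sampling_type = %s\n",
              attr(x, "sampling_type")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
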