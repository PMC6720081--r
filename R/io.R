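# File interfaces. JSON is the lossless canonical format; CSV is a flattened
# convenience view (nested test descriptors become dot-separated headers,
# decision paths semicolon-joined strings). Policies load from YAML or JSON.

#' Load a time-interval policy from a config file
#'
#' The file (YAML or JSON) must contain the four keys
#' `diagnostic_inclusion_max_days`, `diagnostic_low_rob_max_days`,
#' `prognostic_inclusion_min_days`, `prognostic_low_rob_min_days`.
#' A missing key or an invariant violation (e.g. overlapping diagnostic and
#' prognostic windows) is fatal.
#'
#' @param path Path to the config file.
#' @return A [time_interval_policy()].
#' @export
load_policy <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("policy file not found: %s", path), call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  keys <- c("diagnostic_inclusion_max_days", "diagnostic_low_rob_max_days",
            "prognostic_inclusion_min_days", "prognostic_low_rob_min_days")
  missing <- setdiff(keys, names(cfg))
  if (length(missing) > 0L) {
    stop(sprintf("policy file is missing required key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  do.call(time_interval_policy, cfg[keys])
}

# study_record -> plain list for JSON serialisation
record_to_list <- function(rec) {
  test_list <- function(t) {
    if (is.null(t)) return(NULL)
    out <- list(name = t$name, result_scale = t$result_scale)
    if (!is.null(t$cutoff)) out$cutoff <- t$cutoff
    out$is_combination <- t$is_combination
    out
  }
  out <- list(study_id = rec$study_id,
              index_test = test_list(rec$index_test))
  if (!is.null(rec$reference_test)) {
    out$reference_test <- test_list(rec$reference_test)
  }
  if (!is.na(rec$has_reference_standard)) {
    out$has_reference_standard <- rec$has_reference_standard
  }
  if (!is.na(rec$cross_tab_derivable)) {
    out$cross_tab_derivable <- rec$cross_tab_derivable
  }
  if (!is.na(rec$individual_interval_days)) {
    out$individual_interval_days <- rec$individual_interval_days
  }
  out$interval_basis <- rec$interval_basis
  out$sampling_basis <- rec$sampling_basis
  if (!is.na(rec$matching_ratio)) out$matching_ratio <- rec$matching_ratio
  out$treatment_context <- rec$treatment_context
  out$index_blinded_during_followup <- rec$index_blinded_during_followup
  out$sampling_mechanism <- rec$sampling_mechanism
  out$comparative_design <- rec$comparative_design
  if (nzchar(rec$data_source)) out$data_source <- rec$data_source
  out$condition_progression <- rec$condition_progression
  out
}

#' Write study records to a JSON file
#'
#' @param records List of [study_record][validate_study_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_records <- function(records, path) {
  json <- jsonlite::toJSON(lapply(records, record_to_list),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read study records from JSON or CSV
#'
#' JSON input is an array of record objects; CSV input has one row per
#' record with nested test fields flattened to dot-separated headers
#' (`index_test.name`, `reference_test.cutoff`, ...). Each row is passed
#' through [validate_study_record()]; per-row failures are collected and
#' reported while valid rows proceed. Duplicate `study_id`s among the valid
#' records are fatal.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"json"`, or `"csv"`.
#' @return A list with `records` (validated records), `errors` (data frame
#'   of row / study_id / message for rejected rows) and `warnings`.
#' @export
read_study_records <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  rows <- if (format == "json") {
    parsed <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.list(parsed)) stop("JSON input must be an array of record objects",
                               call. = FALSE)
    parsed
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row[!vapply(row, function(v) length(v) == 1L && is.na(v), logical(1))]
    })
  }

  records <- list()
  errors <- data.frame(row = integer(), study_id = character(),
                       message = character(), stringsAsFactors = FALSE)
  warns <- character()
  if (length(rows) == 0L) {
    warns <- c(warns, "input contains no records")
  }
  for (i in seq_along(rows)) {
    res <- withCallingHandlers(
      tryCatch(validate_study_record(rows[[i]]), error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, sprintf("row %d: %s", i, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      sid <- tryCatch(as.character(rows[[i]]$study_id), error = function(e) NA)
      errors <- rbind(errors, data.frame(
        row = i, study_id = if (length(sid) == 1L && !is.na(sid)) sid else "",
        message = conditionMessage(res), stringsAsFactors = FALSE))
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  ids <- vapply(records, function(r) r$study_id, character(1))
  dups <- unique(ids[duplicated(ids)])
  if (length(dups) > 0L) {
    stop(sprintf("duplicate study_id(s): %s", paste(dups, collapse = ", ")),
         call. = FALSE)
  }
  list(records = records, errors = errors, warnings = warns)
}

result_to_list <- function(r) {
  list(
    study_id = r$study_id,
    is_test_accuracy_study = r$is_test_accuracy_study,
    temporal_class = r$temporal_class,
    clinical_question = r$clinical_question,
    sampling_type = r$sampling_type,
    design_label = r$design_label,
    decision_path = lapply(seq_len(nrow(r$decision_path)), function(i) {
      list(criterion = r$decision_path$criterion[i],
           input = r$decision_path$input[i],
           outcome = r$decision_path$outcome[i])
    }),
    warnings = as.list(r$warnings),
    flags = lapply(r$flags, function(f)
      list(code = f$code, severity = f$severity, rationale = f$rationale))
  )
}

list_to_result <- function(x) {
  path <- do.call(rbind, lapply(x$decision_path, function(s) {
    data.frame(criterion = s$criterion, input = s$input, outcome = s$outcome,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    study_id = x$study_id,
    is_test_accuracy_study = isTRUE(x$is_test_accuracy_study),
    temporal_class = x$temporal_class,
    clinical_question = x$clinical_question,
    sampling_type = x$sampling_type,
    design_label = x$design_label,
    decision_path = path,
    warnings = vapply(x$warnings, as.character, character(1),
                      USE.NAMES = FALSE),
    flags = lapply(x$flags, function(f)
      bias_flag(f$code, f$severity, f$rationale))
  ), class = "classification_result")
}

report_json <- function(results) {
  as.character(jsonlite::toJSON(lapply(results, result_to_list),
                                auto_unbox = TRUE, pretty = TRUE, digits = NA))
}

#' Write a classification report
#'
#' Results are written in input order. CSV flattens each result to one row
#' (decision path, warnings and flags semicolon-joined); JSON is lossless
#' and round-trips byte-identically through [read_report()]; markdown adds
#' a design-distribution summary table above the per-study listing.
#'
#' @param results List of `classification_result` objects (possibly empty).
#' @param path Output path.
#' @param format `"json"`, `"csv"`, or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    writeLines(report_json(results), path)
  } else if (format == "csv") {
    tab <- if (length(results) == 0L) {
      empty <- results_table(list(classify_dummy_for_header()))
      empty[0L, , drop = FALSE]
    } else {
      results_table(results)
    }
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    writeLines(render_markdown_report(results), path)
  }
  invisible(path)
}

# a throwaway result used only to materialise the CSV header for empty output
classify_dummy_for_header <- function() {
  new_classification_result(
    structure(list(study_id = "x"), class = "study_record"),
    FALSE, "indeterminate", "not_applicable", "unclear", "unclassifiable",
    path_step("test_accuracy_gate", "", ""), character(), list())
}

render_markdown_report <- function(results) {
  lines <- c("# Test accuracy design classification report", "")
  counts <- table(factor(vapply(results, function(r) r$design_label,
                                character(1)), levels = DESIGN_LABELS))
  lines <- c(lines, "## Design distribution", "",
             "| design_label | n |", "| --- | ---: |",
             sprintf("| %s | %d |", names(counts), as.integer(counts)), "")
  lines <- c(lines, "## Studies", "")
  for (r in results) {
    lines <- c(lines,
               sprintf("### %s", r$study_id),
               "",
               sprintf("- design: **%s** (temporal=%s, question=%s, sampling=%s)",
                       r$design_label, r$temporal_class, r$clinical_question,
                       r$sampling_type),
               sprintf("- decision path: %s",
                       paste(sprintf("%s -> %s", r$decision_path$criterion,
                                     r$decision_path$outcome), collapse = "; ")))
    if (length(r$warnings)) {
      lines <- c(lines, sprintf("- warnings: %s",
                                paste(r$warnings, collapse = "; ")))
    }
    for (f in r$flags) {
      lines <- c(lines, sprintf("- flag [%s] %s: %s", f$severity, f$code,
                                f$rationale))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, sprintf("_%d studies classified._", length(results)))
  lines
}

#' Read a JSON classification report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A list of `classification_result` objects.
#' @export
read_report <- function(path) {
  parsed <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(parsed, list_to_result)
}

#' Write participant-level results to CSV
#'
#' The CSV (columns `index_result`, `reference_result`, plus any extra
#' columns such as `group`) is directly consumable by [build_two_by_two()].
#'
#' @param participants Data frame from a generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE)
  invisible(path)
}
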