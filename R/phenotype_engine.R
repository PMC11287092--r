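# The composition algorithm: index diagnosis selection, care-setting filter,
# clean window, condition window, supporting evidence, optional exposure.

#' Parameterize one computable phenotype
#'
#' A phenotype definition carries everything the engine needs for one AESI:
#' the diagnosis code set, the care settings in which the index diagnosis may
#' be made, the clean-window length (`"all"` = all available history, the
#' default, or an integer number of days, at least 365), the condition window
#' around the index diagnosis (2 days before and 10 days after by default,
#' unioned with the index encounter span), an optional supporting-evidence
#' rule, and an optional vaccine-exposure rule.
#'
#' @param name Phenotype identifier.
#' @param diagnosis_codes A [code_set()] with category `diagnosis`.
#' @param allowed_care_settings Non-empty subset of [care_settings()].
#' @param clean_window_days `"all"` or an integer `>= 365`.
#' @param condition_window_pre_days,condition_window_post_days Non-negative
#'   integers anchoring the evidence search window to the diagnosis date.
#' @param evidence_rule An evidence-rule tree (see [evidence_any()]) or
#'   `NULL` for no supporting-evidence requirement.
#' @param exposure_rule An [exposure_rule()] or `NULL` (the default;
#'   study-replication mode).
#' @param adjudication_note Free-text note for variants that change only how
#'   chart reviewers interpret the case definition, never the engine.
#' @return An object of class `phenotype_definition`.
#' @export
phenotype_definition <- function(name, diagnosis_codes, allowed_care_settings,
                                 clean_window_days = "all",
                                 condition_window_pre_days = 2L,
                                 condition_window_post_days = 10L,
                                 evidence_rule = NULL, exposure_rule = NULL,
                                 adjudication_note = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  stopifnot(inherits(diagnosis_codes, "code_set"))
  if (diagnosis_codes$category != "diagnosis") {
    abort("`diagnosis_codes` must be a diagnosis code set.")
  }
  allowed_care_settings <- unique(allowed_care_settings)
  if (length(allowed_care_settings) == 0 ||
      !all(allowed_care_settings %in% care_settings())) {
    abort("`allowed_care_settings` must be a non-empty subset of the three settings.")
  }
  if (!identical(clean_window_days, "all")) {
    clean_window_days <- as.integer(clean_window_days)
    if (is.na(clean_window_days) || clean_window_days < 365) {
      abort("`clean_window_days` must be \"all\" or an integer >= 365.")
    }
  }
  pre <- as.integer(condition_window_pre_days)
  post <- as.integer(condition_window_post_days)
  if (is.na(pre) || is.na(post) || pre < 0 || post < 0) {
    abort("Condition-window offsets must be non-negative integers.")
  }
  if (!is.null(evidence_rule) && !inherits(evidence_rule, "evidence_rule")) {
    abort("`evidence_rule` must be NULL or an evidence_rule tree.")
  }
  if (!is.null(exposure_rule) && !inherits(exposure_rule, "exposure_rule")) {
    abort("`exposure_rule` must be NULL or an exposure_rule.")
  }
  structure(
    list(name = name, diagnosis_codes = diagnosis_codes,
         allowed_care_settings = allowed_care_settings,
         clean_window_days = clean_window_days,
         condition_window_pre_days = pre, condition_window_post_days = post,
         evidence_rule = evidence_rule, exposure_rule = exposure_rule,
         adjudication_note = adjudication_note),
    class = "phenotype_definition"
  )
}

#' @export
print.phenotype_definition <- function(x, ...) {
  cat(sprintf("<phenotype_definition> %s\n", x$name))
  cat("  diagnosis codes:", nrow(x$diagnosis_codes$codes), "in",
      x$diagnosis_codes$name, "\n")
  cat("  care settings:  ", paste(x$allowed_care_settings, collapse = ", "), "\n")
  cat("  clean window:   ",
      if (identical(x$clean_window_days, "all")) "all history"
      else paste(x$clean_window_days, "days"), "\n")
  cat(sprintf("  condition window: [dx - %d, dx + %d] days, unioned with encounter\n",
              x$condition_window_pre_days, x$condition_window_post_days))
  cat("  evidence rule:  ",
      if (is.null(x$evidence_rule)) "none" else format(x$evidence_rule), "\n")
  cat("  exposure rule:  ",
      if (is.null(x$exposure_rule)) "none (study-replication mode)"
      else sprintf("%s within %d days", x$exposure_rule$vaccine_codes$name,
                   x$exposure_rule$risk_window_days), "\n")
  invisible(x)
}

#' Find candidate index diagnoses
#'
#' Returns every condition event with `diagnosis_role = "final_or_discharge"`
#' whose code appears in the phenotype's diagnosis code set, ordered by
#' `(patient_id, event_date, code)`.  Admitting, working, and other diagnosis
#' roles never qualify.
#'
#' @param conditions The conditions table of an [ehr_bundle()].
#' @param definition A [phenotype_definition()].
#' @return A tibble of candidate rows.
#' @export
find_index_diagnoses <- function(conditions, definition) {
  stopifnot(inherits(definition, "phenotype_definition"))
  out <- conditions[conditions$diagnosis_role == "final_or_discharge" &
                      codes_match(conditions, definition$diagnosis_codes), ]
  dplyr::arrange(tibble::as_tibble(out), .data$patient_id, .data$event_date,
                 .data$code)
}

#' Keep candidates diagnosed in an allowed care setting
#'
#' Joins candidates to their encounters and keeps those whose grouped care
#' setting is allowed by the definition.  Candidates whose encounter cannot
#' be resolved are excluded and counted in the `n_unresolved` attribute.
#'
#' @param candidates Output of [find_index_diagnoses()].
#' @param encounters The encounters table.
#' @param definition A [phenotype_definition()].
#' @return Filtered candidates with a `care_setting` column.
#' @export
apply_care_setting_filter <- function(candidates, encounters, definition) {
  joined <- dplyr::left_join(
    candidates,
    encounters[, c("encounter_id", "start_date", "end_date", "care_setting")],
    by = "encounter_id")
  unresolved <- is.na(joined$care_setting)
  if (any(unresolved)) {
    warn(sprintf("%d candidate(s) excluded: encounter not resolvable.",
                 sum(unresolved)))
  }
  out <- joined[!unresolved &
                  joined$care_setting %in% definition$allowed_care_settings, ]
  attr(out, "n_unresolved") <- sum(unresolved)
  out
}

#' Apply the clean-window (first-ever-diagnosis) rule
#'
#' Ensures the index diagnosis is the first known diagnosis of its type.
#' Patients whose qualifying final/discharge diagnosis codes occur in more
#' than one distinct encounter are excluded entirely as possible chronic
#' conditions (under the default all-history clean window; under a finite
#' window only prior occurrences inside the lookback disqualify).  Multiple
#' qualifying diagnosis rows inside the single index encounter count as one
#' occurrence, and the earliest such date becomes the index date.  Candidates
#' with less than 365 days of coverage before the index date are excluded
#' with reason `insufficient_history`.
#'
#' @param candidates Output of [apply_care_setting_filter()].
#' @param all_conditions The full conditions table (all care settings), used
#'   to find prior occurrences.
#' @param definition A [phenotype_definition()].
#' @param coverage A [dataset_coverage()].
#' @return One candidate row per surviving patient; excluded patients are
#'   tabulated in the `exclusions` attribute (`patient_id`, `reason`).
#' @export
apply_clean_window <- function(candidates, all_conditions, definition,
                               coverage) {
  if (nrow(candidates) == 0) {
    out <- candidates
    attr(out, "exclusions") <- tibble::tibble(patient_id = character(),
                                              reason = character())
    return(out)
  }
  occ <- all_conditions[
    all_conditions$diagnosis_role == "final_or_discharge" &
      codes_match(all_conditions, definition$diagnosis_codes), ]
  # occurrence key: distinct encounter; rows without an encounter each stand
  # alone so an unanchored repeat still reads as recurrence
  occ$occ_key <- ifelse(is.na(occ$encounter_id),
                        paste0("@", seq_len(nrow(occ))), occ$encounter_id)

  exclusions <- list()
  keep <- list()
  for (pid in unique(candidates$patient_id)) {
    cand_p <- candidates[candidates$patient_id == pid, ]
    occ_p <- occ[occ$patient_id == pid, ]
    # index = earliest qualifying diagnosis date in the earliest candidate
    # encounter (tie-break: date, then code order from upstream sorting)
    cand_p <- cand_p[order(cand_p$event_date, cand_p$code), ]
    index <- cand_p[1, ]

    if (identical(definition$clean_window_days, "all")) {
      chronic <- length(unique(occ_p$occ_key)) > 1
    } else {
      lookback_start <- index$event_date - definition$clean_window_days
      prior <- occ_p$event_date <= index$event_date &
        occ_p$event_date >= lookback_start &
        occ_p$occ_key != index$encounter_id
      chronic <- any(prior)
    }
    if (chronic) {
      exclusions[[pid]] <- "chronic_recurrence"
      next
    }
    if (index$event_date - 365 < coverage$coverage_start) {
      exclusions[[pid]] <- "insufficient_history"
      next
    }
    keep[[pid]] <- index
  }
  out <- dplyr::bind_rows(keep)
  if (nrow(out) == 0) out <- candidates[0, ]
  attr(out, "exclusions") <- tibble::tibble(
    patient_id = names(exclusions),
    reason = unlist(exclusions, use.names = FALSE) %||% character())
  out
}

#' Build the condition window for an index diagnosis
#'
#' The condition window is the union of the index encounter span and the
#' diagnosis-anchored interval `[dx - pre, dx + post]`:
#' `[min(encounter_start, dx - pre), max(encounter_end, dx + post)]`, closed
#' on both ends, at day granularity.
#'
#' @param index_date Diagnosis date.
#' @param encounter_start,encounter_end Index encounter span.
#' @param definition A [phenotype_definition()].
#' @return A list with `start` and `end` dates.
#' @export
build_condition_window <- function(index_date, encounter_start, encounter_end,
                                   definition) {
  index_date <- as.Date(index_date)
  list(
    start = min(as.Date(encounter_start),
                index_date - definition$condition_window_pre_days),
    end = max(as.Date(encounter_end),
              index_date + definition$condition_window_post_days)
  )
}

#' Evaluate the supporting-evidence rule for one candidate
#'
#' A leaf is satisfied iff at least one event of its category dated inside
#' the condition window (the event's own date, not its encounter span)
#' carries a code in the leaf's set.  With no rule the filter passes with an
#' empty match list.
#'
#' @param patient_id Candidate patient.
#' @param window A list with `start`/`end` (see [build_condition_window()]).
#' @param bundle An [ehr_bundle()].
#' @param definition A [phenotype_definition()].
#' @return A list with `pass` (logical) and `matched` (tibble of matching
#'   events with the code-set name that matched, for provenance).
#' @export
apply_evidence_filter <- function(patient_id, window, bundle, definition) {
  events_by_cat <- list(
    medication = bundle$medications[bundle$medications$patient_id == patient_id, ],
    observation = bundle$observations[bundle$observations$patient_id == patient_id, ],
    procedure = bundle$procedures[bundle$procedures$patient_id == patient_id, ]
  )
  eval_evidence_rule(definition$evidence_rule, events_by_cat,
                     window$start, window$end)
}

#' Evaluate the vaccine-exposure rule for one candidate
#'
#' Passes iff at least one immunization event with a code in the rule's
#' vaccine set occurred in `[index_date - risk_window_days, index_date]`
#' (the exposure must precede, or fall on, the diagnosis date).  With no
#' exposure rule the filter is skipped and the candidate is unaffected.
#'
#' @param patient_id Candidate patient.
#' @param index_date Diagnosis date.
#' @param immunizations The immunizations table.
#' @param definition A [phenotype_definition()].
#' @return `TRUE`/`FALSE` (always `TRUE` when no rule is set).
#' @export
apply_exposure_filter <- function(patient_id, index_date, immunizations,
                                  definition) {
  rule <- definition$exposure_rule
  if (is.null(rule)) return(TRUE)
  ev <- immunizations[immunizations$patient_id == patient_id, ]
  if (nrow(ev) == 0) return(FALSE)
  any(codes_match(ev, rule$vaccine_codes) &
        ev$event_date >= as.Date(index_date) - rule$risk_window_days &
        ev$event_date <= as.Date(index_date))
}

#' Run the full composition algorithm
#'
#' Composes the filters in order: index-diagnosis selection, care-setting
#' filter, clean window, condition window + supporting evidence, and the
#' optional exposure filter.  Output is deterministic (ordered by
#' `patient_id`), with at most one detected case per patient, and carries an
#' `attrition` attribute counting candidates surviving each filter for
#' CONSORT-style reporting.
#'
#' @param bundle A validated [ehr_bundle()].
#' @param definition A [phenotype_definition()].
#' @param check Validate the bundle first and abort on hard violations
#'   (default `TRUE`).
#' @return A tibble of detected cases: `phenotype`, `patient_id`,
#'   `encounter_id`, `index_date`, `care_setting`, `system`, `code`,
#'   `window_start`, `window_end`, `n_evidence`, `evidence` (list column of
#'   matched-evidence tibbles), `filters_passed`.  Attributes: `attrition`
#'   (tibble of per-filter counts) and `exclusions`.
#' @export
detect <- function(bundle, definition, check = TRUE) {
  stopifnot(inherits(bundle, "ehr_bundle"),
            inherits(definition, "phenotype_definition"))
  if (check) {
    report <- validate_dataset(bundle)
    if (nrow(report) > 0) {
      abort(sprintf("Bundle failed validation with %d violation(s); see validate_dataset().",
                    nrow(report)))
    }
  }

  attrition <- list()
  note <- function(step, n) {
    attrition[[length(attrition) + 1]] <<- tibble::tibble(filter = step, n = n)
  }

  cand <- find_index_diagnoses(bundle$conditions, definition)
  note("index_diagnosis", length(unique(cand$patient_id)))

  cand <- apply_care_setting_filter(cand, bundle$encounters, definition)
  note("care_setting", length(unique(cand$patient_id)))

  cand <- apply_clean_window(cand, bundle$conditions, definition,
                             bundle$coverage)
  exclusions <- attr(cand, "exclusions")
  note("clean_window", nrow(cand))

  rows <- list()
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    window <- build_condition_window(row$event_date, row$start_date,
                                     row$end_date, definition)
    ev <- apply_evidence_filter(row$patient_id, window, bundle, definition)
    if (!ev$pass) {
      exclusions <- dplyr::bind_rows(
        exclusions, tibble::tibble(patient_id = row$patient_id,
                                   reason = "missing_evidence"))
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      phenotype = definition$name,
      patient_id = row$patient_id,
      encounter_id = row$encounter_id,
      index_date = row$event_date,
      care_setting = row$care_setting,
      system = row$system,
      code = row$code,
      window_start = window$start,
      window_end = window$end,
      n_evidence = nrow(ev$matched),
      evidence = list(ev$matched)
    )
  }
  out <- dplyr::bind_rows(rows)
  note("supporting_evidence", nrow(out))

  if (!is.null(definition$exposure_rule) && nrow(out) > 0) {
    exposed <- vapply(seq_len(nrow(out)), function(i) {
      apply_exposure_filter(out$patient_id[i], out$index_date[i],
                            bundle$immunizations, definition)
    }, logical(1))
    if (any(!exposed)) {
      exclusions <- dplyr::bind_rows(
        exclusions, tibble::tibble(patient_id = out$patient_id[!exposed],
                                   reason = "no_exposure"))
    }
    out <- out[exposed, ]
  }
  note("exposure", nrow(out))

  if (nrow(out) == 0) {
    out <- tibble::tibble(
      phenotype = character(), patient_id = character(),
      encounter_id = character(), index_date = as.Date(character()),
      care_setting = character(), system = character(), code = character(),
      window_start = as.Date(character()), window_end = as.Date(character()),
      n_evidence = integer(), evidence = list())
  }
  out <- dplyr::arrange(out, .data$patient_id)
  out$filters_passed <- rep(paste(
    c("index_diagnosis", "care_setting", "clean_window",
      "supporting_evidence",
      if (!is.null(definition$exposure_rule)) "exposure"), collapse = ";"),
    nrow(out))
  attr(out, "attrition") <- dplyr::bind_rows(attrition)
  attr(out, "exclusions") <- exclusions
  out
}

#' Per-filter attrition counts of a detection run
#'
#' @param detected The result of [detect()].
#' @return A tibble with one row per filter stage and the number of
#'   candidate patients surviving it.
#' @export
attrition <- function(detected) attr(detected, "attrition")
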