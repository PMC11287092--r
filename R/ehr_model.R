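# Domain types for EHR-shaped data: concept codes, code sets, the seven-table
# bundle, dataset coverage, and structural validation.

# Alias map from raw system spellings to the canonical enumeration.  Keys are
# the raw string lowercased with all non-alphanumerics removed.
.system_aliases <- c(
  "icd10cm"    = "ICD-10-CM",
  "icd10"      = "ICD-10-CM",
  "snomedct"   = "SNOMED-CT",
  "snomed"     = "SNOMED-CT",
  "sct"        = "SNOMED-CT",
  "rxnorm"     = "RxNorm",
  "rxn"        = "RxNorm",
  "ndc"        = "NDC",
  "cpt"        = "CPT",
  "cpt4"       = "CPT",
  "icd10pcs"   = "ICD-10-PCS",
  "loinc"      = "LOINC"
)

#' Normalize an interoperable concept code
#'
#' Maps a raw coding-system label (case-insensitively, accepting common
#' aliases such as `"icd10cm"` or `"SnomedCT"`) onto the closed enumeration in
#' [code_systems()], trims the code, and uppercases it for ICD and CPT
#' systems.  Dots are preserved as written; normalization is idempotent.
#'
#' @param raw_system Character vector of coding-system labels.
#' @param raw_code Character vector of codes (recycled against `raw_system`).
#' @return A tibble with columns `system` and `code`.
#' @examples
#' normalize_code("icd10cm", "i40.1")
#' normalize_code("SnomedCT", " 39579001 ")
#' @export
normalize_code <- function(raw_system, raw_code) {
  if (length(raw_system) == 0) {
    return(tibble::tibble(system = character(), code = character()))
  }
  n <- max(length(raw_system), length(raw_code))
  raw_system <- rep_len(as.character(raw_system), n)
  raw_code <- rep_len(as.character(raw_code), n)

  key <- gsub("[^a-z0-9]", "", tolower(raw_system))
  system <- unname(.system_aliases[key])
  if (anyNA(system)) {
    bad <- unique(raw_system[is.na(system)])
    abort(sprintf("Unknown coding system(s): %s", paste(bad, collapse = ", ")),
          class = "aesidetect_unknown_system")
  }
  code <- trimws(raw_code)
  upper <- system %in% c("ICD-10-CM", "ICD-10-PCS", "CPT")
  code[upper] <- toupper(code[upper])
  if (any(!nzchar(code) | is.na(code))) {
    abort("Empty code after normalization.", class = "aesidetect_empty_code")
  }
  tibble::tibble(system = system, code = code)
}

#' Construct a named, categorized code set
#'
#' A code set is the algorithm's vocabulary unit: a named collection of
#' `(system, code)` pairs with a category that constrains which event stream
#' it may be matched against (diagnosis, medication, observation, procedure,
#' or immunization).
#'
#' @param name Identifier for the set.
#' @param category One of [code_set_categories()].
#' @param codes A data frame with columns `system` and `code` (normalized on
#'   construction; duplicates collapsed).
#' @param concept_label Free-text description of the clinical concept.
#' @param provenance `"published"` for lists transcribed from the validation
#'   study's tables, `"placeholder"` for structurally valid stand-ins the user
#'   is expected to replace with a curated value set.
#' @return An object of class `code_set`.
#' @export
code_set <- function(name, category, codes, concept_label = name,
                     provenance = "user") {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  category <- match.arg(category, code_set_categories())
  codes <- tibble::as_tibble(codes)
  if (!all(c("system", "code") %in% names(codes))) {
    abort("`codes` needs columns `system` and `code`.")
  }
  if (nrow(codes) == 0) {
    abort(sprintf("Code set '%s' has no codes.", name),
          class = "aesidetect_empty_code_set")
  }
  codes <- dplyr::distinct(normalize_code(codes$system, codes$code))
  structure(
    list(name = name, category = category, concept_label = concept_label,
         codes = codes, provenance = provenance),
    class = "code_set"
  )
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf("<code_set> %s [%s, %s]: %d code(s)\n",
              x$name, x$category, x$provenance, nrow(x$codes)))
  invisible(x)
}

#' @export
length.code_set <- function(x) nrow(x$codes)

#' Load a code set from a structured config section or a CSV file
#'
#' Accepts either a parsed config section (a list with `name`, `category`,
#' optional `concept_label`/`provenance`, and a `codes` list of
#' `{system, code}` entries) or the path to a code-list CSV with columns
#' `system, code, description, provenance`.
#'
#' @param x A list (parsed YAML section) or a file path.
#' @param name,category Required when `x` is a CSV path (the CSV carries only
#'   the codes themselves).
#' @param concept_label,provenance Optional overrides for CSV input.
#' @return A [code_set()].
#' @export
load_code_set <- function(x, name = NULL, category = NULL,
                          concept_label = NULL, provenance = NULL) {
  if (is.character(x) && length(x) == 1) {
    df <- readr::read_csv(x, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
    if (is.null(name) || is.null(category)) {
      abort("`name` and `category` are required when loading a code-list CSV.")
    }
    prov <- provenance %||%
      (if ("provenance" %in% names(df)) unique(df$provenance)[1] else "user")
    cs <- code_set(name, category, df[c("system", "code")],
                   concept_label = concept_label %||% name,
                   provenance = prov)
  } else if (is.list(x)) {
    for (field in c("name", "category", "codes")) {
      if (is.null(x[[field]])) {
        abort(sprintf("Code-set section is missing '%s'.", field))
      }
    }
    if (length(x$codes) == 0) {
      abort(sprintf("Code set '%s' has no codes.", x$name),
            class = "aesidetect_empty_code_set")
    }
    codes <- purrr::map_dfr(x$codes, function(entry) {
      tibble::tibble(system = entry$system, code = as.character(entry$code))
    })
    cs <- code_set(x$name, x$category, codes,
                   concept_label = x$concept_label %||% x$name,
                   provenance = x$provenance %||% "user")
  } else {
    abort("`x` must be a config section (list) or a file path.")
  }
  inform(sprintf("Loaded code set '%s': %d code(s).", cs$name, nrow(cs$codes)))
  cs
}

# TRUE where (system, code) rows of `events` appear in the code set.
codes_match <- function(events, set) {
  paste(events$system, events$code) %in%
    paste(set$codes$system, set$codes$code)
}

#' Declare dataset coverage and study period
#'
#' The engine requires at least one year of pre-study history so that every
#' index diagnosis has a minimum one-year clean window; `coverage_start` must
#' therefore be at least 365 days before `study_start`.
#'
#' @param coverage_start,coverage_end First/last date any event may carry.
#' @param study_start,study_end The surveillance period proper.
#' @return An object of class `dataset_coverage`.
#' @export
dataset_coverage <- function(coverage_start = "2017-01-01",
                             coverage_end = "2022-05-01",
                             study_start = "2018-01-01",
                             study_end = "2022-05-01") {
  cov <- list(
    coverage_start = as.Date(coverage_start),
    coverage_end = as.Date(coverage_end),
    study_start = as.Date(study_start),
    study_end = as.Date(study_end)
  )
  if (cov$coverage_start > cov$study_start - 365) {
    abort("coverage_start must be at least 365 days before study_start.")
  }
  if (cov$study_end > cov$coverage_end || cov$study_start > cov$study_end) {
    abort("Study period must lie inside the coverage interval.")
  }
  structure(cov, class = "dataset_coverage")
}

# Empty typed tables -----------------------------------------------------------

empty_patients <- function() {
  tibble::tibble(patient_id = character(), birth_date = as.Date(character()),
                 sex = character(), race = character(), ethnicity = character())
}

empty_encounters <- function() {
  tibble::tibble(encounter_id = character(), patient_id = character(),
                 start_date = as.Date(character()),
                 end_date = as.Date(character()), care_setting = character())
}

empty_events <- function(conditions = FALSE, observations = FALSE) {
  out <- tibble::tibble(patient_id = character(), encounter_id = character(),
                        event_date = as.Date(character()),
                        system = character(), code = character())
  if (conditions) out$diagnosis_role <- character()
  if (observations) {
    out$value_num <- numeric()
    out$value_unit <- character()
  }
  out
}

bundle_tables <- function() {
  c("patients", "encounters", "conditions", "medications", "observations",
    "procedures", "immunizations")
}

#' Assemble an EHR table bundle
#'
#' Bundles the seven flat tables the algorithm consumes (patients,
#' encounters, conditions, medications, observations, procedures,
#' immunizations) together with the dataset coverage declaration.  Tables may
#' be omitted; missing ones become empty typed tables.  Dates are coerced with
#' `as.Date()`.
#'
#' @param patients,encounters,conditions,medications,observations,procedures,immunizations
#'   Data frames in the documented column schemas (see [read_bundle()]).
#' @param coverage A [dataset_coverage()].
#' @return An object of class `ehr_bundle`: a named list of tibbles plus
#'   `coverage`.
#' @export
ehr_bundle <- function(patients = NULL, encounters = NULL, conditions = NULL,
                       medications = NULL, observations = NULL,
                       procedures = NULL, immunizations = NULL,
                       coverage = dataset_coverage()) {
  stopifnot(inherits(coverage, "dataset_coverage"))
  as_tbl <- function(x, empty) {
    if (is.null(x) || nrow(x) == 0) return(empty)
    x <- tibble::as_tibble(x)
    for (col in intersect(names(x), c("event_date", "start_date", "end_date",
                                      "birth_date"))) {
      x[[col]] <- as.Date(x[[col]])
    }
    for (col in setdiff(names(empty), names(x))) x[[col]] <- empty[[col]][NA]
    x[names(empty)]
  }
  structure(
    list(
      patients = as_tbl(patients, empty_patients()),
      encounters = as_tbl(encounters, empty_encounters()),
      conditions = as_tbl(conditions, empty_events(conditions = TRUE)),
      medications = as_tbl(medications, empty_events()),
      observations = as_tbl(observations, empty_events(observations = TRUE)),
      procedures = as_tbl(procedures, empty_events()),
      immunizations = as_tbl(immunizations, empty_events()),
      coverage = coverage
    ),
    class = "ehr_bundle"
  )
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle>", format(x$coverage$coverage_start), "..",
      format(x$coverage$coverage_end), "\n")
  for (tb in bundle_tables()) {
    cat(sprintf("  %-13s %6d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Validate an EHR bundle structurally
#'
#' Produces a report of hard violations: referential breaks (events naming
#' unknown patients or encounters), encounter date inversions, care-setting
#' and diagnosis-role vocabulary violations, event dates outside the declared
#' coverage, and duplicate patient identifiers.  The bundle is accepted only
#' when the report is empty.
#'
#' @param bundle An [ehr_bundle()].
#' @return A tibble with columns `table`, `rule`, `id`, `detail`; zero rows
#'   means the dataset is accepted.
#' @export
validate_dataset <- function(bundle) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  cov <- bundle$coverage
  v <- list()
  add <- function(table, rule, id, detail) {
    if (length(id) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(
        table = table, rule = rule, id = as.character(id), detail = detail)
    }
  }

  p <- bundle$patients
  dup <- p$patient_id[duplicated(p$patient_id)]
  add("patients", "duplicate_patient_id", unique(dup), "patient_id not unique")

  e <- bundle$encounters
  add("encounters", "end_before_start",
      e$encounter_id[!is.na(e$end_date) & e$end_date < e$start_date],
      "end_date < start_date")
  add("encounters", "unknown_care_setting",
      e$encounter_id[!e$care_setting %in% care_settings()],
      "care_setting outside {inpatient, outpatient, emergency}")
  add("encounters", "unknown_patient",
      e$encounter_id[!e$patient_id %in% p$patient_id], "patient not in bundle")

  for (tb in setdiff(bundle_tables(), c("patients", "encounters"))) {
    ev <- bundle[[tb]]
    if (nrow(ev) == 0) next
    add(tb, "unknown_patient", ev$patient_id[!ev$patient_id %in% p$patient_id],
        "patient not in bundle")
    has_enc <- !is.na(ev$encounter_id)
    add(tb, "unknown_encounter",
        ev$patient_id[has_enc & !ev$encounter_id %in% e$encounter_id],
        "encounter not in bundle")
    out_of_range <- ev$event_date < cov$coverage_start |
      ev$event_date > cov$coverage_end
    add(tb, "date_outside_coverage", ev$patient_id[out_of_range],
        "event_date outside declared coverage")
  }

  cond <- bundle$conditions
  add("conditions", "invalid_diagnosis_role",
      cond$patient_id[!cond$diagnosis_role %in%
                        setdiff(diagnosis_roles(), "not_applicable")],
      "conditions must carry a diagnosis role other than not_applicable")

  if (length(v) == 0) {
    tibble::tibble(table = character(), rule = character(), id = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}
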