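# CSV bundle dialect: UTF-8, header row, ISO-8601 dates.  Seven event
# tables plus a coverage.json declaring the coverage and study intervals.

bundle_schemas <- function() {
  list(
    patients = c(patient_id = "c", birth_date = "D", sex = "c", race = "c",
                 ethnicity = "c"),
    encounters = c(encounter_id = "c", patient_id = "c", start_date = "D",
                   end_date = "D", care_setting = "c"),
    conditions = c(patient_id = "c", encounter_id = "c", event_date = "D",
                   system = "c", code = "c", diagnosis_role = "c"),
    medications = c(patient_id = "c", encounter_id = "c", event_date = "D",
                    system = "c", code = "c"),
    observations = c(patient_id = "c", encounter_id = "c", event_date = "D",
                     system = "c", code = "c", value_num = "d",
                     value_unit = "c"),
    procedures = c(patient_id = "c", encounter_id = "c", event_date = "D",
                   system = "c", code = "c"),
    immunizations = c(patient_id = "c", encounter_id = "c", event_date = "D",
                      system = "c", code = "c")
  )
}

#' Write an EHR bundle to a directory
#'
#' `format = "csv"` writes the seven CSV tables plus `coverage.json`;
#' `format = "fhir-ndjson"` writes one newline-delimited-JSON file per FHIR
#' resource type (see [map_fhir_resources()] for the mapping).
#'
#' @param bundle An [ehr_bundle()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"fhir-ndjson"`.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, format = c("csv", "fhir-ndjson")) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "ehr_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "csv") {
    for (tb in bundle_tables()) {
      readr::write_csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
                       na = "")
    }
  } else {
    write_bundle_fhir(bundle, dir)
  }
  cov <- bundle$coverage
  jsonlite::write_json(
    lapply(unclass(cov), as.character),
    file.path(dir, "coverage.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an EHR bundle from a directory
#'
#' Validates file presence (a missing table is an error naming the file)
#' and column schemas (a missing column is an error naming table and
#' column), then returns a typed [ehr_bundle()].
#'
#' @param dir Directory written by [write_bundle()] (or assembled by hand
#'   in the documented dialect).
#' @param format `"csv"` or `"fhir-ndjson"`.
#' @return An [ehr_bundle()].
#' @export
read_bundle <- function(dir, format = c("csv", "fhir-ndjson")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) abort(sprintf("Directory '%s' does not exist.", dir))
  cov_path <- file.path(dir, "coverage.json")
  if (!file.exists(cov_path)) {
    abort("Missing file: coverage.json", class = "aesidetect_missing_file")
  }
  cov_raw <- jsonlite::read_json(cov_path)
  coverage <- dataset_coverage(cov_raw$coverage_start, cov_raw$coverage_end,
                               cov_raw$study_start, cov_raw$study_end)
  if (format == "fhir-ndjson") {
    return(read_bundle_fhir(dir, coverage))
  }

  schemas <- bundle_schemas()
  tables <- list()
  for (tb in names(schemas)) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      abort(sprintf("Missing file: %s.csv", tb),
            class = "aesidetect_missing_file")
    }
    spec <- schemas[[tb]]
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
    missing <- setdiff(names(spec), names(df))
    if (length(missing) > 0) {
      abort(sprintf("Table '%s' is missing column(s): %s", tb,
                    paste(missing, collapse = ", ")),
            class = "aesidetect_schema_mismatch")
    }
    df <- df[names(spec)]
    for (col in names(spec)) {
      if (spec[[col]] == "D") df[[col]] <- as.Date(df[[col]])
      if (spec[[col]] == "d") df[[col]] <- as.numeric(df[[col]])
    }
    tables[[tb]] <- df
    inform(sprintf("Read %s: %d rows.", tb, nrow(df)))
  }
  ehr_bundle(patients = tables$patients, encounters = tables$encounters,
             conditions = tables$conditions, medications = tables$medications,
             observations = tables$observations,
             procedures = tables$procedures,
             immunizations = tables$immunizations, coverage = coverage)
}
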