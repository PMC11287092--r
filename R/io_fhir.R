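# FHIR-style NDJSON: one resource per line, one file per resource type
# (Patient, Encounter, Condition, MedicationAdministration, Observation,
# Procedure, Immunization).  The field mapping is a documented convention
# covering exactly what the detection engine consumes.

fhir_system_uris <- c(
  "ICD-10-CM" = "http://hl7.org/fhir/sid/icd-10-cm",
  "SNOMED-CT" = "http://snomed.info/sct",
  "RxNorm" = "http://www.nlm.nih.gov/research/umls/rxnorm",
  "NDC" = "http://hl7.org/fhir/sid/ndc",
  "CPT" = "http://www.ama-assn.org/go/cpt",
  "ICD-10-PCS" = "http://www.cms.gov/Medicare/Coding/ICD10",
  "LOINC" = "http://loinc.org"
)

fhir_class_codes <- c(inpatient = "IMP", outpatient = "AMB",
                      emergency = "EMER")

# diagnosis_role <-> Condition extension valueCode
fhir_role_codes <- c(final_or_discharge = "final", admitting = "admitting",
                     working = "working", other = "other")

fhir_resource_files <- function() {
  c(patients = "Patient", encounters = "Encounter",
    conditions = "Condition", medications = "MedicationAdministration",
    observations = "Observation", procedures = "Procedure",
    immunizations = "Immunization")
}

coding_of <- function(system, code) {
  list(coding = list(list(system = unname(fhir_system_uris[system]),
                          code = code)))
}

coding_back <- function(concept) {
  coding <- req(concept$coding)[[1]]
  list(system = req(names(fhir_system_uris)[
         match(coding$system, fhir_system_uris)]),
       code = req(coding$code))
}

# a required scalar field: malformed resources fail loudly so the caller
# can skip and log them
req <- function(x) {
  if (is.null(x) || length(x) != 1 || is.na(x)) stop("malformed resource")
  x
}

ref_id <- function(ref) sub("^[A-Za-z]+/", "", req(ref))

event_resource <- function(type, row, date_field) {
  res <- list(resourceType = type,
              subject = list(reference = paste0("Patient/", row$patient_id)))
  if (!is.na(row$encounter_id)) {
    res$encounter <- list(reference = paste0("Encounter/", row$encounter_id))
  }
  res[[date_field]] <- format(row$event_date)
  res
}

write_ndjson <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
}

write_bundle_fhir <- function(bundle, dir) {
  files <- fhir_resource_files()

  recs <- lapply(seq_len(nrow(bundle$patients)), function(i) {
    p <- bundle$patients[i, ]
    list(resourceType = "Patient", id = p$patient_id,
         birthDate = format(p$birth_date), gender = p$sex,
         extension = list(
           list(url = "race", valueString = p$race),
           list(url = "ethnicity", valueString = p$ethnicity)))
  })
  write_ndjson(recs, file.path(dir, "Patient.ndjson"))

  recs <- lapply(seq_len(nrow(bundle$encounters)), function(i) {
    e <- bundle$encounters[i, ]
    list(resourceType = "Encounter", id = e$encounter_id,
         subject = list(reference = paste0("Patient/", e$patient_id)),
         class = list(code = unname(fhir_class_codes[e$care_setting])),
         period = list(start = format(e$start_date),
                       end = format(e$end_date)))
  })
  write_ndjson(recs, file.path(dir, "Encounter.ndjson"))

  recs <- lapply(seq_len(nrow(bundle$conditions)), function(i) {
    r <- bundle$conditions[i, ]
    res <- event_resource("Condition", r, "recordedDate")
    res$code <- coding_of(r$system, r$code)
    res$category <- list(list(coding = list(list(
      code = "encounter-diagnosis"))))
    res$extension <- list(list(
      url = "diagnosis-role",
      valueCode = unname(fhir_role_codes[r$diagnosis_role])))
    res
  })
  write_ndjson(recs, file.path(dir, "Condition.ndjson"))

  recs <- lapply(seq_len(nrow(bundle$medications)), function(i) {
    r <- bundle$medications[i, ]
    res <- event_resource("MedicationAdministration", r, "effectiveDateTime")
    res$medicationCodeableConcept <- coding_of(r$system, r$code)
    res
  })
  write_ndjson(recs, file.path(dir, "MedicationAdministration.ndjson"))

  recs <- lapply(seq_len(nrow(bundle$observations)), function(i) {
    r <- bundle$observations[i, ]
    res <- event_resource("Observation", r, "effectiveDateTime")
    res$code <- coding_of(r$system, r$code)
    if (!is.na(r$value_num)) {
      res$valueQuantity <- list(value = r$value_num, unit = r$value_unit)
    }
    res
  })
  write_ndjson(recs, file.path(dir, "Observation.ndjson"))

  recs <- lapply(seq_len(nrow(bundle$procedures)), function(i) {
    r <- bundle$procedures[i, ]
    res <- event_resource("Procedure", r, "performedDateTime")
    res$code <- coding_of(r$system, r$code)
    res
  })
  write_ndjson(recs, file.path(dir, "Procedure.ndjson"))

  recs <- lapply(seq_len(nrow(bundle$immunizations)), function(i) {
    r <- bundle$immunizations[i, ]
    res <- event_resource("Immunization", r, "occurrenceDateTime")
    res$patient <- res$subject
    res$subject <- NULL
    res$vaccineCode <- coding_of(r$system, r$code)
    res
  })
  write_ndjson(recs, file.path(dir, "Immunization.ndjson"))
  invisible(dir)
}

#' Map parsed FHIR resources to typed records
#'
#' Converts parsed NDJSON records (lists) of the seven supported resource
#' types into rows of the corresponding bundle tables.  The Condition
#' `diagnosis-role` extension maps onto the diagnosis-role vocabulary (a
#' missing role extension defaults to `final_or_discharge`, the USCDI
#' encounter-diagnosis reading).  Unsupported resource types are skipped
#' and counted; malformed records are skipped with a warning naming the
#' line.
#'
#' @param records List of parsed resources (e.g., from one NDJSON file).
#' @return A list of tibbles keyed by bundle table plus `skipped` (named
#'   counts of unmapped resource types).
#' @export
map_fhir_resources <- function(records) {
  sink <- new_event_sink()
  sink$patients <- list()
  skipped <- integer()

  for (i in seq_along(records)) {
    rec <- records[[i]]
    ok <- tryCatch({
      switch(
        rec$resourceType %||% "unknown",
        Patient = {
          sink$patients[[length(sink$patients) + 1]] <- tibble::tibble(
            patient_id = req(rec$id), birth_date = as.Date(req(rec$birthDate)),
            sex = rec$gender %||% "unknown",
            race = fhir_extension(rec, "race") %||% "unknown",
            ethnicity = fhir_extension(rec, "ethnicity") %||% "unknown")
        },
        Encounter = {
          setting <- names(fhir_class_codes)[
            match(rec$class$code, fhir_class_codes)]
          sink$encounters[[length(sink$encounters) + 1]] <- tibble::tibble(
            encounter_id = req(rec$id),
            patient_id = ref_id(rec$subject$reference),
            start_date = as.Date(req(rec$period$start)),
            end_date = as.Date(req(rec$period$end)),
            care_setting = setting)
        },
        Condition = {
          cc <- coding_back(rec$code)
          role_code <- fhir_extension(rec, "diagnosis-role") %||% "final"
          role <- names(fhir_role_codes)[match(role_code, fhir_role_codes)]
          sink$conditions[[length(sink$conditions) + 1]] <- tibble::tibble(
            patient_id = ref_id(rec$subject$reference),
            encounter_id = fhir_encounter_id(rec),
            event_date = as.Date(req(rec$recordedDate)),
            system = cc$system, code = cc$code, diagnosis_role = role)
        },
        MedicationAdministration = {
          cc <- coding_back(rec$medicationCodeableConcept)
          sink$medications[[length(sink$medications) + 1]] <- tibble::tibble(
            patient_id = ref_id(rec$subject$reference),
            encounter_id = fhir_encounter_id(rec),
            event_date = as.Date(req(rec$effectiveDateTime)),
            system = cc$system, code = cc$code)
        },
        Observation = {
          cc <- coding_back(rec$code)
          sink$observations[[length(sink$observations) + 1]] <- tibble::tibble(
            patient_id = ref_id(rec$subject$reference),
            encounter_id = fhir_encounter_id(rec),
            event_date = as.Date(req(rec$effectiveDateTime)),
            system = cc$system, code = cc$code,
            value_num = rec$valueQuantity$value %||% NA_real_,
            value_unit = rec$valueQuantity$unit %||% NA_character_)
        },
        Procedure = {
          cc <- coding_back(rec$code)
          sink$procedures[[length(sink$procedures) + 1]] <- tibble::tibble(
            patient_id = ref_id(rec$subject$reference),
            encounter_id = fhir_encounter_id(rec),
            event_date = as.Date(req(rec$performedDateTime)),
            system = cc$system, code = cc$code)
        },
        Immunization = {
          cc <- coding_back(rec$vaccineCode)
          sink$immunizations[[length(sink$immunizations) + 1]] <- tibble::tibble(
            patient_id = ref_id(rec$patient$reference),
            encounter_id = fhir_encounter_id(rec),
            event_date = as.Date(req(rec$occurrenceDateTime)),
            system = cc$system, code = cc$code)
        },
        {
          nm <- rec$resourceType %||% "unknown"
          cur <- if (nm %in% names(skipped)) skipped[[nm]] else 0L
          skipped[nm] <- cur + 1L
        }
      )
      TRUE
    }, error = function(e) FALSE)
    if (!ok) warn(sprintf("Skipping malformed FHIR record at line %d.", i))
  }

  out <- lapply(sink, function(rows) {
    if (length(rows) == 0) NULL else dplyr::bind_rows(rows)
  })
  out$skipped <- skipped
  out
}

fhir_extension <- function(rec, url) {
  for (ext in rec$extension %||% list()) {
    if (identical(ext$url, url)) {
      return(ext$valueString %||% ext$valueCode)
    }
  }
  NULL
}

fhir_encounter_id <- function(rec) {
  if (is.null(rec$encounter)) NA_character_ else
    ref_id(rec$encounter$reference)
}

read_ndjson <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
             error = function(e) list(resourceType = "malformed"))
  })
}

read_bundle_fhir <- function(dir, coverage) {
  files <- fhir_resource_files()
  parts <- list()
  for (tb in names(files)) {
    path <- file.path(dir, paste0(files[[tb]], ".ndjson"))
    if (!file.exists(path)) {
      abort(sprintf("Missing file: %s.ndjson", files[[tb]]),
            class = "aesidetect_missing_file")
    }
    mapped <- map_fhir_resources(read_ndjson(path))
    parts[[tb]] <- mapped[[tb]]
    n_rec <- if (is.null(mapped[[tb]])) 0L else nrow(mapped[[tb]])
    inform(sprintf("Read %s.ndjson: %d record(s).", files[[tb]], n_rec))
  }
  ehr_bundle(patients = parts$patients, encounters = parts$encounters,
             conditions = parts$conditions, medications = parts$medications,
             observations = parts$observations,
             procedures = parts$procedures,
             immunizations = parts$immunizations, coverage = coverage)
}
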