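# Small fixture builders used across test files.  Everything is constructed
# in code; no stored data.

# A bundle from partial tables, auto-deriving the patients table from the
# ids referenced in encounters.
toy_bundle <- function(encounters = NULL, conditions = NULL,
                       medications = NULL, observations = NULL,
                       procedures = NULL, immunizations = NULL,
                       coverage = dataset_coverage()) {
  pids <- unique(c(
    if (!is.null(encounters)) encounters$patient_id,
    if (!is.null(conditions)) conditions$patient_id))
  patients <- tibble::tibble(
    patient_id = pids,
    birth_date = as.Date("1980-06-15"),
    sex = "female", race = "unknown", ethnicity = "unknown")
  ehr_bundle(patients = patients, encounters = encounters,
             conditions = conditions, medications = medications,
             observations = observations, procedures = procedures,
             immunizations = immunizations, coverage = coverage)
}

enc_row <- function(id, pid, start, end = start, setting = "inpatient") {
  tibble::tibble(encounter_id = id, patient_id = pid,
                 start_date = as.Date(start), end_date = as.Date(end),
                 care_setting = setting)
}

cond_row <- function(pid, enc, date, code, system = "ICD-10-CM",
                     role = "final_or_discharge") {
  tibble::tibble(patient_id = pid, encounter_id = enc,
                 event_date = as.Date(date), system = system, code = code,
                 diagnosis_role = role)
}

event_row <- function(pid, enc, date, code, system) {
  tibble::tibble(patient_id = pid, encounter_id = enc,
                 event_date = as.Date(date), system = system, code = code)
}

# Leaf code-set names of a definition's evidence tree.
rule_set_names_for_test <- function(def) {
  collect <- function(rule) {
    if (is.null(rule)) return(character())
    if (rule$kind == "leaf") return(rule$set$name)
    unlist(lapply(rule$children, collect))
  }
  collect(def$evidence_rule)
}

# A generator config with rates high enough that every planted class is
# exercised in a small cohort.
busy_config <- function(n_patients, seed, phenotypes = aesi_phenotypes()) {
  generator_config(
    n_patients, seed = seed, phenotypes = phenotypes,
    true_case_rate = 0.06, chronic_contamination_rate = 0.02,
    evidence_completeness = 0.6, wrong_role_rate = 0.2,
    wrong_setting_rate = 0.3, background_event_rate = 1)
}
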