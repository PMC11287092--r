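# Seeded synthetic EHR generator with ground-truth labels.  Every planted
# scenario either satisfies all phenotype criteria by construction
# (qualifying_case) or violates exactly one named criterion, so the engine's
# behaviour on generated cohorts is fully known in advance.

#' Distractor code lists for background noise
#'
#' Background events draw from these lists, which are disjoint from every
#' shipped phenotype code set by construction, so a generated cohort can
#' never contain an accidental qualifying diagnosis or accidental supporting
#' evidence: any false positive on synthetic data is a genuine engine bug.
#'
#' @return A named list of tibbles (`condition`, `medication`,
#'   `observation`, `procedure`, `immunization`) with `system`/`code`.
#' @export
distractor_codes <- function() {
  list(
    condition = tibble::tibble(
      system = "ICD-10-CM",
      code = c("Z00.00", "J06.9", "K21.9", "M54.5", "E11.9", "I10")),
    medication = tibble::tibble(
      system = "RxNorm", code = c("197361", "617314", "310965")),
    observation = tibble::tibble(
      system = "LOINC", code = c("2345-7", "718-7", "2160-0")),
    procedure = tibble::tibble(system = "CPT", code = c("99213", "99214")),
    immunization = tibble::tibble(system = "NDC", code = c("49281-0422-50"))
  )
}

planted_classes <- function() {
  c("qualifying_case", "chronic_excluded", "wrong_setting",
    "missing_evidence", "wrong_role", "background")
}

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the study conditions the shipped phenotypes were
#' validated under: a surveillance period from 2018-01-01 to 2022-05-01 with
#' one additional historical year of coverage, no exposure requirement, and
#' an era cutoff at the first US COVID-19 vaccine emergency use
#' authorization (2020-12-11).
#'
#' @param n_patients Number of patients (>= 0).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param phenotypes Character names of shipped phenotypes to plant, or a
#'   named list of [phenotype_definition()]s (variants allowed).
#' @param coverage A [dataset_coverage()].
#' @param true_case_rate Per-patient, per-phenotype probability of planting
#'   an AESI scenario.
#' @param chronic_contamination_rate Probability of instead planting a
#'   multi-encounter (chronic-looking) diagnosis history.
#' @param evidence_completeness Probability that a planted case carries
#'   qualifying supporting evidence (phenotypes without an evidence rule
#'   always qualify).
#' @param wrong_role_rate Probability a planted diagnosis is recorded with an
#'   admitting/working role instead of final/discharge.
#' @param wrong_setting_rate Probability a planted diagnosis is made in a
#'   disallowed care setting (only possible for phenotypes that restrict
#'   settings).
#' @param care_setting_mix Named probabilities over the three settings used
#'   for background encounters and (restricted to allowed settings) planted
#'   cases.
#' @param background_event_rate Expected background events per patient-year.
#' @param exposure_rate Probability a qualifying case receives a vaccination
#'   inside a 42-day window before the index date.
#' @param era_cutoff Date splitting pre/post eras.
#' @param post_era_weight `NULL` for index dates uniform over the study
#'   period, or a probability concentrating planted cases after the cutoff.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients, seed,
                             phenotypes = aesi_phenotypes(),
                             coverage = dataset_coverage(),
                             true_case_rate = 0.01,
                             chronic_contamination_rate = 0.005,
                             evidence_completeness = 0.9,
                             wrong_role_rate = 0.05,
                             wrong_setting_rate = 0.005,
                             care_setting_mix = c(inpatient = 0.2,
                                                  outpatient = 0.6,
                                                  emergency = 0.2),
                             background_event_rate = 2,
                             exposure_rate = 0,
                             era_cutoff = as.Date("2020-12-11"),
                             post_era_weight = NULL) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 0) abort("`n_patients` must be >= 0.")
  if (missing(seed) || is.na(as.integer(seed))) {
    abort("`seed` is mandatory for reproducibility.")
  }
  probs <- c(true_case_rate = true_case_rate,
             chronic_contamination_rate = chronic_contamination_rate,
             evidence_completeness = evidence_completeness,
             wrong_role_rate = wrong_role_rate,
             wrong_setting_rate = wrong_setting_rate,
             exposure_rate = exposure_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("All rates must be probabilities in [0, 1].")
  }
  if (!is.null(post_era_weight) &&
      (post_era_weight < 0 || post_era_weight > 1)) {
    abort("`post_era_weight` must be NULL or in [0, 1].")
  }
  if (!setequal(names(care_setting_mix), care_settings()) ||
      any(care_setting_mix < 0) || sum(care_setting_mix) <= 0) {
    abort("`care_setting_mix` must be non-negative weights over the three settings.")
  }
  if (is.character(phenotypes)) {
    defs <- lapply(phenotypes, get_definition)
    names(defs) <- phenotypes
  } else {
    defs <- phenotypes
    ok <- vapply(defs, inherits, logical(1), "phenotype_definition")
    if (length(defs) == 0 || !all(ok)) {
      abort("`phenotypes` must be phenotype names or definitions.")
    }
    names(defs) <- vapply(defs, function(d) d$name, character(1))
  }
  structure(
    list(n_patients = n_patients, seed = as.integer(seed),
         definitions = defs, coverage = coverage,
         true_case_rate = true_case_rate,
         chronic_contamination_rate = chronic_contamination_rate,
         evidence_completeness = evidence_completeness,
         wrong_role_rate = wrong_role_rate,
         wrong_setting_rate = wrong_setting_rate,
         care_setting_mix = care_setting_mix / sum(care_setting_mix),
         background_event_rate = background_event_rate,
         exposure_rate = exposure_rate,
         era_cutoff = as.Date(era_cutoff),
         post_era_weight = post_era_weight),
    class = "generator_config"
  )
}

# Per-patient seed in [0, 2^31): a fixed affine hash of (cohort seed, index)
# so adding patients never perturbs earlier patients' draws.
patient_seed <- function(seed, i) {
  (as.double(seed) * 48271 + as.double(i) * 110351) %% 2147483647
}

# sample() without the length-1 integer surprise
resample <- function(x, n = 1) x[sample.int(length(x), n, replace = TRUE)]

sample_date <- function(from, to, n = 1) {
  from <- as.Date(from); to <- as.Date(to)
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

sample_setting <- function(mix, allowed = names(mix)) {
  w <- mix[allowed]
  sample(names(w), 1, prob = w / sum(w))
}

# Pick events satisfying an evidence rule: one leaf for ANY nodes, all
# children for ALL nodes.  Returns tibble(system, code, category).
satisfying_evidence <- function(rule) {
  if (is.null(rule)) {
    return(tibble::tibble(system = character(), code = character(),
                          category = character()))
  }
  if (rule$kind == "leaf") {
    pick <- rule$set$codes[sample.int(nrow(rule$set$codes), 1), ]
    return(tibble::tibble(system = pick$system, code = pick$code,
                          category = rule$set$category))
  }
  children <- if (rule$kind == "any") {
    rule$children[sample.int(length(rule$children), 1)]
  } else {
    rule$children
  }
  dplyr::bind_rows(lapply(children, satisfying_evidence))
}

new_event_sink <- function() {
  list(encounters = list(), conditions = list(), medications = list(),
       observations = list(), procedures = list(), immunizations = list())
}

sink_add <- function(sink, table, row) {
  sink[[table]][[length(sink[[table]]) + 1]] <- row
  sink
}

#' Plant one labeled scenario for a patient
#'
#' Emits the minimal encounter/event set realizing the planted class for the
#' given definition: `qualifying_case` satisfies every criterion;
#' `chronic_excluded` repeats the diagnosis in two encounters;
#' `wrong_setting` diagnoses in a disallowed setting; `missing_evidence`
#' omits qualifying evidence (half the time placing evidence strictly
#' outside the condition window to exercise the boundary); `wrong_role`
#' records an admitting/working diagnosis.  Dates are drawn inside the study
#' interval; call inside an established RNG state.
#'
#' @param patient_id Patient identifier.
#' @param definition A [phenotype_definition()].
#' @param planted_class One of [planted_classes()] except `background`.
#' @param config A [generator_config()].
#' @param enc_prefix Prefix for generated encounter ids.
#' @return A named list of row tibbles keyed by bundle table.
#' @export
plant_case <- function(patient_id, definition, planted_class, config,
                       enc_prefix = paste0("E-", patient_id)) {
  stopifnot(planted_class %in% setdiff(planted_classes(), "background"))
  cov <- config$coverage
  mix <- config$care_setting_mix
  sink <- new_event_sink()

  # index date with a 30-day margin so condition windows and boundary
  # evidence stay inside coverage
  late <- cov$study_end - 30
  if (!is.null(config$post_era_weight)) {
    post_from <- max(config$era_cutoff, cov$study_start)
    index_date <- if (runif(1) < config$post_era_weight) {
      sample_date(post_from, late)
    } else {
      sample_date(cov$study_start, min(late, config$era_cutoff - 1))
    }
  } else {
    index_date <- sample_date(cov$study_start, late)
  }

  setting <- if (planted_class == "wrong_setting") {
    disallowed <- setdiff(care_settings(), definition$allowed_care_settings)
    if (length(disallowed) == 0) {
      abort(sprintf(
        "Cannot plant wrong_setting for '%s': all care settings are allowed.",
        definition$name))
    }
    sample(disallowed, 1)
  } else {
    sample_setting(mix, definition$allowed_care_settings)
  }

  enc_id <- paste0(enc_prefix, "-idx")
  enc_end <- index_date + sample(0:4, 1)
  sink <- sink_add(sink, "encounters", tibble::tibble(
    encounter_id = enc_id, patient_id = patient_id,
    start_date = index_date, end_date = enc_end, care_setting = setting))

  role <- if (planted_class == "wrong_role") {
    sample(c("admitting", "working"), 1)
  } else {
    "final_or_discharge"
  }
  dx <- definition$diagnosis_codes$codes[
    sample.int(nrow(definition$diagnosis_codes$codes), 1), ]
  sink <- sink_add(sink, "conditions", tibble::tibble(
    patient_id = patient_id, encounter_id = enc_id, event_date = index_date,
    system = dx$system, code = dx$code, diagnosis_role = role))

  window <- build_condition_window(index_date, index_date, enc_end, definition)

  add_evidence <- function(sink, dates_outside = FALSE) {
    ev <- satisfying_evidence(definition$evidence_rule)
    for (j in seq_len(nrow(ev))) {
      date <- if (dates_outside) {
        window$end + sample(1:5, 1)
      } else {
        index_date + resample(seq(-definition$condition_window_pre_days,
                                  definition$condition_window_post_days))
      }
      tb <- category_table(ev$category[j])
      row <- tibble::tibble(patient_id = patient_id, encounter_id = enc_id,
                            event_date = date, system = ev$system[j],
                            code = ev$code[j])
      if (tb == "observations") {
        row$value_num <- round(runif(1, 1, 100), 1)
        row$value_unit <- "unit"
      }
      sink <- sink_add(sink, tb, row)
    }
    sink
  }

  if (planted_class %in% c("qualifying_case", "wrong_setting", "wrong_role",
                           "chronic_excluded")) {
    sink <- add_evidence(sink)
  } else if (planted_class == "missing_evidence") {
    if (is.null(definition$evidence_rule)) {
      abort(sprintf(
        "Cannot plant missing_evidence for '%s': no evidence rule.",
        definition$name))
    }
    if (runif(1) < 0.5) sink <- add_evidence(sink, dates_outside = TRUE)
  }

  if (planted_class == "chronic_excluded") {
    prior_date <- index_date - sample(60:200, 1)
    enc2 <- paste0(enc_prefix, "-pri")
    sink <- sink_add(sink, "encounters", tibble::tibble(
      encounter_id = enc2, patient_id = patient_id,
      start_date = prior_date, end_date = prior_date + sample(0:3, 1),
      care_setting = sample_setting(mix, definition$allowed_care_settings)))
    sink <- sink_add(sink, "conditions", tibble::tibble(
      patient_id = patient_id, encounter_id = enc2, event_date = prior_date,
      system = dx$system, code = dx$code,
      diagnosis_role = "final_or_discharge"))
  }

  if (planted_class == "qualifying_case" && config$exposure_rate > 0 &&
      runif(1) < config$exposure_rate) {
    vax <- aesi_code_set("covid_vaccines")$codes
    pick <- vax[sample.int(nrow(vax), 1), ]
    sink <- sink_add(sink, "immunizations", tibble::tibble(
      patient_id = patient_id, encounter_id = NA_character_,
      event_date = index_date - sample(0:42, 1),
      system = pick$system, code = pick$code))
  }
  sink
}

#' Generate a synthetic EHR cohort with ground truth
#'
#' Produces an [ehr_bundle()] plus a label table.  Identical
#' `(config, seed)` give byte-identical output; the pseudo-random stream is
#' split per patient so enlarging the cohort never changes earlier
#' patients' data.
#'
#' @param config A [generator_config()].
#' @return A list with `bundle` (an [ehr_bundle()]) and `labels` (a tibble
#'   with `patient_id`, `phenotype`, `planted_class`, `expected_detection`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cov <- config$coverage
  defs <- config$definitions
  distract <- distractor_codes()
  years <- as.numeric(cov$coverage_end - cov$coverage_start) / 365.25

  sink <- new_event_sink()
  patients <- list()
  labels <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%06d", i)
    set.seed(patient_seed(config$seed, i))

    patients[[i]] <- tibble::tibble(
      patient_id = pid,
      birth_date = sample_date("1940-01-01", "2017-12-31"),
      sex = sample(c("male", "female", "unknown"), 1,
                   prob = c(0.44, 0.55, 0.01)),
      race = sample(c("white", "black", "asian", "other", "unknown"), 1,
                    prob = c(0.39, 0.28, 0.02, 0.07, 0.24)),
      ethnicity = sample(c("hispanic", "non_hispanic", "unknown"), 1,
                         prob = c(0.04, 0.70, 0.26)))

    planted_any <- FALSE
    for (ph in names(defs)) {
      def <- defs[[ph]]
      u <- runif(1)
      cls <- NULL
      if (u < config$chronic_contamination_rate) {
        cls <- "chronic_excluded"
      } else if (u < config$chronic_contamination_rate + config$true_case_rate) {
        r <- runif(3)
        restricted <- length(def$allowed_care_settings) < 3
        cls <- if (r[1] < config$wrong_role_rate) {
          "wrong_role"
        } else if (restricted && r[2] < config$wrong_setting_rate) {
          "wrong_setting"
        } else if (!is.null(def$evidence_rule) &&
                   r[3] >= config$evidence_completeness) {
          "missing_evidence"
        } else {
          "qualifying_case"
        }
      }
      if (is.null(cls)) next
      planted_any <- TRUE
      rows <- plant_case(pid, def, cls, config,
                         enc_prefix = paste0("E-", pid, "-", ph))
      for (tb in names(rows)) {
        sink[[tb]] <- c(sink[[tb]], rows[[tb]])
      }
      labels[[length(labels) + 1]] <- tibble::tibble(
        patient_id = pid, phenotype = ph, planted_class = cls,
        expected_detection = cls == "qualifying_case")
    }

    # background noise: distractor-coded encounters across full coverage
    n_bg <- rpois(1, config$background_event_rate * years)
    for (k in seq_len(n_bg)) {
      date <- sample_date(cov$coverage_start, cov$coverage_end - 5)
      enc_id <- sprintf("E-%s-bg%02d", pid, k)
      sink <- sink_add(sink, "encounters", tibble::tibble(
        encounter_id = enc_id, patient_id = pid, start_date = date,
        end_date = date + sample(0:2, 1),
        care_setting = sample_setting(config$care_setting_mix)))
      stream <- sample(c("condition", "medication", "observation",
                         "procedure"), 1, prob = c(0.5, 0.2, 0.2, 0.1))
      pool <- distract[[stream]]
      pick <- pool[sample.int(nrow(pool), 1), ]
      row <- tibble::tibble(patient_id = pid, encounter_id = enc_id,
                            event_date = date, system = pick$system,
                            code = pick$code)
      if (stream == "condition") {
        row$diagnosis_role <- sample(c("final_or_discharge", "admitting",
                                       "working", "other"), 1)
      }
      if (stream == "observation") {
        row$value_num <- round(runif(1, 1, 100), 1)
        row$value_unit <- "unit"
      }
      sink <- sink_add(sink, category_table(stream), row)
    }

    if (!planted_any) {
      labels[[length(labels) + 1]] <- tibble::tibble(
        patient_id = pid, phenotype = NA_character_,
        planted_class = "background", expected_detection = FALSE)
    }
  }

  bundle <- ehr_bundle(
    patients = dplyr::bind_rows(patients),
    encounters = dplyr::bind_rows(sink$encounters),
    conditions = dplyr::bind_rows(sink$conditions),
    medications = dplyr::bind_rows(sink$medications),
    observations = dplyr::bind_rows(sink$observations),
    procedures = dplyr::bind_rows(sink$procedures),
    immunizations = dplyr::bind_rows(sink$immunizations),
    coverage = cov
  )
  labels <- if (length(labels) > 0) {
    dplyr::bind_rows(labels)
  } else {
    tibble::tibble(patient_id = character(), phenotype = character(),
                   planted_class = character(), expected_detection = logical())
  }
  list(bundle = bundle, labels = labels)
}

#' Simulate adjudication records with known operating characteristics
#'
#' Assigns diagnostic-certainty levels so that the expected
#' sufficient-evidence PPV equals `ppv_target` and the expected insufficient
#' fraction equals `insufficiency_rate`; reviewer disagreement on the
#' positive/negative dichotomy is injected at `disagreement_rate` (the first
#' reviewer's read is taken as ground truth and supplied as the tiebreaker).
#'
#' @param case_ids Character vector of case identifiers (or a detected-case
#'   tibble with a `patient_id` column).
#' @param ppv_target Expected P(positive | sufficient evidence).
#' @param insufficiency_rate Expected fraction of level-3 insufficient
#'   records.
#' @param disagreement_rate Probability the second reviewer flips the
#'   dichotomy.
#' @param seed Integer seed.
#' @return An adjudication tibble ready for [adjudicate()].
#' @export
generate_adjudication_truth <- function(case_ids, ppv_target,
                                        insufficiency_rate = 0,
                                        disagreement_rate = 0, seed = 1) {
  if (is.data.frame(case_ids)) case_ids <- case_ids$patient_id
  probs <- c(ppv_target, insufficiency_rate, disagreement_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("Rates must be probabilities in [0, 1].")
  }
  n <- length(case_ids)
  set.seed(seed)
  insufficient <- runif(n) < insufficiency_rate
  positive <- !insufficient & runif(n) < ppv_target
  r1 <- ifelse(insufficient, 3L,
               ifelse(positive, sample(1:2, n, replace = TRUE),
                      sample(4:5, n, replace = TRUE)))
  flip <- !insufficient & runif(n) < disagreement_rate
  r2 <- r1
  r2[flip & positive] <- sample(4:5, sum(flip & positive), replace = TRUE)
  r2[flip & !positive] <- sample(1:2, sum(flip & !positive), replace = TRUE)
  tibble::tibble(
    case_id = as.character(case_ids),
    reviewer_1_level = r1,
    reviewer_2_level = r2,
    tiebreaker_level = ifelse(flip, r1, NA_integer_),
    insufficient_evidence = insufficient,
    is_negative_control = FALSE
  )
}
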