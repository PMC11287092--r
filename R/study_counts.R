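# Published validation counts for the five shipped phenotypes, and the
# machinery to rebuild adjudication record sets from them.  Because the
# validation study published every true-positive count, total case count,
# and sufficient-evidence count, its PPVs are recomputable at desk scale.

#' Published validation counts for the shipped phenotypes
#'
#' True-positive, total-case, and sufficient-evidence counts from the
#' single-site validation study of the shipped algorithms, for the overall
#' samples, the era and care-setting strata, and every sensitivity-analysis
#' variant.  These counts drive the count-regression report in
#' [replicate_study()].
#'
#' @return A tibble: `phenotype`, `analysis` (`overall`, a stratum, or a
#'   variant name), `stratum_type`, `tp`, `n_all`, `n_sufficient`.
#' @export
validation_study_counts <- function() {
  tribble <- tibble::tribble
  tribble(
    ~phenotype, ~analysis, ~stratum_type, ~tp, ~n_all, ~n_sufficient,
    "myocarditis_pericarditis", "overall",    "overall",      86L, 135L, 103L,
    "myocarditis_pericarditis", "pre",        "era",          68L, 100L,  79L,
    "myocarditis_pericarditis", "post",       "era",          18L,  35L,  24L,
    "myocarditis_pericarditis", "inpatient",  "care_setting", 72L,  91L,  79L,
    "myocarditis_pericarditis", "outpatient", "care_setting", 10L,  26L,  16L,
    "myocarditis_pericarditis", "emergency",  "care_setting",  4L,  18L,   8L,
    "myocarditis_pericarditis", "no_nsaids",        "variant", 86L, 135L, 103L,
    "myocarditis_pericarditis", "pericarditis_only", "variant", 59L, 82L,  67L,
    "myocarditis_pericarditis", "myocarditis_only",  "variant", 27L, 53L,  36L,
    "anaphylaxis", "overall",   "overall",      98L, 135L, 105L,
    "anaphylaxis", "pre",       "era",          70L, 100L,  74L,
    "anaphylaxis", "post",      "era",          28L,  35L,  31L,
    "anaphylaxis", "inpatient", "care_setting", 17L,  27L,  19L,
    "anaphylaxis", "emergency", "care_setting", 81L, 108L,  86L,
    "gbs", "overall",   "overall",      34L, 110L, 72L,
    "gbs", "pre",       "era",          24L,  65L, 52L,
    "gbs", "post",      "era",          20L,  45L, 20L,
    "gbs", "inpatient", "care_setting", 34L, 110L, 72L,
    "gbs", "no_gabapentin",            "variant", 33L,  86L, 53L,
    "gbs", "adjusted_case_definition", "variant", 49L, 110L, 72L,
    "gbs", "adjusted_plus_no_gabapentin", "variant", 49L, 86L, 68L,
    "tts", "overall",    "overall",      87L, 135L, 124L,
    "tts", "pre",        "era",          64L, 100L,  91L,
    "tts", "post",       "era",          23L,  35L,  33L,
    "tts", "inpatient",  "care_setting", 86L, 133L, 122L,
    "tts", "outpatient", "care_setting",  1L,   1L,   1L,
    "tts", "emergency",  "care_setting",  0L,   1L,   1L,
    "tts", "i81_only", "variant", 75L, 102L, 96L,
    "tts", "non_i81",  "variant", 12L,  33L, 28L,
    "febrile_seizure", "overall",   "overall",      73L, 100L, 83L,
    "febrile_seizure", "pre",       "era",          73L, 100L, 83L,
    "febrile_seizure", "inpatient", "care_setting",  0L,   1L,  1L,
    "febrile_seizure", "emergency", "care_setting", 73L,  99L, 82L,
    "febrile_seizure", "either_evidence", "variant", 70L, 75L, 73L,
    "febrile_seizure", "both_evidence",   "variant", 63L, 65L, 63L
  )
}

#' Published interrater-reliability results
#'
#' Cohen kappa between the two primary reviewers, per phenotype, with the
#' number of validated cases (sampled cases plus negative controls).
#'
#' @return A tibble: `phenotype`, `n_validated`, `kappa`.
#' @export
validation_study_kappa <- function() {
  tibble::tribble(
    ~phenotype, ~n_validated, ~kappa,
    "myocarditis_pericarditis", 162L, 0.814,
    "anaphylaxis",              162L, 0.770,
    "gbs",                      137L, 0.832,
    "tts",                      162L, 0.851,
    "febrile_seizure",          120L, 0.965
  )
}

#' Reconstruct adjudication records from summary counts
#'
#' Builds the minimal finalized record set consistent with published counts:
#' `tp` concordant level-1 positives, `n_sufficient - tp` concordant level-5
#' negatives, and `n_all - n_sufficient` level-3 insufficient-evidence
#' records.  Running [compute_ppv()] on the result reproduces the published
#' point estimates exactly under both denominator policies.
#'
#' @param tp True positives.
#' @param n_all Total adjudicated cases.
#' @param n_sufficient Cases with sufficient evidence (`tp <= n_sufficient
#'   <= n_all`).
#' @param prefix Case-id prefix.
#' @return A finalized adjudication tibble (see [adjudicate()]).
#' @export
records_from_counts <- function(tp, n_all, n_sufficient = n_all,
                                prefix = "case") {
  if (tp > n_sufficient || n_sufficient > n_all) {
    abort("Need tp <= n_sufficient <= n_all.")
  }
  lv <- c(rep(1L, tp), rep(5L, n_sufficient - tp),
          rep(3L, n_all - n_sufficient))
  adjudicate(tibble::tibble(
    case_id = sprintf("%s-%04d", prefix, seq_along(lv)),
    reviewer_1_level = lv,
    reviewer_2_level = lv,
    tiebreaker_level = NA_integer_,
    insufficient_evidence = lv == 3L,
    is_negative_control = FALSE
  ))
}

#' Recompute every published PPV from its counts
#'
#' For each row of [validation_study_counts()], rebuilds the adjudication
#' record set with [records_from_counts()] and recomputes the PPV under both
#' denominator policies together with Agresti-Coull intervals.
#'
#' @return A tibble with computed `ppv_all`, `ppv_sufficient` (display
#'   percentages) and interval bounds, one row per published analysis.
#' @export
replicate_study <- function() {
  counts <- validation_study_counts()
  purrr::pmap_dfr(counts, function(phenotype, analysis, stratum_type,
                                   tp, n_all, n_sufficient) {
    rec <- records_from_counts(tp, n_all, n_sufficient)
    inc <- compute_ppv(rec, "include_all")
    exc <- compute_ppv(rec, "exclude_insufficient")
    tibble::tibble(
      phenotype = phenotype, analysis = analysis,
      stratum_type = stratum_type,
      tp = tp, n_all = n_all, n_sufficient = n_sufficient,
      ppv_all = inc$ppv_percent,
      ppv_all_lower = round_half_up(100 * inc$ci$lower, 1),
      ppv_all_upper = round_half_up(100 * inc$ci$upper, 1),
      ppv_sufficient = exc$ppv_percent,
      ppv_sufficient_lower = round_half_up(100 * exc$ci$lower, 1),
      ppv_sufficient_upper = round_half_up(100 * exc$ci$upper, 1))
  })
}
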