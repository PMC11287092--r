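myo <- get_definition("myocarditis_pericarditis")
gbs <- get_definition("gbs")

test_that("only final/discharge diagnoses in the code list become candidates", {
  expect_equal(nrow(find_index_diagnoses(empty_events(conditions = TRUE)[0, ],
                                         myo)), 0)

  cand <- find_index_diagnoses(cond_row("P1", "E1", "2019-03-02", "I40.1"),
                               myo)
  expect_equal(nrow(cand), 1)

  for (role in c("admitting", "working", "other")) {
    expect_equal(nrow(find_index_diagnoses(
      cond_row("P1", "E1", "2019-03-02", "I40.1", role = role), myo)), 0)
  }
  expect_equal(nrow(find_index_diagnoses(
    cond_row("P1", "E1", "2019-03-02", "Z00.00"), myo)), 0)
})

test_that("care-setting filter honors the definition's allowed settings", {
  cand <- cond_row("P1", "E1", "2019-03-02", "G61.0")
  er <- enc_row("E1", "P1", "2019-03-02", setting = "emergency")
  expect_equal(nrow(apply_care_setting_filter(cand, er, gbs)), 0)

  inp <- enc_row("E1", "P1", "2019-03-02", setting = "inpatient")
  expect_equal(nrow(apply_care_setting_filter(cand, inp, gbs)), 1)

  myo_cand <- cond_row("P1", "E1", "2019-03-02", "I40.1")
  outp <- enc_row("E1", "P1", "2019-03-02", setting = "outpatient")
  expect_equal(nrow(apply_care_setting_filter(myo_cand, outp, myo)), 1)

  ana <- get_definition("anaphylaxis")  # inpatient + emergency only
  ana_cand <- cond_row("P1", "E1", "2019-03-02", "T78.2")
  expect_equal(nrow(apply_care_setting_filter(ana_cand, outp, ana)), 0)

  expect_warning(
    unresolved <- apply_care_setting_filter(
      cond_row("P1", "EX", "2019-03-02", "I40.1"), inp, myo),
    "not resolvable")
  expect_equal(nrow(unresolved), 0)
})

test_that("clean window keeps first-ever diagnoses and excludes recurrence", {
  cov <- dataset_coverage()
  one_enc <- enc_row("E1", "P1", "2019-03-01", "2019-03-05")
  cand <- apply_care_setting_filter(
    cond_row("P1", "E1", "2019-03-02", "I40.1"), one_enc, myo)

  kept <- apply_clean_window(cand, cond_row("P1", "E1", "2019-03-02", "I40.1"),
                             myo, cov)
  expect_equal(nrow(kept), 1)

  # prior same-code final diagnosis 200 days earlier in another encounter
  hist <- dplyr::bind_rows(cond_row("P1", "E0", "2018-08-14", "I40.1"),
                           cond_row("P1", "E1", "2019-03-02", "I40.1"))
  out <- apply_clean_window(cand, hist, myo, cov)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "exclusions")$reason, "chronic_recurrence")

  # two matching diagnoses in two encounters 5 days apart: patient excluded
  close_pair <- dplyr::bind_rows(cond_row("P1", "E1", "2019-03-02", "I40.1"),
                                 cond_row("P1", "E2", "2019-03-07", "I30.9"))
  expect_equal(nrow(apply_clean_window(cand, close_pair, myo, cov)), 0)

  # several qualifying codes inside the single index encounter are one
  # occurrence; index date is the earliest
  co_coded <- dplyr::bind_rows(cond_row("P1", "E1", "2019-03-03", "I30.9"),
                               cond_row("P1", "E1", "2019-03-02", "I40.1"))
  cand2 <- apply_care_setting_filter(co_coded, one_enc, myo)
  kept2 <- apply_clean_window(cand2, co_coded, myo, cov)
  expect_equal(nrow(kept2), 1)
  expect_equal(kept2$event_date, as.Date("2019-03-02"))

  # a prior admitting diagnosis is not an occurrence
  admit_hist <- dplyr::bind_rows(
    cond_row("P1", "E0", "2018-08-14", "I40.1", role = "admitting"),
    cond_row("P1", "E1", "2019-03-02", "I40.1"))
  expect_equal(nrow(apply_clean_window(cand, admit_hist, myo, cov)), 1)
})

test_that("insufficient pre-index history excludes with its own reason", {
  cov <- dataset_coverage()
  cand <- apply_care_setting_filter(
    cond_row("P1", "E1", "2017-06-01", "I40.1"),
    enc_row("E1", "P1", "2017-06-01"), myo)
  out <- apply_clean_window(cand, cond_row("P1", "E1", "2017-06-01", "I40.1"),
                            myo, cov)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "exclusions")$reason, "insufficient_history")
})

test_that("condition window is the union of encounter span and dx-anchored window", {
  w <- build_condition_window("2021-03-02", "2021-03-01", "2021-03-05", myo)
  expect_equal(w$start, as.Date("2021-02-28"))
  expect_equal(w$end, as.Date("2021-03-12"))

  # long encounter dominates the post side; the dx-anchored pre side stays
  w <- build_condition_window("2021-03-02", "2021-03-01", "2021-03-20", myo)
  expect_equal(w$start, as.Date("2021-02-28"))
  expect_equal(w$end, as.Date("2021-03-20"))

  degenerate <- phenotype_definition(
    "deg", myo$diagnosis_codes, care_settings(),
    condition_window_pre_days = 0, condition_window_post_days = 0)
  w <- build_condition_window("2021-03-02", "2021-03-02", "2021-03-02",
                              degenerate)
  expect_equal(w$start, w$end)
  expect_equal(w$start, as.Date("2021-03-02"))
})

test_that("evidence rules evaluate ANY/ALL trees against the window", {
  feb <- get_definition("febrile_seizure")
  bundle <- toy_bundle(encounters = enc_row("E1", "P1", "2019-03-02"))
  w <- list(start = as.Date("2019-02-28"), end = as.Date("2019-03-12"))

  # base febrile seizure has no rule: pass with no matches
  res <- apply_evidence_filter("P1", w, bundle, feb)
  expect_true(res$pass)
  expect_equal(nrow(res$matched), 0)

  # epinephrine inside the window satisfies the anaphylaxis rule
  ana <- get_definition("anaphylaxis")
  bundle_epi <- toy_bundle(
    encounters = enc_row("E1", "P1", "2019-03-02"),
    medications = event_row("P1", "E1", "2019-03-03", "3992", "RxNorm"))
  res <- apply_evidence_filter("P1", w, bundle_epi, ana)
  expect_true(res$pass)
  expect_equal(res$matched$code_set, "epinephrine_meds")

  # the only evidence 12 days after the window end fails
  bundle_late <- toy_bundle(
    encounters = enc_row("E1", "P1", "2019-03-02"),
    medications = event_row("P1", "E1", "2019-03-24", "3992", "RxNorm"))
  expect_false(apply_evidence_filter("P1", w, bundle_late, ana)$pass)

  # ALL(medication, observation) with only the medication present fails
  feb_both <- apply_variant(feb, "both_evidence")
  bundle_med <- toy_bundle(
    encounters = enc_row("E1", "P1", "2019-03-02"),
    medications = event_row("P1", "E1", "2019-03-03", "161", "RxNorm"))
  expect_false(apply_evidence_filter("P1", w, bundle_med, feb_both)$pass)
  both <- toy_bundle(
    encounters = enc_row("E1", "P1", "2019-03-02"),
    medications = event_row("P1", "E1", "2019-03-03", "161", "RxNorm"),
    observations = event_row("P1", "E1", "2019-03-03", "8310-5", "LOINC"))
  expect_true(apply_evidence_filter("P1", w, both, feb_both)$pass)
})

test_that("exposure filter requires a vaccination on or before the index date", {
  myo_exp <- myo
  myo_exp$exposure_rule <- exposure_rule(aesi_code_set("covid_vaccines"), 21)
  vax <- function(date) event_row("P1", NA_character_, date,
                                  "59267-1000-1", "NDC")
  # no rule: skipped
  expect_true(apply_exposure_filter("P1", "2021-03-02",
                                    vax("2099-01-01"), myo))
  expect_true(apply_exposure_filter("P1", "2021-03-02",
                                    vax("2021-02-23"), myo_exp))
  expect_false(apply_exposure_filter("P1", "2021-03-02",
                                     vax("2021-03-03"), myo_exp))
  expect_false(apply_exposure_filter("P1", "2021-03-02",
                                     vax("2021-01-01"), myo_exp))
})

test_that("detect returns an empty typed frame on diagnosis-free data", {
  bundle <- toy_bundle(
    encounters = enc_row("E1", "P1", "2019-03-01"),
    conditions = cond_row("P1", "E1", "2019-03-01", "Z00.00"))
  out <- detect(bundle, myo)
  expect_equal(nrow(out), 0)
  expect_named(attrition(out), c("filter", "n"))
  expect_equal(attrition(out)$n, rep(0L, 5))
})

test_that("detect recovers exactly the planted qualifying cases", {
  cohort <- generate_cohort(busy_config(150, seed = 42))
  labels <- cohort$labels
  for (ph in aesi_phenotypes()) {
    d <- detect(cohort$bundle, get_definition(ph))
    planted <- labels[labels$phenotype %in% ph, ]
    expect_setequal(d$patient_id,
                    planted$patient_id[planted$expected_detection])
    # every detected case carries provenance
    expect_true(all(d$phenotype == ph))
    if (!is.null(get_definition(ph)$evidence_rule) && nrow(d) > 0) {
      expect_true(all(d$n_evidence >= 1))
      for (i in seq_len(nrow(d))) {
        ev <- d$evidence[[i]]
        expect_true(all(ev$event_date >= d$window_start[i] &
                          ev$event_date <= d$window_end[i]))
      }
    }
  }
})

test_that("planted violations are excluded with the matching attrition reason", {
  cohort <- generate_cohort(busy_config(300, seed = 99))
  labels <- cohort$labels
  reason_for <- c(chronic_excluded = "chronic_recurrence",
                  missing_evidence = "missing_evidence")
  for (ph in aesi_phenotypes()) {
    d <- detect(cohort$bundle, get_definition(ph))
    excl <- attr(d, "exclusions")
    planted <- labels[labels$phenotype %in% ph, ]
    for (cls in c("chronic_excluded", "missing_evidence")) {
      pids <- planted$patient_id[planted$planted_class == cls]
      if (length(pids) == 0) next
      expect_true(all(pids %in% excl$patient_id), info = paste(ph, cls))
      expect_true(all(excl$reason[excl$patient_id %in% pids] ==
                        reason_for[[cls]]), info = paste(ph, cls))
    }
  }
})

test_that("engine matches the brute-force oracle on random cohorts", {
  for (seed in c(3, 17, 201)) {
    cohort <- generate_cohort(busy_config(120, seed = seed))
    for (ph in aesi_phenotypes()) {
      def <- get_definition(ph)
      expect_identical(sort(detect(cohort$bundle, def)$patient_id),
                       brute_force_detect(cohort$bundle, def),
                       info = paste("seed", seed, ph))
    }
  }
})

test_that("detection is monotone in evidence breadth and care settings", {
  cohort <- generate_cohort(busy_config(200, seed = 5))
  def <- get_definition("myocarditis_pericarditis")
  n_base <- nrow(detect(cohort$bundle, def))

  # shrinking the evidence rule never adds cases
  narrowed <- apply_variant(def, "no_nsaids")
  expect_lte(nrow(detect(cohort$bundle, narrowed)), n_base)

  # narrowing allowed care settings never adds cases
  inpatient_only <- def
  inpatient_only$allowed_care_settings <- "inpatient"
  expect_lte(nrow(detect(cohort$bundle, inpatient_only)), n_base)

  # a strictly larger evidence rule never removes cases
  widened <- def
  widened$evidence_rule <- evidence_any(
    def$evidence_rule, evidence_leaf(aesi_code_set("antipyretic_meds")))
  expect_gte(nrow(detect(cohort$bundle, widened)), n_base)
})

test_that("identical inputs give byte-identical detection output", {
  cohort <- generate_cohort(busy_config(80, seed = 8))
  a <- detect(cohort$bundle, myo)
  b <- detect(cohort$bundle, myo)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})
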