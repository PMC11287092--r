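test_that("round_half_up rounds display percentages conventionally", {
  expect_equal(round_half_up(83.45), 83.5)
  expect_equal(round_half_up(86 / 103 * 100), 83.5)
  expect_equal(round_half_up(87.95), 88.0)
  expect_equal(round_half_up(2.5, 0), 3)
})

fake_cases <- function(n_pre, n_post, phenotype = "gbs",
                       cutoff = as.Date("2020-12-11")) {
  tibble::tibble(
    phenotype = phenotype,
    patient_id = sprintf("%s-P%04d", phenotype, seq_len(n_pre + n_post)),
    index_date = c(cutoff - 30 - seq_len(n_pre),
                   cutoff + seq_len(n_post)))
}

test_that("stratified sampling honors caps, eras, and overrides", {
  plan <- sampling_plan(seed = 77)

  # all 75 pre-era cases and a random 35 of the 45 post-era cases
  gbs_sample <- stratified_sample(fake_cases(75, 45), plan)
  expect_equal(sum(gbs_sample$era == "pre"), 75)
  expect_equal(sum(gbs_sample$era == "post"), 35)

  # caps bind when both eras are rich
  big <- stratified_sample(fake_cases(120, 60, "tts"), plan)
  expect_equal(table(big$era)[["pre"]], 100)
  expect_equal(table(big$era)[["post"]], 35)

  # an empty era contributes nothing
  pre_only <- stratified_sample(fake_cases(40, 0, "anaphylaxis"), plan)
  expect_equal(nrow(pre_only), 40)

  # febrile seizure samples from the pre-EUA era only
  feb <- stratified_sample(fake_cases(120, 30, "febrile_seizure"), plan)
  expect_equal(nrow(feb), 100)
  expect_true(all(feb$era == "pre"))
})

test_that("sampling is deterministic, a subset, and seed-sensitive", {
  cases <- fake_cases(150, 80)
  plan <- sampling_plan(seed = 123)
  a <- stratified_sample(cases, plan)
  b <- stratified_sample(cases, plan)
  expect_identical(a, b)
  expect_true(all(a$patient_id %in% cases$patient_id))
  expect_false(identical(
    a$patient_id,
    stratified_sample(cases, sampling_plan(seed = 124))$patient_id))
})

test_that("negative controls are drawn per era and exhaust small pools", {
  pool <- dplyr::bind_rows(
    enc_row(sprintf("pre%03d", 1:200), "P1", "2019-05-01"),
    enc_row(sprintf("post%03d", 1:200), "P1", "2021-05-01"))
  plan <- sampling_plan(seed = 9)
  controls <- select_negative_controls(pool, plan)
  expect_equal(nrow(controls), 27)
  expect_equal(sum(controls$era == "pre"), 20)
  expect_equal(sum(controls$era == "post"), 7)
  expect_true(all(controls$is_negative_control))

  small <- pool[1:5, ]  # pre-era only: both eras fall short of the request
  warns <- testthat::capture_warnings(
    few <- select_negative_controls(small, plan))
  expect_match(warns, "pool has", all = TRUE)
  expect_equal(nrow(few), 5)

  none <- sampling_plan(negative_controls_pre = 0, negative_controls_post = 0,
                        seed = 9)
  expect_equal(nrow(select_negative_controls(pool, none)), 0)
})

test_that("the review worklist interleaves and blinds controls", {
  sampled <- fake_cases(10, 5)
  controls <- select_negative_controls(
    enc_row(sprintf("c%02d", 1:30), "P1", "2019-05-01"),
    sampling_plan(negative_controls_post = 0, seed = 1))
  work <- export_review_worklist(sampled, controls, seed = 4)
  expect_equal(nrow(work), nrow(sampled) + nrow(controls))
  expect_false("is_negative_control" %in% names(work))
  expect_true(all(grepl("^case-", work$case_id)))
})

test_that("adjudication follows the dichotomy-and-tiebreaker protocol", {
  rec <- function(r1, r2, tb = NA_integer_, insufficient = FALSE) {
    tibble::tibble(case_id = "c1", reviewer_1_level = r1,
                   reviewer_2_level = r2, tiebreaker_level = tb,
                   insufficient_evidence = insufficient,
                   is_negative_control = FALSE)
  }
  expect_true(adjudicate(rec(2L, 1L))$final_positive)
  expect_false(adjudicate(rec(5L, 5L))$final_positive)
  expect_false(adjudicate(rec(2L, 4L, tb = 4L))$final_positive)
  expect_true(adjudicate(rec(4L, 2L, tb = 1L))$final_positive)
  expect_error(adjudicate(rec(2L, 4L)),
               class = "aesidetect_tiebreak_required")
  expect_error(adjudicate(rec(1L, 2L, tb = 1L)),
               class = "aesidetect_tiebreak_unexpected")
  # insufficient-evidence designations adjudicate to level 3, never positive
  expect_false(adjudicate(rec(3L, 3L, insufficient = TRUE))$final_positive)
  expect_error(adjudicate(rec(5L, 5L, insufficient = TRUE)), "level 3")
  expect_error(adjudicate(rec(0L, 5L)), "1..5")
})

test_that("dual-denominator PPV reproduces published point estimates", {
  # 86 positives among 135 cases, 103 with sufficient evidence
  rec <- records_from_counts(86, 135, 103)
  exc <- compute_ppv(rec, "exclude_insufficient")
  inc <- compute_ppv(rec, "include_all")
  expect_equal(exc$ppv_percent, 83.5)
  expect_equal(inc$ppv_percent, 63.7)
  expect_equal(exc$numerator, inc$numerator)

  expect_equal(compute_ppv(records_from_counts(98, 135, 105),
                           "include_all")$ppv_percent, 72.6)
  expect_equal(compute_ppv(records_from_counts(0, 10),
                           "include_all")$ppv_percent, 0)
})

test_that("PPV handles degenerate denominators and negative controls", {
  all_insufficient <- records_from_counts(0, 5, 0)
  res <- compute_ppv(all_insufficient, "exclude_insufficient")
  expect_true(res$undefined)
  expect_true(is.na(res$ppv))

  rec <- records_from_counts(8, 10)
  rec$is_negative_control[1:2] <- TRUE  # two controls, both positive rows
  res <- compute_ppv(rec, "include_all")
  expect_equal(res$denominator, 8)
  expect_equal(res$numerator, 6)
})

test_that("exclude-insufficient PPV dominates include-all with equal numerators", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(20:150, 1)
    n_suff <- sample(5:n, 1)
    tp <- sample(0:n_suff, 1)
    rec <- records_from_counts(tp, n, n_suff)
    exc <- compute_ppv(rec, "exclude_insufficient")
    inc <- compute_ppv(rec, "include_all")
    expect_equal(exc$numerator, inc$numerator)
    expect_gte(exc$ppv, inc$ppv)
    if (n_suff == n) expect_equal(exc$ppv, inc$ppv)
  }
})

test_that("Agresti-Coull intervals match direct evaluation and clip to [0,1]", {
  ci <- agresti_coull_ci(86, 135)
  expect_equal(round(ci$lower, 3), 0.553)
  expect_equal(round(ci$upper, 3), 0.713)
  expect_equal(unname(oracle_agresti_coull(86, 135)),
               c(ci$lower, ci$upper), tolerance = 1e-12)

  sym <- agresti_coull_ci(50, 100)
  expect_equal(sym$p_tilde, 0.5)
  expect_equal(sym$upper - 0.5, 0.5 - sym$lower, tolerance = 1e-12)

  low <- agresti_coull_ci(0, 10)
  expect_equal(low$lower, 0)  # raw bound is negative before clipping
  expect_gt(low$upper, 0)
  expect_error(agresti_coull_ci(1, 0), "n")
  expect_error(agresti_coull_ci(5, 3))
})

test_that("Cohen kappa matches hand computation and its invariants", {
  # identical ratings
  expect_equal(cohen_kappa(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))$kappa, 1)

  # balanced independence: 2x2 table [[25,25],[25,25]]
  r1 <- rep(c(TRUE, TRUE, FALSE, FALSE), each = 25)
  r2 <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 25)
  expect_equal(cohen_kappa(r1, r2)$kappa, 0)

  # [[20,5],[10,65]]: p_o = 0.85, p_e = 0.60, kappa = 0.625
  r1 <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 5, 10, 65))
  r2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 5, 10, 65))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$p_o, 0.85)
  expect_equal(k$p_e, 0.60)
  expect_equal(k$kappa, 0.625)

  # independent cross-check against e1071's agreement implementation
  expect_equal(k$kappa, e1071::classAgreement(table(r1, r2))$kappa)

  # swap invariance
  expect_equal(cohen_kappa(!r1, !r2)$kappa, k$kappa)

  # degenerate expected agreement is flagged, not silently zero
  deg <- cohen_kappa(rep(TRUE, 10), rep(TRUE, 10))
  expect_true(deg$undefined)
  expect_error(cohen_kappa(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("pooled two-proportion test reproduces published comparisons", {
  # pre- vs post-era myocarditis/pericarditis: 68/100 vs 18/35
  res <- two_proportion_test(68, 100, 18, 35)
  expect_equal(round(res$p_value, 2), 0.08)

  # febrile seizure either-evidence variant vs base: 70/75 vs 73/100
  res <- two_proportion_test(70, 75, 73, 100)
  expect_lt(res$p_value, 0.001)

  eq <- two_proportion_test(30, 60, 15, 30)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  deg <- two_proportion_test(10, 10, 5, 5)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  # cross-check z^2 against the uncorrected chi-square test
  res <- two_proportion_test(68, 100, 18, 35)
  chi <- stats::prop.test(c(68, 18), c(100, 35), correct = FALSE)
  expect_equal(res$z^2, unname(chi$statistic), tolerance = 1e-10)
})

test_that("strata summaries give the machine-readable validation table", {
  rec <- dplyr::bind_rows(
    dplyr::mutate(records_from_counts(72, 91, 79, prefix = "inpt"),
                  care_setting = "inpatient", era = "pre"),
    dplyr::mutate(records_from_counts(10, 26, 16, prefix = "outp"),
                  care_setting = "outpatient", era = "pre"),
    dplyr::mutate(records_from_counts(4, 18, 8, prefix = "ed"),
                  care_setting = "emergency", era = "post"))
  report <- summarize_strata(rec)
  inpt <- report[report$stratum == "inpatient", ]
  expect_equal(inpt$ppv_all, 79.1)
  expect_equal(inpt$true_positives, 72)
  expect_equal(report$n_all[report$stratum == "overall"], 135)

  single <- summarize_strata(
    dplyr::mutate(records_from_counts(5, 10), era = "pre"))
  expect_equal(nrow(single), 2)  # overall + one era

  empty <- summarize_strata(records_from_counts(0, 0))
  expect_equal(nrow(empty), 0)
})
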