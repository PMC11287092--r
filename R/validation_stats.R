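# Validation design and statistics: stratified sampling with negative
# controls, two-reviewer adjudication with tiebreaker, dual-denominator PPV
# with Agresti-Coull intervals, Cohen kappa, pooled two-proportion z test,
# and strata summaries.

#' Round half-up for display
#'
#' PPVs are displayed as percentages rounded half-up to one decimal (base
#' `round()` rounds half to even, which does not reproduce conventional
#' table displays).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Plan the validation sample
#'
#' Defaults match the study design the shipped phenotypes were validated
#' under: per phenotype, up to 100 algorithm-selected cases from the
#' pre-EUA era and 35 from the post-EUA era, plus 20 + 7 negative controls;
#' febrile seizure samples from the pre-EUA era only.  The era cutoff
#' defaults to the first US COVID-19 vaccine emergency use authorization.
#'
#' @param pre_cap,post_cap Per-era sampling caps.
#' @param negative_controls_pre,negative_controls_post Control counts.
#' @param era_cutoff Date; index dates on or after it are "post".
#' @param overrides Named list of per-phenotype cap overrides, e.g.
#'   `list(febrile_seizure = list(post_cap = 0))` (the default).
#' @param seed Integer sampling seed.
#' @return A `sampling_plan` list.
#' @export
sampling_plan <- function(pre_cap = 100L, post_cap = 35L,
                          negative_controls_pre = 20L,
                          negative_controls_post = 7L,
                          era_cutoff = as.Date("2020-12-11"),
                          overrides = list(febrile_seizure =
                                             list(post_cap = 0L)),
                          seed = 20180101L) {
  caps <- c(pre_cap, post_cap, negative_controls_pre, negative_controls_post)
  if (any(caps < 0)) abort("Sampling caps must be >= 0.")
  structure(list(pre_cap = as.integer(pre_cap),
                 post_cap = as.integer(post_cap),
                 negative_controls_pre = as.integer(negative_controls_pre),
                 negative_controls_post = as.integer(negative_controls_post),
                 era_cutoff = as.Date(era_cutoff),
                 overrides = overrides, seed = as.integer(seed)),
            class = "sampling_plan")
}

plan_caps <- function(plan, phenotype) {
  caps <- list(pre_cap = plan$pre_cap, post_cap = plan$post_cap)
  ov <- plan$overrides[[phenotype]]
  if (!is.null(ov)) caps <- modifyList(caps, ov)
  caps
}

#' Era of an index date
#' @param date Date vector.
#' @param cutoff Era cutoff date.
#' @return `"pre"`/`"post"` character vector.
#' @export
era_of <- function(date, cutoff) {
  ifelse(as.Date(date) < as.Date(cutoff), "pre", "post")
}

#' Stratified validation sample of detected cases
#'
#' Per phenotype and era, samples `min(cap, available)` cases without
#' replacement, deterministically for a given plan seed.
#'
#' @param detected_cases Tibble with `phenotype`, `patient_id`,
#'   `index_date` columns (output of [detect()] works).
#' @param plan A [sampling_plan()].
#' @return The sampled rows with an `era` column.
#' @export
stratified_sample <- function(detected_cases, plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (nrow(detected_cases) == 0) {
    out <- detected_cases
    out$era <- character()
    return(out)
  }
  cases <- detected_cases
  cases$era <- era_of(cases$index_date, plan$era_cutoff)
  cases <- dplyr::arrange(cases, .data$phenotype, .data$patient_id)

  set.seed(plan$seed)
  picked <- list()
  for (ph in sort(unique(cases$phenotype))) {
    caps <- plan_caps(plan, ph)
    for (era in c("pre", "post")) {
      pool <- cases[cases$phenotype == ph & cases$era == era, ]
      cap <- if (era == "pre") caps$pre_cap else caps$post_cap
      take <- min(cap, nrow(pool))
      if (take > 0) {
        picked[[paste(ph, era)]] <-
          pool[sort(sample.int(nrow(pool), take)), ]
      }
    }
  }
  out <- dplyr::bind_rows(picked)
  if (nrow(out) == 0) out <- cases[0, ]
  out
}

#' Draw negative controls from non-selected encounters
#'
#' Controls are encounters the algorithm did not select, drawn without
#' replacement per era as a blinded data-quality check.  If the pool is
#' smaller than the request the whole pool is returned with a warning.
#'
#' @param non_selected_encounters Encounters tibble (must exclude all
#'   algorithm-selected cases' encounters).
#' @param plan A [sampling_plan()].
#' @return Sampled encounters with `era` and `is_negative_control = TRUE`.
#' @export
select_negative_controls <- function(non_selected_encounters, plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  pool <- non_selected_encounters
  if (nrow(pool) == 0 &&
      plan$negative_controls_pre + plan$negative_controls_post > 0) {
    warn("Negative-control pool is empty.")
  }
  pool$era <- era_of(pool$start_date, plan$era_cutoff)
  pool <- dplyr::arrange(pool, .data$encounter_id)
  set.seed(plan$seed + 1L)
  picked <- list()
  for (era in c("pre", "post")) {
    want <- if (era == "pre") plan$negative_controls_pre else
      plan$negative_controls_post
    sub <- pool[pool$era == era, ]
    if (want > nrow(sub)) {
      warn(sprintf("Requested %d %s-era controls but pool has %d.",
                   want, era, nrow(sub)))
      want <- nrow(sub)
    }
    if (want > 0) picked[[era]] <- sub[sort(sample.int(nrow(sub), want)), ]
  }
  out <- dplyr::bind_rows(picked)
  if (nrow(out) == 0) out <- pool[0, ]
  out$is_negative_control <- rep(TRUE, nrow(out))
  out
}

#' Export a blinded review worklist
#'
#' Interleaves sampled cases and negative controls in a seeded shuffle and
#' drops the `is_negative_control` flag so reviewers are blinded to which
#' rows are controls.
#'
#' @param sampled Sampled cases (tibble).
#' @param controls Output of [select_negative_controls()].
#' @param seed Shuffle seed.
#' @return A tibble with a `case_id` column and no control flag.
#' @export
export_review_worklist <- function(sampled, controls, seed = 1L) {
  sampled$is_negative_control <- rep(FALSE, nrow(sampled))
  all <- dplyr::bind_rows(sampled, controls)
  set.seed(seed)
  all <- all[sample.int(nrow(all)), ]
  all$case_id <- sprintf("case-%04d", seq_len(nrow(all)))
  all$is_negative_control <- NULL
  all
}

#' Finalize two-reviewer adjudication records
#'
#' Each record carries two reviewer certainty levels (1 definite, 2
#' probable, 3 possible, 4 doubtful, 5 ruled out); levels 1-2 are the
#' positive dichotomy.  If the reviewers agree on the dichotomy the shared
#' call stands; a disagreement requires a tiebreaker level, whose dichotomy
#' is final.  A tiebreaker supplied when none is needed, or missing when
#' needed, is an error.  `insufficient_evidence` marks "possible,
#' insufficient evidence" designations and forces the adjudicated level to 3.
#'
#' @param records Tibble with `case_id`, `reviewer_1_level`,
#'   `reviewer_2_level`, optional `tiebreaker_level`,
#'   `insufficient_evidence`, `is_negative_control` columns.
#' @return The records with `final_level` and `final_positive` columns.
#' @export
adjudicate <- function(records) {
  records <- tibble::as_tibble(records)
  for (col in c("reviewer_1_level", "reviewer_2_level")) {
    if (!col %in% names(records)) abort(sprintf("Missing column '%s'.", col))
    lv <- records[[col]]
    if (any(is.na(lv) | lv < 1 | lv > 5)) {
      abort(sprintf("%s must be integers 1..5.", col))
    }
  }
  if (!"tiebreaker_level" %in% names(records)) {
    records$tiebreaker_level <- NA_integer_
  }
  if (!"insufficient_evidence" %in% names(records)) {
    records$insufficient_evidence <- FALSE
  }
  if (!"is_negative_control" %in% names(records)) {
    records$is_negative_control <- FALSE
  }
  pos1 <- records$reviewer_1_level %in% 1:2
  pos2 <- records$reviewer_2_level %in% 1:2
  disagree <- pos1 != pos2
  has_tb <- !is.na(records$tiebreaker_level)
  if (any(disagree & !has_tb)) {
    abort(sprintf("tiebreak_required for %d record(s) with a positive/negative disagreement.",
                  sum(disagree & !has_tb)),
          class = "aesidetect_tiebreak_required")
  }
  if (any(!disagree & has_tb)) {
    abort("tiebreaker_level supplied for records whose reviewers agree.",
          class = "aesidetect_tiebreak_unexpected")
  }
  final_level <- ifelse(disagree, records$tiebreaker_level,
                        records$reviewer_1_level)
  if (any(records$insufficient_evidence & final_level != 3)) {
    abort("insufficient_evidence records must adjudicate to level 3.")
  }
  records$final_level <- as.integer(final_level)
  records$final_positive <- final_level %in% 1:2 &
    !records$insufficient_evidence
  records
}

#' Agresti-Coull binomial confidence interval
#'
#' Adjusted-count interval: with `n_tilde = n + z^2` and
#' `p_tilde = (x + z^2/2) / n_tilde`, the interval is
#' `p_tilde +/- z * sqrt(p_tilde (1 - p_tilde) / n_tilde)`, clipped to
#' `[0, 1]`.
#'
#' @param x Successes (0 <= x <= n).
#' @param n Trials (> 0).
#' @param confidence Coverage level (default 0.95, z = 1.959964).
#' @return A `binomial_interval` list: `x`, `n`, `z`, `n_tilde`, `p_tilde`,
#'   `lower`, `upper`.
#' @export
agresti_coull_ci <- function(x, n, confidence = 0.95) {
  if (length(n) != 1 || is.na(n) || n <= 0) abort("`n` must be > 0.")
  if (is.na(x) || x < 0 || x > n) abort("`x` must satisfy 0 <= x <= n.")
  z <- qnorm(1 - (1 - confidence) / 2)
  n_tilde <- n + z^2
  p_tilde <- (x + z^2 / 2) / n_tilde
  half <- z * sqrt(p_tilde * (1 - p_tilde) / n_tilde)
  structure(list(x = x, n = n, z = z, n_tilde = n_tilde, p_tilde = p_tilde,
                 lower = max(0, p_tilde - half), upper = min(1, p_tilde + half)),
            class = "binomial_interval")
}

#' @export
print.binomial_interval <- function(x, ...) {
  cat(sprintf("%d/%d: %.1f%% (%.1f%%-%.1f%%)\n", x$x, x$n,
              100 * x$x / x$n, 100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Dual-denominator positive predictive value
#'
#' PPV is the fraction of algorithm-selected cases adjudicated positive
#' (levels 1-2).  Under `exclude_insufficient` (the primary display),
#' level-3 insufficient-evidence records are removed from the denominator;
#' under `include_all` they stay in.  The numerator is identical under both
#' policies, so the exclude-insufficient PPV is never smaller.  Negative
#' controls are excluded from both numerator and denominator.
#'
#' @param records Finalized records from [adjudicate()].
#' @param policy `"exclude_insufficient"` or `"include_all"`.
#' @return A `validation_result` list: `numerator`, `denominator`, `ppv`
#'   (proportion), `ppv_percent` (display rounding, half-up to 1 decimal),
#'   `ci` (a `binomial_interval`), `policy`, `undefined`.
#' @export
compute_ppv <- function(records,
                        policy = c("exclude_insufficient", "include_all")) {
  policy <- match.arg(policy)
  if (!"final_positive" %in% names(records)) records <- adjudicate(records)
  records <- records[!records$is_negative_control, ]
  num <- sum(records$final_positive)
  den <- if (policy == "exclude_insufficient") {
    sum(!records$insufficient_evidence)
  } else {
    nrow(records)
  }
  if (den == 0) {
    return(structure(list(numerator = num, denominator = 0L, ppv = NA_real_,
                          ppv_percent = NA_real_, ci = NULL, policy = policy,
                          undefined = TRUE),
                     class = "validation_result"))
  }
  ppv <- num / den
  structure(list(numerator = num, denominator = den, ppv = ppv,
                 ppv_percent = round_half_up(100 * ppv, 1),
                 ci = agresti_coull_ci(num, den), policy = policy,
                 undefined = FALSE),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<validation_result> %s: undefined (denominator 0)\n",
                x$policy))
  } else {
    cat(sprintf("<validation_result> %s: %d/%d = %.1f%% (%.1f%%-%.1f%%)\n",
                x$policy, x$numerator, x$denominator, x$ppv_percent,
                100 * x$ci$lower, 100 * x$ci$upper))
  }
  invisible(x)
}

#' Cohen kappa for two raters on a dichotomy
#'
#' Chance-corrected agreement from the 2x2 table with marginal-product
#' expected agreement: `kappa = (p_o - p_e) / (1 - p_e)`.  Flagged undefined
#' when `p_e = 1` (both raters constant and identical margins).
#'
#' @param rater1,rater2 Equal-length logical (or two-level) vectors.
#' @return A `kappa_result` list: `p_o`, `p_e`, `kappa`, `n_rated`,
#'   `undefined`.
#' @export
cohen_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) {
    abort("Rater vectors must have equal length.")
  }
  if (length(rater1) == 0) abort("Need at least one rated pair.")
  r1 <- as.logical(rater1)
  r2 <- as.logical(rater2)
  n <- length(r1)
  p_o <- mean(r1 == r2)
  p_e <- mean(r1) * mean(r2) + mean(!r1) * mean(!r2)
  undefined <- isTRUE(all.equal(p_e, 1))
  kappa <- if (undefined) NA_real_ else (p_o - p_e) / (1 - p_e)
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa, n_rated = n,
                 undefined = undefined),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %.3f (p_o = %.3f, p_e = %.3f, n = %d)\n",
              x$kappa, x$p_o, x$p_e, x$n_rated))
  invisible(x)
}

#' Pooled two-sample proportion test
#'
#' Normal-approximation z test with pooled variance for comparing two
#' binomial proportions; two-sided p value.  Zero pooled variance (both
#' samples all successes or all failures) returns `p = 1` with a flag.
#'
#' @param x1,n1,x2,n2 Successes and trials in the two samples.
#' @return A list: `z`, `p_value`, `p1`, `p2`, `degenerate`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (any(c(x1, n1, x2, n2) < 0) || x1 > n1 || x2 > n2 ||
      n1 == 0 || n2 == 0) {
    abort("Counts must satisfy 0 <= x <= n, n > 0.")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  var_pooled <- pooled * (1 - pooled) * (1 / n1 + 1 / n2)
  if (var_pooled == 0) {
    return(list(z = 0, p_value = 1, p1 = p1, p2 = p2, degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(var_pooled)
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2,
       degenerate = FALSE)
}

#' Per-stratum validation summary
#'
#' The machine-readable analogue of a stratified validation table: for the
#' overall sample and for each era and care-setting stratum (marginal, not
#' crossed), the case counts and PPVs under both denominator policies with
#' their Agresti-Coull intervals.
#'
#' @param records Finalized adjudication records carrying `era` and/or
#'   `care_setting` columns.
#' @return A tibble with one row per stratum.
#' @export
summarize_strata <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(stratum_type = character(), stratum = character(),
                          n_all = integer(), n_sufficient = integer(),
                          true_positives = integer(),
                          ppv_all = numeric(), ppv_all_lower = numeric(),
                          ppv_all_upper = numeric(),
                          ppv_sufficient = numeric(),
                          ppv_sufficient_lower = numeric(),
                          ppv_sufficient_upper = numeric()))
  }
  if (!"final_positive" %in% names(records)) records <- adjudicate(records)
  records <- records[!records$is_negative_control, ]

  one <- function(sub, type, label) {
    inc <- compute_ppv(sub, "include_all")
    exc <- compute_ppv(sub, "exclude_insufficient")
    tibble::tibble(
      stratum_type = type, stratum = label,
      n_all = nrow(sub), n_sufficient = sum(!sub$insufficient_evidence),
      true_positives = sum(sub$final_positive),
      ppv_all = inc$ppv_percent,
      ppv_all_lower = if (inc$undefined) NA_real_ else
        round_half_up(100 * inc$ci$lower, 1),
      ppv_all_upper = if (inc$undefined) NA_real_ else
        round_half_up(100 * inc$ci$upper, 1),
      ppv_sufficient = exc$ppv_percent,
      ppv_sufficient_lower = if (exc$undefined) NA_real_ else
        round_half_up(100 * exc$ci$lower, 1),
      ppv_sufficient_upper = if (exc$undefined) NA_real_ else
        round_half_up(100 * exc$ci$upper, 1))
  }

  out <- list(one(records, "overall", "overall"))
  for (col in c("era", "care_setting")) {
    if (!col %in% names(records)) next
    for (lev in sort(unique(records[[col]]))) {
      out[[length(out) + 1]] <-
        one(records[records[[col]] == lev, ], col, lev)
    }
  }
  dplyr::bind_rows(out)
}
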