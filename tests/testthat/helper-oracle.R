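# Independent brute-force re-implementation of the composition algorithm:
# enumerates every (patient, diagnosis event) pair and re-checks all rules
# naively with plain loops.  Deliberately shares no code with the engine.

brute_force_detect <- function(bundle, definition) {
  dx_keys <- paste(definition$diagnosis_codes$codes$system,
                   definition$diagnosis_codes$codes$code)
  cond <- as.data.frame(bundle$conditions)
  enc <- as.data.frame(bundle$encounters)
  detected <- character()

  rule_ok <- function(rule, pid, ws, we) {
    if (is.null(rule)) return(TRUE)
    if (rule$kind == "leaf") {
      tb <- switch(rule$set$category, medication = "medications",
                   observation = "observations", procedure = "procedures")
      ev <- as.data.frame(bundle[[tb]])
      ev <- ev[ev$patient_id == pid, , drop = FALSE]
      keys <- paste(rule$set$codes$system, rule$set$codes$code)
      return(any(paste(ev$system, ev$code) %in% keys &
                   ev$event_date >= ws & ev$event_date <= we))
    }
    res <- vapply(rule$children, rule_ok, logical(1), pid = pid,
                  ws = ws, we = we)
    if (rule$kind == "any") any(res) else all(res)
  }

  for (pid in unique(bundle$patients$patient_id)) {
    pc <- cond[cond$patient_id == pid, , drop = FALSE]
    occ <- pc[pc$diagnosis_role == "final_or_discharge" &
                paste(pc$system, pc$code) %in% dx_keys, , drop = FALSE]
    if (nrow(occ) == 0) next

    # candidates: final/discharge qualifying diagnoses in resolvable,
    # allowed-setting encounters
    cands <- NULL
    for (i in seq_len(nrow(occ))) {
      e <- enc[!is.na(occ$encounter_id[i]) &
                 enc$encounter_id == occ$encounter_id[i], , drop = FALSE]
      if (nrow(e) == 1 &&
          e$care_setting %in% definition$allowed_care_settings) {
        row <- occ[i, ]
        row$start_date <- e$start_date
        row$end_date <- e$end_date
        cands <- rbind(cands, row)
      }
    }
    if (is.null(cands) || nrow(cands) == 0) next
    cands <- cands[order(cands$event_date, cands$code), , drop = FALSE]
    index <- cands[1, ]

    occ_keys <- ifelse(is.na(occ$encounter_id),
                       paste0("solo", seq_len(nrow(occ))), occ$encounter_id)
    if (identical(definition$clean_window_days, "all")) {
      if (length(unique(occ_keys)) > 1) next
    } else {
      prior <- occ$event_date <= index$event_date &
        occ$event_date >= index$event_date - definition$clean_window_days &
        occ_keys != index$encounter_id
      if (any(prior)) next
    }
    if (index$event_date - 365 < bundle$coverage$coverage_start) next

    ws <- min(index$start_date,
              index$event_date - definition$condition_window_pre_days)
    we <- max(index$end_date,
              index$event_date + definition$condition_window_post_days)
    if (!rule_ok(definition$evidence_rule, pid, ws, we)) next

    if (!is.null(definition$exposure_rule)) {
      im <- as.data.frame(bundle$immunizations)
      im <- im[im$patient_id == pid, , drop = FALSE]
      keys <- paste(definition$exposure_rule$vaccine_codes$codes$system,
                    definition$exposure_rule$vaccine_codes$codes$code)
      hit <- any(paste(im$system, im$code) %in% keys &
                   im$event_date >=
                     index$event_date - definition$exposure_rule$risk_window_days &
                   im$event_date <= index$event_date)
      if (!hit) next
    }
    detected <- c(detected, pid)
  }
  sort(detected)
}

# Independent Agresti-Coull evaluation used to freeze expected CI values.
oracle_agresti_coull <- function(x, n, z = qnorm(0.975)) {
  nt <- n + z^2
  pt <- (x + z^2 / 2) / nt
  h <- z * sqrt(pt * (1 - pt) / nt)
  c(lower = max(0, pt - h), upper = min(1, pt + h))
}
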