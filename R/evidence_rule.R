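# Boolean expression trees over code-set leaves, evaluated against the
# medication / observation / procedure streams inside a condition window.

#' Build supporting-evidence rules
#'
#' An evidence rule is a boolean expression tree whose leaves are code sets
#' drawn from the medication, observation, or procedure streams.  A leaf is
#' satisfied when at least one event of its category inside the condition
#' window carries a code in the set; `evidence_any()` / `evidence_all()`
#' combine sub-rules with OR / AND.
#'
#' @param set A [code_set()] with category medication, observation, or
#'   procedure.
#' @param ... Child rules (leaves or nested any/all nodes).
#' @return An `evidence_rule` tree node.
#' @export
evidence_leaf <- function(set) {
  stopifnot(inherits(set, "code_set"))
  if (!set$category %in% evidence_categories()) {
    abort(sprintf(
      "Evidence leaves must be medication/observation/procedure sets; '%s' is %s.",
      set$name, set$category))
  }
  structure(list(kind = "leaf", set = set),
            class = c("evidence_leaf", "evidence_rule"))
}

new_evidence_node <- function(kind, children) {
  children <- lapply(children, function(x) {
    if (inherits(x, "code_set")) evidence_leaf(x) else x
  })
  if (length(children) == 0) abort("Evidence node needs at least one child.")
  ok <- vapply(children, inherits, logical(1), what = "evidence_rule")
  if (!all(ok)) abort("Evidence node children must be rules or code sets.")
  structure(list(kind = kind, children = children),
            class = c("evidence_node", "evidence_rule"))
}

#' @rdname evidence_leaf
#' @export
evidence_any <- function(...) new_evidence_node("any", list(...))

#' @rdname evidence_leaf
#' @export
evidence_all <- function(...) new_evidence_node("all", list(...))

#' @export
format.evidence_rule <- function(x, ...) {
  if (x$kind == "leaf") {
    sprintf("%s[%s]", x$set$name, x$set$category)
  } else {
    sprintf("%s(%s)", toupper(x$kind),
            paste(vapply(x$children, format, character(1)), collapse = ", "))
  }
}

#' @export
print.evidence_rule <- function(x, ...) {
  cat("<evidence_rule>", format(x), "\n")
  invisible(x)
}

rule_depth <- function(rule) {
  if (is.null(rule)) return(0L)
  if (rule$kind == "leaf") return(1L)
  1L + max(vapply(rule$children, rule_depth, integer(1)))
}

# Names of code sets referenced anywhere in the tree.
rule_set_names <- function(rule) {
  if (is.null(rule)) return(character())
  if (rule$kind == "leaf") return(rule$set$name)
  unlist(lapply(rule$children, rule_set_names))
}

# Drop leaves whose set name is in `names`; prune nodes left childless.
# Returns NULL when nothing remains.
rule_remove_sets <- function(rule, names) {
  if (is.null(rule)) return(NULL)
  if (rule$kind == "leaf") {
    if (rule$set$name %in% names) return(NULL) else return(rule)
  }
  kept <- purrr::compact(lapply(rule$children, rule_remove_sets, names = names))
  if (length(kept) == 0) return(NULL)
  if (length(kept) == 1) return(kept[[1]])
  new_evidence_node(rule$kind, kept)
}

# Evaluate a rule for one patient.  `events_by_cat` is a named list of event
# tibbles (medication/observation/procedure) already restricted to the
# patient; the window is a closed date interval.
eval_evidence_rule <- function(rule, events_by_cat, window_start, window_end) {
  if (is.null(rule)) {
    return(list(pass = TRUE, matched = empty_matched_evidence()))
  }
  if (rule$kind == "leaf") {
    ev <- events_by_cat[[rule$set$category]]
    if (is.null(ev) || nrow(ev) == 0) {
      return(list(pass = FALSE, matched = empty_matched_evidence()))
    }
    hit <- codes_match(ev, rule$set) &
      ev$event_date >= window_start & ev$event_date <= window_end
    matched <- ev[hit, c("patient_id", "event_date", "system", "code")]
    matched$code_set <- rep(rule$set$name, nrow(matched))
    matched$category <- rep(rule$set$category, nrow(matched))
    return(list(pass = any(hit), matched = tibble::as_tibble(matched)))
  }
  parts <- lapply(rule$children, eval_evidence_rule, events_by_cat,
                  window_start, window_end)
  passes <- vapply(parts, `[[`, logical(1), "pass")
  pass <- if (rule$kind == "any") any(passes) else all(passes)
  matched <- dplyr::bind_rows(lapply(parts[passes], `[[`, "matched"))
  if (nrow(matched) == 0) matched <- empty_matched_evidence()
  list(pass = pass, matched = dplyr::distinct(matched))
}

empty_matched_evidence <- function() {
  tibble::tibble(patient_id = character(), event_date = as.Date(character()),
                 system = character(), code = character(),
                 code_set = character(), category = character())
}

#' Require a vaccine exposure inside a risk window
#'
#' An exposure rule keeps an index diagnosis only when a qualifying
#' immunization occurred within `risk_window_days` days before (or on) the
#' diagnosis date.  Exposure rules are optional and are disabled in
#' study-replication mode, where the validation population is defined without
#' regard to vaccination.
#'
#' @param vaccine_codes A [code_set()] with category `immunization`.
#' @param risk_window_days Positive integer.
#' @return An object of class `exposure_rule`.
#' @export
exposure_rule <- function(vaccine_codes, risk_window_days = 42L) {
  stopifnot(inherits(vaccine_codes, "code_set"))
  if (vaccine_codes$category != "immunization") {
    abort("`vaccine_codes` must be an immunization code set.")
  }
  risk_window_days <- as.integer(risk_window_days)
  if (is.na(risk_window_days) || risk_window_days <= 0) {
    abort("`risk_window_days` must be a positive integer.")
  }
  structure(list(vaccine_codes = vaccine_codes,
                 risk_window_days = risk_window_days),
            class = "exposure_rule")
}
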