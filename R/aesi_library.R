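# Shipped AESI definitions and sensitivity-analysis variants, expressed as
# data (YAML configs + code-list CSVs under inst/extdata) rather than code.

the <- new.env(parent = emptyenv())

extdata <- function(...) {
  system.file("extdata", ..., package = "aesidetect", mustWork = TRUE)
}

#' Names of the five shipped AESI phenotypes
#' @return Character vector.
#' @export
aesi_phenotypes <- function() {
  c("myocarditis_pericarditis", "anaphylaxis", "gbs", "tts", "febrile_seizure")
}

#' Shipped code sets
#'
#' Loads (and caches) every code set registered in the shipped manifest.
#' `aesi_code_set()` returns one by name.
#'
#' @param name Code-set name as listed in the manifest.
#' @return A named list of [code_set()] objects, or a single one.
#' @export
aesi_code_sets <- function() {
  if (!is.null(the$code_sets)) return(the$code_sets)
  manifest <- yaml::read_yaml(extdata("codesets", "manifest.yaml"))
  sets <- purrr::imap(manifest, function(entry, nm) {
    suppressMessages(load_code_set(
      extdata("codesets", entry$file),
      name = nm, category = entry$category,
      concept_label = entry$concept_label))
  })
  the$code_sets <- sets
  sets
}

#' @rdname aesi_code_sets
#' @export
aesi_code_set <- function(name) {
  sets <- aesi_code_sets()
  if (!name %in% names(sets)) {
    abort(sprintf("Unknown code set '%s'. Available: %s", name,
                  paste(names(sets), collapse = ", ")))
  }
  sets[[name]]
}

# Parse an evidence-rule config node: a code-set name, or a one-key map
# {any: [...]} / {all: [...]} with nested nodes.
parse_evidence_node <- function(node) {
  if (is.character(node) && length(node) == 1) {
    return(evidence_leaf(aesi_code_set(node)))
  }
  if (is.list(node) && length(node) == 1 &&
      names(node) %in% c("any", "all")) {
    children <- lapply(node[[1]], parse_evidence_node)
    return(new_evidence_node(names(node), children))
  }
  abort("Malformed evidence-rule config node.")
}

# Union several diagnosis code sets into one, tracking provenance.
union_code_sets <- function(names, out_name) {
  sets <- lapply(names, aesi_code_set)
  codes <- dplyr::distinct(dplyr::bind_rows(lapply(sets, function(s) s$codes)))
  prov <- unique(vapply(sets, function(s) s$provenance, character(1)))
  code_set(out_name, sets[[1]]$category, codes,
           concept_label = paste(vapply(sets, function(s) s$concept_label,
                                        character(1)), collapse = " + "),
           provenance = if (length(prov) == 1) prov else "mixed")
}

#' Retrieve a shipped phenotype definition
#'
#' Resolves the YAML definition config and its referenced code sets into a
#' ready-to-run [phenotype_definition()].  The combined diagnosis code set
#' remembers its component sets (for diagnosis-restriction variants) in the
#' `diagnosis_components` attribute.
#'
#' @param name One of [aesi_phenotypes()].
#' @return A [phenotype_definition()].
#' @examples
#' get_definition("tts")
#' @export
get_definition <- function(name) {
  if (!name %in% aesi_phenotypes()) {
    abort(sprintf("Unknown phenotype '%s'. Valid names: %s", name,
                  paste(aesi_phenotypes(), collapse = ", ")))
  }
  cfg <- yaml::read_yaml(extdata("definitions", paste0(name, ".yaml")))
  dx <- union_code_sets(cfg$diagnosis_code_sets, paste0(name, "_dx"))
  rule <- if (is.null(cfg$evidence_rule)) NULL else
    parse_evidence_node(cfg$evidence_rule)
  def <- phenotype_definition(
    name = cfg$name,
    diagnosis_codes = dx,
    allowed_care_settings = unlist(cfg$allowed_care_settings),
    clean_window_days = cfg$clean_window_days,
    condition_window_pre_days = cfg$condition_window_pre_days,
    condition_window_post_days = cfg$condition_window_post_days,
    evidence_rule = rule
  )
  attr(def, "diagnosis_components") <- cfg$diagnosis_code_sets
  def
}

#' Sensitivity-analysis variant specifications
#'
#' `list_variants()` names the shipped variants of a phenotype;
#' `get_variant()` returns one as a `variant_spec`; `variant_spec()` builds
#' one programmatically.
#'
#' @param phenotype Base phenotype name.
#' @param variant Variant name.
#' @param modification One of `remove_code_set`, `add_evidence_rule`,
#'   `restrict_diagnosis_codes`, `adjusted_adjudication_criteria`.
#' @param payload Code-set names, an evidence-rule config fragment, or a
#'   free-text adjudication note, depending on the modification.
#' @return `variant_spec` object / character vector of names.
#' @export
variant_spec <- function(phenotype, variant, modification, payload = NULL) {
  modification <- match.arg(modification,
                            c("remove_code_set", "add_evidence_rule",
                              "restrict_diagnosis_codes",
                              "adjusted_adjudication_criteria"))
  structure(list(base_phenotype = phenotype, name = variant,
                 modification = modification, payload = payload),
            class = "variant_spec")
}

shipped_variants <- function() {
  if (is.null(the$variants)) {
    the$variants <- yaml::read_yaml(extdata("definitions", "variants.yaml"))
  }
  the$variants
}

#' @rdname variant_spec
#' @export
list_variants <- function(phenotype) {
  names(shipped_variants()[[phenotype]]) %||% character()
}

#' @rdname variant_spec
#' @export
get_variant <- function(phenotype, variant) {
  entry <- shipped_variants()[[phenotype]][[variant]]
  if (is.null(entry)) {
    abort(sprintf("Unknown variant '%s' for phenotype '%s'. Available: %s",
                  variant, phenotype,
                  paste(list_variants(phenotype), collapse = ", ")))
  }
  variant_spec(phenotype, variant, entry$modification, entry$payload)
}

#' Apply a sensitivity-analysis variant to a definition
#'
#' Returns a modified copy of the definition; the original is untouched.
#' `remove_code_set` drops the named code sets from the evidence tree;
#' `add_evidence_rule` installs a new evidence rule;
#' `restrict_diagnosis_codes` replaces the diagnosis list with the union of
#' the named component sets (which must be a subset of the base list);
#' `adjusted_adjudication_criteria` changes only the adjudication
#' interpretation and leaves the engine rules intact.
#'
#' @param definition A [phenotype_definition()].
#' @param variant A [variant_spec()] (or the name of a shipped variant).
#' @return A modified [phenotype_definition()].
#' @export
apply_variant <- function(definition, variant) {
  if (is.character(variant)) {
    variant <- get_variant(definition$name, variant)
  }
  stopifnot(inherits(variant, "variant_spec"))
  if (!identical(variant$base_phenotype, definition$name)) {
    abort(sprintf("Variant '%s' targets phenotype '%s', not '%s'.",
                  variant$name, variant$base_phenotype, definition$name))
  }
  out <- definition
  payload <- variant$payload
  switch(
    variant$modification,
    remove_code_set = {
      out$evidence_rule <- rule_remove_sets(out$evidence_rule,
                                            unlist(payload))
    },
    add_evidence_rule = {
      out$evidence_rule <- parse_evidence_node(payload)
    },
    restrict_diagnosis_codes = {
      restricted <- union_code_sets(unlist(payload),
                                    paste0(definition$name, "_dx_restricted"))
      base_keys <- paste(definition$diagnosis_codes$codes$system,
                         definition$diagnosis_codes$codes$code)
      new_keys <- paste(restricted$codes$system, restricted$codes$code)
      if (!all(new_keys %in% base_keys)) {
        abort("Restricted diagnosis codes must be a subset of the base list.")
      }
      out$diagnosis_codes <- restricted
      attr(out, "diagnosis_components") <- unlist(payload)
    },
    adjusted_adjudication_criteria = {
      out$adjudication_note <- as.character(payload)
    }
  )
  out$name <- paste0(definition$name, ".", variant$name)
  out
}
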