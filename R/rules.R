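# Weighted production rules: AND-joined antecedents over fact attributes, and
# consequents that assert new facts (intermediate facts or *_CODING facts).

#' The registry coding items handled by the shipped configuration
#'
#' Thirty lung-cancer registry items spanning staging, histology, grading,
#' lymph-node counts, surgical margins, dates and site-specific factors.
#'
#' @return Character vector of 30 item names.
#' @export
registry_items <- function() {
  c("AJCC Edition", "Behavior Code", "Clinical Other Staging Group",
    "Clinical Stage Descriptor", "Date of First Microscopic Confirmation",
    "Date of First Surgical Procedure", "Date of Initial Diagnosis",
    "Date of Surgical Diagnostic and Staging Procedure",
    "Diagnostic Confirmation", "Grade Clinical", "Grade Pathological",
    "Histology", "Laterality", "Lymph vessels or Vascular Invasion",
    "Nodes Examined", "Nodes Positive", "Other Staging System",
    "Pathologic M", "Pathologic N", "Pathologic Stage Descriptor",
    "Pathologic T", "Perineural Invasion", "Primary Site",
    "Scope of Regional Lymph Node Surgery", "SSF 2", "SSF 5", "SSF 6",
    "SSF 7", "Surgical Margins", "Surgical Margins Distance")
}

#' Coding fact type for a registry item
#'
#' `"Primary Site"` maps to `"PRIMARY_SITE_CODING"`; the inverse is
#' [coding_type_item()].
#'
#' @param item Registry item name(s).
#' @return Fact type string(s).
#' @export
item_coding_type <- function(item) {
  x <- toupper(gsub("[^A-Za-z0-9]+", "_", item))
  paste0(gsub("_+$", "", x), "_CODING")
}

#' Registry item for a coding fact type
#' @param type Fact type string(s) ending in `_CODING`.
#' @param items Item universe to invert over.
#' @return Item name, or `NA` if the type names no configured item.
#' @export
coding_type_item <- function(type, items = registry_items()) {
  map <- stats::setNames(items, item_coding_type(items))
  unname(map[type])
}

#' Construct a production rule
#'
#' @param rule_id Unique rule identifier.
#' @param coding_item Registry item the rule codes, or `"intermediate"` for
#'   rules that only assert intermediate facts.
#' @param antecedents List of conditions, each a list with `attribute`,
#'   `op` (one of `eq`, `ne`, `ge`, `le`, `present`), `value`, and optionally
#'   `fact_ref`: antecedents sharing a `fact_ref` must be satisfied by one and
#'   the same fact; antecedents without one are bound independently.
#' @param consequent List of assertions, each a named list of attribute-value
#'   pairs including `type` and `value`. A value of the form `"@R.attr"`
#'   copies attribute `attr` from the fact bound to `fact_ref` `R`.
#' @param weight Non-negative rule weight (default 1 until learned).
#' @return An object of class `regcode_rule`.
#' @export
rule <- function(rule_id, coding_item, antecedents, consequent, weight = 1) {
  if (length(antecedents) == 0L) {
    stop("rule ", rule_id, ": antecedents must be non-empty", call. = FALSE)
  }
  ops <- c("eq", "ne", "ge", "le", "present")
  antecedents <- lapply(antecedents, function(a) {
    if (is.null(a$attribute) || is.null(a$op)) {
      stop("rule ", rule_id, ": antecedent lacks attribute/op", call. = FALSE)
    }
    if (!a$op %in% ops) {
      stop("rule ", rule_id, ": unknown operator '", a$op, "'", call. = FALSE)
    }
    if (is.null(a$value) && a$op != "present") {
      stop("rule ", rule_id, ": operator '", a$op, "' needs a value", call. = FALSE)
    }
    list(attribute = as.character(a$attribute), op = a$op,
         value = if (is.null(a$value)) NA_character_ else .fact_scalar(a$value),
         fact_ref = if (is.null(a$fact_ref)) NA_character_ else as.character(a$fact_ref))
  })
  if (length(consequent) == 0L) {
    stop("rule ", rule_id, ": consequent must assert at least one fact",
         call. = FALSE)
  }
  consequent <- lapply(consequent, function(a) {
    if (!all(c("type", "value") %in% names(a))) {
      stop("rule ", rule_id, ": assertion lacks type/value", call. = FALSE)
    }
    lapply(a, .fact_scalar)
  })
  if (is.na(weight) || weight < 0) {
    stop("rule ", rule_id, ": weight must be >= 0", call. = FALSE)
  }
  structure(list(rule_id = as.character(rule_id),
                 coding_item = as.character(coding_item),
                 antecedents = antecedents, consequent = consequent,
                 weight = as.numeric(weight)),
            class = "regcode_rule")
}

#' @export
print.regcode_rule <- function(x, ...) {
  ants <- vapply(x$antecedents, function(a) {
    sym <- c(eq = "=", ne = "!=", ge = ">=", le = "<=", present = "?")[[a$op]]
    ref <- if (is.na(a$fact_ref)) "" else paste0(a$fact_ref, ".")
    if (a$op == "present") paste0(ref, a$attribute, "?")
    else paste0(ref, a$attribute, sym, "'", a$value, "'")
  }, character(1))
  cons <- vapply(x$consequent, function(a) {
    paste0("{", paste(names(a), unlist(a), sep = "=", collapse = ", "), "}")
  }, character(1))
  cat(sprintf("<rule %s [%s] w=%.3g>\n  IF   %s\n  THEN %s\n",
              x$rule_id, x$coding_item, x$weight,
              paste(ants, collapse = " AND "), paste(cons, collapse = " AND ")))
  invisible(x)
}

#' Read a rule base from JSON
#'
#' The file is a JSON array of rule objects with keys `rule_id`,
#' `coding_item`, `antecedents`, `consequent` and optional `weight`.
#'
#' @param path JSON file path.
#' @return List of [rule()] objects.
#' @export
read_rules <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    rule(rule_id = r$rule_id, coding_item = r$coding_item,
         antecedents = r$antecedents, consequent = r$consequent,
         weight = if (is.null(r$weight)) 1 else r$weight)
  })
}

#' Write a rule base to JSON
#'
#' @param rules List of [rule()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  out <- lapply(rules, function(r) {
    list(rule_id = r$rule_id, coding_item = r$coding_item,
         antecedents = lapply(r$antecedents, function(a) {
           a[!vapply(a, function(v) is.na(v) || is.null(v), logical(1))]
         }),
         consequent = r$consequent, weight = r$weight)
  })
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' The worked-example Diagnosis-section rule
#'
#' A primary-site/laterality rule whose antecedents require a concept described
#' under the "Diagnosis" section that co-occurs with a histology concept in the
#' same sentence; firing asserts `PRIMARY_SITE_CODING = "C341"` (left upper
#' lobe of lung, ICD-O-3) and `LATERALITY_CODING = "2"` (left).
#'
#' @return A single [rule()].
#' @export
worked_example_rule <- function() {
  rule(
    rule_id = "primary-site-diagnosis-cooccur",
    coding_item = "Primary Site",
    antecedents = list(
      list(attribute = "section", op = "eq", value = "Diagnosis"),
      list(attribute = "cooccurHistology", op = "eq", value = TRUE)
    ),
    consequent = list(
      list(type = "PRIMARY_SITE_CODING", value = "C341"),
      list(type = "LATERALITY_CODING", value = "2")
    )
  )
}
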