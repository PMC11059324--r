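# Facts are flat named lists of scalar attributes ("type" always present).
# The fact database has set semantics: two facts are the same fact iff their
# attribute maps are equal, which the canonical key below encodes.

.fact_scalar <- function(v) {
  if (inherits(v, "Date")) return(as.character(v))
  if (is.logical(v)) return(ifelse(v, "TRUE", "FALSE"))
  if (is.numeric(v)) {
    # canonical numeric printing so 6 and 6.0 are one fact
    return(format(v, trim = TRUE, scientific = FALSE, drop0trailing = TRUE))
  }
  as.character(v)
}

#' Construct a fact
#'
#' A fact is an attribute-value record in the engine's working memory, e.g.
#' `fact(type = "PrimarySiteLaterality", UMLS = "C1261076", section = "Diagnosis")`.
#' All values are stored as canonical scalar strings; the `type` attribute is
#' mandatory.
#'
#' @param ... Named scalar attributes; `type` is required.
#' @return A named character vector of class `regcode_fact`.
#' @export
fact <- function(...) {
  attrs <- list(...)
  if (length(attrs) == 1L && is.null(names(attrs)) && is.list(attrs[[1]])) {
    attrs <- attrs[[1]]
  }
  if (is.null(names(attrs)) || any(!nzchar(names(attrs)))) {
    stop("all fact attributes must be named", call. = FALSE)
  }
  if (!"type" %in% names(attrs)) stop("fact lacks a 'type' attribute", call. = FALSE)
  vals <- vapply(attrs, .fact_scalar, character(1))
  structure(vals, class = "regcode_fact")
}

fact_key <- function(f) {
  nm <- sort(names(f))
  paste(nm, unclass(f)[nm], sep = "\x1f", collapse = "\x1e")
}

#' Create an empty fact database
#'
#' Working memory of the expert system: a set of facts plus provenance (which
#' rules asserted each fact, or `"observed"`) and the earliest supporting
#' report date seen for it (used only for deterministic tie-breaking).
#'
#' @param facts Optional list of [fact()] objects to seed as observed facts.
#' @return An object of class `regcode_factdb`.
#' @export
fact_db <- function(facts = list()) {
  db <- structure(
    list(facts = list(), prov = list(), support_date = list(), by_type = list()),
    class = "regcode_factdb"
  )
  for (f in facts) db <- db_add(db, f, source = "observed")
  db
}

#' Add a fact to a database
#'
#' Re-asserting an existing fact is a no-op apart from provenance/date merging.
#'
#' @param db A [fact_db()].
#' @param f A [fact()].
#' @param source `"observed"` or a rule id.
#' @param support_date Optional ISO date string backing the assertion.
#' @return The updated database.
#' @export
db_add <- function(db, f, source = "observed", support_date = NA_character_) {
  key <- fact_key(f)
  fresh <- is.null(db$facts[[key]])
  if (fresh) {
    db$facts[[key]] <- f
    ty <- unname(f[["type"]])
    db$by_type[[ty]] <- c(db$by_type[[ty]], key)
    db$prov[[key]] <- character(0)
    db$support_date[[key]] <- NA_character_
  }
  db$prov[[key]] <- union(db$prov[[key]], source)
  old <- db$support_date[[key]]
  if (!is.na(support_date) && (is.na(old) || support_date < old)) {
    db$support_date[[key]] <- support_date
  }
  attr(db, "added") <- fresh
  db
}

db_size <- function(db) length(db$facts)

db_facts_of_type <- function(db, type) {
  keys <- db$by_type[[type]]
  if (is.null(keys)) return(list())
  db$facts[keys]
}

#' @export
print.regcode_factdb <- function(x, ...) {
  cat(sprintf("<fact database: %d facts, %d types>\n",
              length(x$facts), length(x$by_type)))
  invisible(x)
}

#' Facts as a tibble
#'
#' Long view of the database for inspection: one row per attribute.
#'
#' @param db A [fact_db()].
#' @return Tibble with columns `fact`, `attribute`, `value`.
#' @export
facts_as_tibble <- function(db) {
  keys <- names(db$facts)
  rows <- lapply(seq_along(keys), function(i) {
    f <- db$facts[[i]]
    tibble::tibble(fact = i, attribute = names(f), value = unname(unclass(f)))
  })
  if (!length(rows)) {
    return(tibble::tibble(fact = integer(), attribute = character(),
                          value = character()))
  }
  do.call(rbind, rows)
}
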