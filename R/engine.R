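# Forward-chaining inference over the fact database, and per-item code
# selection by highest rule weight.

# warning-free numeric parse (NA when the string is not a plain number)
.as_num <- function(x) {
  if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)$", x)) as.numeric(x) else NA_real_
}

#' Match one antecedent against one fact
#'
#' True iff the fact carries the attribute and the operator holds. An absent
#' attribute never matches (including under `present`, which is the existence
#' test itself). `ge`/`le` compare numerically, or as ISO date strings when
#' both sides look like dates; anything else is a type error.
#'
#' @param antecedent An antecedent list (`attribute`, `op`, `value`).
#' @param f A [fact()].
#' @return Logical scalar.
#' @export
matches <- function(antecedent, f) {
  a <- antecedent$attribute
  if (!a %in% names(f)) return(FALSE)
  got <- unclass(f)[[a]]
  if (antecedent$op == "present") return(TRUE)
  want <- antecedent$value
  if (antecedent$op %in% c("eq", "ne")) {
    same <- identical(got, want)
    if (!same) {
      gn <- .as_num(got)
      if (!is.na(gn)) {
        wn <- .as_num(want)
        same <- !is.na(wn) && gn == wn
      }
    }
    return(if (antecedent$op == "eq") same else !same)
  }
  # ge / le
  gn <- .as_num(got)
  wn <- .as_num(want)
  if (is.na(gn) || is.na(wn)) {
    iso <- "^\\d{4}-\\d{2}-\\d{2}$"
    if (grepl(iso, got) && grepl(iso, want)) {
      gn <- as.numeric(as.Date(got)); wn <- as.numeric(as.Date(want))
    } else {
      stop("operator '", antecedent$op, "' on non-comparable attribute '",
           a, "' (value '", got, "')", call. = FALSE)
    }
  }
  if (antecedent$op == "ge") gn >= wn else gn <= wn
}

# For each binding group of a rule (antecedents sharing a fact_ref, or an
# anonymous singleton group) return the facts satisfying every condition of
# the group; NULL if some group is unsatisfiable.
.rule_bindings <- function(r, db) {
  groups <- list()
  for (a in r$antecedents) {
    key <- if (is.na(a$fact_ref)) paste0(".anon", length(groups) + 1L) else a$fact_ref
    groups[[key]] <- c(groups[[key]], list(a))
  }
  out <- list()
  for (key in names(groups)) {
    conds <- groups[[key]]
    # narrow candidates through a type-eq condition when available
    ty <- NULL
    for (a in conds) {
      if (a$attribute == "type" && a$op == "eq") { ty <- a$value; break }
    }
    cand <- if (is.null(ty)) db$facts else db_facts_of_type(db, ty)
    sat <- Filter(function(f) all(vapply(conds, matches, logical(1), f = f)), cand)
    if (length(sat) == 0L) return(NULL)
    out[[key]] <- sat
  }
  out
}

.min_date <- function(facts) {
  d <- unlist(lapply(facts, function(f) {
    if ("date" %in% names(f)) unclass(f)[["date"]] else NULL
  }))
  if (is.null(d) || !length(d)) NA_character_ else min(d)
}

#' Fire one rule against a database
#'
#' The rule fires iff every binding group is satisfied by at least one fact
#' (antecedents without a shared `fact_ref` may each bind a different fact).
#' Assertion values of the form `"@R.attr"` are instantiated once per fact
#' bound to reference `R`, so a rule over, say, a node-count fact emits one
#' coding fact per distinct observed count.
#'
#' @param r A [rule()].
#' @param db A [fact_db()].
#' @return A list of firings, each `list(fact = <fact>, support_date = <chr>)`;
#'   empty list when the rule does not fire.
#' @export
fire <- function(r, db) {
  bindings <- .rule_bindings(r, db)
  if (is.null(bindings)) return(list())
  all_support <- .min_date(unlist(unname(bindings), recursive = FALSE))

  refs_used <- unique(unlist(lapply(r$consequent, function(a) {
    hits <- regmatches(unlist(a), regexpr("^@[^.]+\\.", unlist(a)))
    if (!length(hits)) character(0) else sub("^@", "", sub("\\.$", "", hits))
  })))
  refs_used <- refs_used[refs_used %in% names(bindings)]

  instantiate <- function(binding) {
    lapply(r$consequent, function(a) {
      vals <- lapply(a, function(v) {
        if (grepl("^@[^.]+\\.", v)) {
          ref <- sub("^@([^.]+)\\..*$", "\\1", v)
          at <- sub("^@[^.]+\\.", "", v)
          bf <- binding[[ref]]
          if (is.null(bf) || !at %in% names(bf)) return(NULL)
          unclass(bf)[[at]]
        } else v
      })
      vals <- vals[!vapply(vals, is.null, logical(1))]
      fact(vals)
    })
  }

  if (length(refs_used) == 0L) {
    facts <- instantiate(list())
    return(lapply(facts, function(f) list(fact = f, support_date = all_support)))
  }
  combos <- expand.grid(lapply(refs_used, function(ref)
    seq_along(bindings[[ref]])), KEEP.OUT.ATTRS = FALSE)
  names(combos) <- refs_used
  out <- list()
  for (i in seq_len(nrow(combos))) {
    binding <- lapply(refs_used, function(ref) bindings[[ref]][[combos[i, ref]]])
    names(binding) <- refs_used
    sd <- .min_date(binding)
    if (is.na(sd)) sd <- all_support
    for (f in instantiate(binding)) {
      out[[length(out) + 1L]] <- list(fact = f, support_date = sd)
    }
  }
  out
}

#' Forward-chain a rule base to its fixpoint
#'
#' Repeated sweeps over all rules add asserted facts (set semantics) until a
#' sweep adds nothing. The result is the least fixpoint and is independent of
#' rule order; a sweep-count guard turns a (theoretically impossible) runaway
#' derivation into an internal error rather than a hang.
#'
#' @param db A [fact_db()] of observed facts.
#' @param rules List of [rule()] objects.
#' @return The saturated [fact_db()], with per-fact rule provenance.
#' @export
forward_chain <- function(db, rules) {
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    if (sweeps > length(rules) * 50L + db_size(db) + 10L) {
      stop("forward chaining failed to reach a fixpoint (internal error)",
           call. = FALSE)
    }
    added <- FALSE
    for (r in rules) {
      for (hit in fire(r, db)) {
        db <- db_add(db, hit$fact, source = r$rule_id,
                     support_date = hit$support_date)
        if (isTRUE(attr(db, "added"))) added <- TRUE
      }
    }
    if (!added) break
  }
  attr(db, "sweeps") <- sweeps
  db
}

#' Infer registry codes for one patient's facts
#'
#' Runs [forward_chain()], then for each configured item collects all asserted
#' `*_CODING` facts, groups them by code value, scores each value by the
#' maximum (or, optionally, sum) of the weights of the rules that asserted it,
#' and ranks descending. Ties break on earlier supporting report date, then
#' lexicographically smaller code. Items with no asserted code select the
#' sentinel `"NOT_CODED"`.
#'
#' @param journey_facts A [fact_db()] of observed facts for one patient.
#' @param rules List of [rule()] objects carrying weights.
#' @param patient_id Patient identifier stamped onto the result.
#' @param items Items to report (default the 30 shipped items).
#' @param aggregate `"max"` (default) or `"sum"` over asserting-rule weights.
#' @return Tibble with one row per item: `patient_id`, `item`, `selected`,
#'   `n_candidates`, and a `candidates` list-column of tibbles
#'   (`value`, `weight`, `rules`, `support_date`) sorted by rank.
#' @export
infer_codes <- function(journey_facts, rules, patient_id = NA_character_,
                        items = registry_items(),
                        aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  db <- forward_chain(journey_facts, rules)
  wmap <- stats::setNames(vapply(rules, function(r) r$weight, numeric(1)),
                          vapply(rules, function(r) r$rule_id, character(1)))
  new_tbl <- function(cols) {
    tibble::new_tibble(cols, nrow = length(cols[[1L]]))
  }
  empty_cand <- tibble::tibble(value = character(), weight = numeric(),
                               rules = list(), support_date = character())
  selected <- character(length(items))
  n_cand <- integer(length(items))
  cand_list <- vector("list", length(items))
  for (ii in seq_along(items)) {
    keys <- db$by_type[[item_coding_type(items[ii])]]
    if (is.null(keys) || !length(keys)) {
      selected[ii] <- "NOT_CODED"; n_cand[ii] <- 0L
      cand_list[[ii]] <- empty_cand
      next
    }
    vals <- vapply(keys, function(k) unclass(db$facts[[k]])[["value"]], character(1))
    uv <- unique(vals)
    weight <- numeric(length(uv)); sdate <- character(length(uv))
    rids_l <- vector("list", length(uv))
    for (vi in seq_along(uv)) {
      ks <- keys[vals == uv[vi]]
      rids <- setdiff(unique(unlist(db$prov[ks], use.names = FALSE)), "observed")
      w <- wmap[rids]
      w <- w[!is.na(w)]
      weight[vi] <- if (!length(w)) 0 else if (aggregate == "max") max(w) else sum(w)
      sd <- unlist(db$support_date[ks], use.names = FALSE)
      sd <- sd[!is.na(sd)]
      sdate[vi] <- if (length(sd)) min(sd) else NA_character_
      rids_l[[vi]] <- rids
    }
    ord <- order(-weight, ifelse(is.na(sdate), "9999-12-31", sdate), uv)
    cand_list[[ii]] <- new_tbl(list(value = uv[ord], weight = weight[ord],
                                    rules = rids_l[ord],
                                    support_date = sdate[ord]))
    selected[ii] <- uv[ord][1L]
    n_cand[ii] <- length(uv)
  }
  new_tbl(list(patient_id = rep(patient_id, length(items)), item = items,
               selected = selected, n_candidates = n_cand,
               candidates = cand_list))
}

#' Code a whole cohort of journeys
#'
#' Convenience wrapper: extract facts per journey, infer codes, bind rows.
#'
#' @param journeys List of [journey()] objects.
#' @param rules Rule base.
#' @param dictionary Dictionary tibble.
#' @param section_lexicon Heading vector.
#' @param pattern_set Numeric patterns (or `NULL`).
#' @inheritParams infer_codes
#' @return Long tibble of [infer_codes()] rows for every patient.
#' @export
code_cohort <- function(journeys, rules, dictionary, section_lexicon,
                        pattern_set = numeric_patterns(),
                        items = registry_items(),
                        aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  dictionary <- compile_dictionary(dictionary)
  out <- lapply(journeys, function(j) {
    db <- extract_journey_facts(j, dictionary, section_lexicon, pattern_set)
    infer_codes(db, rules, patient_id = j$patient_id, items = items,
                aggregate = aggregate)
  })
  do.call(rbind, out)
}
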