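# Rule-weight estimation from coded training journeys.
#
# Per coding item, the rule base induces a directed graph whose vertices are
# rule antecedents and consequences (plus one non-match twin per consequence,
# written with a '-' prefix). A co-occurrence matrix B counts, over training
# records, (i) antecedent pairs jointly matched by the facts and (ii)
# antecedent -> consequence events split by agreement with the gold code.
# Row-normalising B gives the adjacency matrix A, and a one-hop message-
# passing sum over in-neighbours yields vertex weights, which become the rule
# weights.

.op_symbol <- c(eq = "=", ne = "!=", ge = ">=", le = "<=", present = "?")

antecedent_label <- function(a) {
  if (a$attribute == "type" && a$op == "eq") return(a$value)
  if (a$op == "present") return(paste0(a$attribute, "?"))
  paste0(a$attribute, .op_symbol[[a$op]], a$value)
}

assertion_label <- function(a) {
  if (grepl("_CODING$", a$type)) paste0(a$type, "=", a$value) else a$type
}

# Rules participating in the graph of one coding item: rules asserting that
# item's coding fact type, plus (transitively) intermediate rules whose
# asserted fact type appears among the antecedents of rules already included.
rules_for_coding_type <- function(rules, item) {
  target <- item_coding_type(item)
  asserts_type <- function(r, ty) {
    any(vapply(r$consequent, function(a) a$type == ty, logical(1)))
  }
  included <- vapply(rules, asserts_type, logical(1), ty = target)
  repeat {
    needed <- unique(unlist(lapply(rules[included], function(r) {
      vapply(Filter(function(a) a$attribute == "type" && a$op == "eq",
                    r$antecedents),
             function(a) a$value, character(1))
    })))
    add <- vapply(rules, function(r) {
      any(vapply(r$consequent,
                 function(a) !grepl("_CODING$", a$type) && a$type %in% needed,
                 logical(1)))
    }, logical(1)) & !included
    if (!any(add)) break
    included <- included | add
  }
  rules[included]
}

#' Build the per-item rule graph skeleton
#'
#' Bidirectional edges join every within-rule antecedent pair; each antecedent
#' additionally points at each of the rule's consequences and at the
#' consequence's non-match twin. Vertices are deduplicated across rules, and a
#' consequence that also serves as an antecedent elsewhere (an intermediate
#' fact) is a single shared vertex. Non-match vertices have no outgoing edges.
#'
#' @param rules Rules of one coding item (see [rules_for_coding_type()]).
#' @param coding_type The registry item the graph is for.
#' @return Object of class `regcode_rulegraph`: vertex labels (antecedents
#'   first, then consequences, then non-match twins), edge matrix, zeroed
#'   co-occurrence matrix `B`, and per-rule label bookkeeping.
#' @export
build_skeleton <- function(rules, coding_type = NA_character_) {
  if (!length(rules)) stop("no rules for coding type ", coding_type, call. = FALSE)
  per_rule <- lapply(rules, function(r) {
    if (!length(r$antecedents)) {
      stop("rule ", r$rule_id, " has no antecedents", call. = FALSE)
    }
    list(rule_id = r$rule_id,
         ants = unique(vapply(r$antecedents, antecedent_label, character(1))),
         cons = unique(vapply(r$consequent, assertion_label, character(1))),
         rule = r)
  })
  ant_labels <- unique(unlist(lapply(per_rule, `[[`, "ants")))
  con_labels <- unique(unlist(lapply(per_rule, `[[`, "cons")))
  nonmatch <- paste0("-", con_labels)
  vertices <- c(setdiff(ant_labels, con_labels), con_labels, nonmatch)
  n <- length(vertices)
  E <- matrix(FALSE, n, n, dimnames = list(vertices, vertices))
  for (pr in per_rule) {
    if (length(pr$ants) > 1L) {
      for (i in pr$ants) for (j in pr$ants) if (i != j) E[i, j] <- TRUE
    }
    for (i in pr$ants) for (k in pr$cons) {
      E[i, k] <- TRUE
      E[i, paste0("-", k)] <- TRUE
    }
  }
  B <- matrix(0, n, n, dimnames = list(vertices, vertices))
  structure(
    list(coding_type = coding_type, vertices = vertices,
         consequences = con_labels, nonmatch = nonmatch,
         edges = E, B = B, A = NULL,
         w = stats::setNames(rep(0, n), vertices),
         per_rule = per_rule),
    class = "regcode_rulegraph"
  )
}

#' @export
print.regcode_rulegraph <- function(x, ...) {
  cat(sprintf("<rule graph '%s': %d vertices (%d consequences), %d edges>\n",
              x$coding_type, length(x$vertices), length(x$consequences),
              sum(x$edges)))
  invisible(x)
}

#' In-neighbourhood of a vertex
#'
#' The vertices with an edge into `v`; non-match vertices never appear (they
#' have no outgoing edges).
#'
#' @param graph A rule graph.
#' @param v Vertex label.
#' @return Character vector of neighbour labels.
#' @export
neighborhood <- function(graph, v) {
  rownames(graph$edges)[graph$edges[, v]]
}

#' Accumulate the co-occurrence matrix from training records
#'
#' For each training record (one patient journey's facts plus that patient's
#' gold codes): every within-rule antecedent pair with both antecedents
#' individually matched in the chained fact database increments `B[i,j]` and
#' `B[j,i]` (once per distinct vertex pair per record); every fired rule
#' increments each antecedent's cell toward the consequence when the asserted
#' code agrees with the gold code for the graph's coding item, and toward the
#' non-match twin when it disagrees. Intermediate consequences have no gold
#' code to disagree with, so a fired intermediate rule always counts toward
#' its consequence vertex. Records without a gold value for the coding item
#' are skipped. Counts accumulate across calls.
#'
#' @param graph A rule graph from [build_skeleton()].
#' @param training List of records, each `list(facts = <fact_db or list of
#'   facts>, gold = <named character vector: item -> code>)`.
#' @return The graph with `B` updated.
#' @export
accumulate_cooccurrence <- function(graph, training) {
  target_type <- item_coding_type(graph$coding_type)
  rule_objs <- lapply(graph$per_rule, `[[`, "rule")
  for (rec in training) {
    gold <- rec$gold
    if (!graph$coding_type %in% names(gold)) next
    gold_code <- .fact_scalar(gold[[graph$coding_type]])
    db <- if (inherits(rec$facts, "regcode_factdb")) rec$facts else fact_db(rec$facts)
    db <- forward_chain(db, rule_objs)

    pair_seen <- character(0)
    for (pr in graph$per_rule) {
      r <- pr$rule
      ant_labels <- vapply(r$antecedents, antecedent_label, character(1))
      matched <- vapply(r$antecedents, function(a) {
        ty <- if (a$attribute == "type" && a$op == "eq") a$value else NULL
        cand <- if (is.null(ty)) db$facts else db_facts_of_type(db, ty)
        any(vapply(cand, function(f) matches(a, f), logical(1)))
      }, logical(1))
      mlab <- unique(ant_labels[matched])
      if (length(mlab) > 1L) {
        for (i in seq_along(mlab)) for (j in seq_along(mlab)) {
          if (i >= j) next
          key <- paste(sort(c(mlab[i], mlab[j])), collapse = "\x1f")
          if (key %in% pair_seen) next
          pair_seen <- c(pair_seen, key)
          graph$B[mlab[i], mlab[j]] <- graph$B[mlab[i], mlab[j]] + 1
          graph$B[mlab[j], mlab[i]] <- graph$B[mlab[j], mlab[i]] + 1
        }
      }

      # consequence counting for fired rules
      firings <- fire(r, db)
      if (!length(firings)) next
      handled <- character(0)
      for (hit in firings) {
        f <- hit$fact
        ty <- unclass(f)[["type"]]
        if (ty == target_type) {
          k <- assertion_label(.template_for(r, f))
          col <- if (identical(unclass(f)[["value"]], gold_code)) k else paste0("-", k)
          for (i in unique(ant_labels)) {
            graph$B[i, col] <- graph$B[i, col] + 1
          }
        } else if (!grepl("_CODING$", ty) && !(ty %in% handled)) {
          handled <- c(handled, ty)
          if (ty %in% colnames(graph$B)) {
            for (i in unique(ant_labels)) {
              graph$B[i, ty] <- graph$B[i, ty] + 1
            }
          }
        }
      }
    }
  }
  graph
}

# Map an instantiated asserted fact back to the rule's assertion template whose
# label names the consequence vertex (needed when values are "@ref.attr").
.template_for <- function(r, f) {
  ty <- unclass(f)[["type"]]
  for (a in r$consequent) {
    if (a$type == ty) return(a)
  }
  stop("asserted fact type '", ty, "' not found among consequents of rule ",
       r$rule_id, " (internal error)", call. = FALSE)
}

#' Compute the row-normalised adjacency matrix
#'
#' With `q_i` the i-th row sum of `B`: `A[i,j]` is 0 on the diagonal when
#' `q_i != 0`, 1 on the diagonal when `q_i == 0`, and `B[i,j]/q_i` otherwise.
#' Rows with positive mass are therefore probability vectors over `j != i`.
#'
#' @param graph Graph with `B` accumulated.
#' @return The graph with `A` filled in.
#' @export
compute_adjacency <- function(graph) {
  B <- graph$B
  q <- rowSums(B)
  A <- B
  pos <- q > 0
  A[pos, ] <- B[pos, , drop = FALSE] / q[pos]
  A[!pos, ] <- 0
  diag(A)[pos] <- 0
  diag(A)[!pos] <- 1
  graph$A <- A
  graph
}

#' Message passing over the rule graph
#'
#' One phase applies the literal update `w_i = sum over in-neighbours j of
#' A[j, i]`. Additional phases (exposed for exploration) re-aggregate using
#' the previous weights normalised to sum 1:
#' `w_i <- sum_j A[j, i] * w_j / sum(w)`.
#'
#' @param graph Graph with `A` computed.
#' @param phases Number of passes (default 1, the literal update).
#' @return The graph with vertex weights `w` set.
#' @export
message_pass <- function(graph, phases = 1L) {
  if (is.null(graph$A)) stop("adjacency matrix not computed", call. = FALSE)
  AE <- graph$A * graph$edges  # contributions only along existing edges j -> i
  w <- colSums(AE)
  if (phases > 1L) {
    for (p in seq_len(phases - 1L)) {
      s <- sum(w)
      wn <- if (s > 0) w / s else w
      w <- as.numeric(crossprod(AE, wn))
      names(w) <- graph$vertices
    }
  }
  graph$w <- stats::setNames(as.numeric(w), graph$vertices)
  graph
}

#' Copy learned vertex weights onto rules
#'
#' Each rule's weight becomes the weight of its consequence vertex in this
#' graph (for rules asserting the graph's coding type, the coding vertex;
#' for intermediate rules, the intermediate vertex). Rules not represented in
#' the graph are returned unchanged; list order is preserved.
#'
#' @param graph Graph after [message_pass()].
#' @param rules Full ordered rule list.
#' @return The rule list with updated weights.
#' @export
assign_rule_weights <- function(graph, rules) {
  target_type <- item_coding_type(graph$coding_type)
  in_graph <- stats::setNames(
    lapply(graph$per_rule, `[[`, "cons"),
    vapply(graph$per_rule, `[[`, "rule_id", FUN.VALUE = character(1)))
  lapply(rules, function(r) {
    cons <- in_graph[[r$rule_id]]
    if (is.null(cons)) return(r)
    # the vertex of the assertion targeting this graph's coding type, else the
    # rule's (intermediate) consequence vertex
    own <- cons[grepl(paste0("^", target_type, "="), cons)]
    v <- if (length(own)) own else cons
    missing <- setdiff(v, names(graph$w))
    if (length(missing)) {
      stop("consequence vertex '", missing[1L], "' missing from graph (internal error)",
           call. = FALSE)
    }
    r$weight <- max(graph$w[v])
    r
  })
}

#' Learn rule weights over all coding items
#'
#' Builds one graph per item that has rules, accumulates co-occurrence counts
#' from the training records, computes adjacency and message passing, and
#' writes each rule's learned weight back. A rule asserting codes for several
#' items receives the maximum of its per-graph vertex weights; rules whose
#' consequences never co-occur with matching gold codes end up with weight 0.
#'
#' @param rules Full rule list.
#' @param training Training records as in [accumulate_cooccurrence()].
#' @param items Items to learn over (default all shipped items).
#' @param phases Message-passing phases (default 1).
#' @return List with `rules` (reweighted, original order) and `graphs`
#'   (named per-item list of fitted graphs).
#' @export
learn_weights <- function(rules, training, items = registry_items(),
                          phases = 1L) {
  ids <- vapply(rules, function(r) r$rule_id, character(1))
  weights <- stats::setNames(rep(NA_real_, length(rules)), ids)
  graphs <- list()
  for (item in items) {
    sub <- rules_for_coding_type(rules, item)
    if (!length(sub)) next
    g <- build_skeleton(sub, coding_type = item)
    g <- accumulate_cooccurrence(g, training)
    g <- compute_adjacency(g)
    g <- message_pass(g, phases = phases)
    graphs[[item]] <- g
    reweighted <- assign_rule_weights(g, sub)
    for (r in reweighted) {
      cur <- weights[[r$rule_id]]
      weights[[r$rule_id]] <- if (is.na(cur)) r$weight else max(cur, r$weight)
    }
  }
  rules <- lapply(rules, function(r) {
    w <- weights[[r$rule_id]]
    if (!is.na(w)) r$weight <- w
    r
  })
  list(rules = rules, graphs = graphs)
}

#' Build training records from journeys and gold codes
#'
#' @param journeys List of [journey()] objects.
#' @param gold Long gold tibble (`patient_id`, `item`, `code`), see
#'   [read_gold()].
#' @param dictionary,section_lexicon,pattern_set Extraction configuration.
#' @param scope `"journey"` (one record per patient, the default) or
#'   `"report"` (one record per report, sharing the patient's gold codes).
#' @return List of `list(facts, gold)` records.
#' @export
prepare_training <- function(journeys, gold, dictionary, section_lexicon,
                             pattern_set = numeric_patterns(),
                             scope = c("journey", "report")) {
  scope <- match.arg(scope)
  dictionary <- compile_dictionary(dictionary)
  lapply_flat <- function(x, f) do.call(c, lapply(x, f))
  gold_for <- function(pid) {
    rows <- gold[gold$patient_id == pid & !is.na(gold$code) & nzchar(gold$code), ]
    stats::setNames(rows$code, rows$item)
  }
  if (scope == "journey") {
    lapply(journeys, function(j) {
      list(facts = extract_journey_facts(j, dictionary, section_lexicon,
                                         pattern_set),
           gold = gold_for(j$patient_id))
    })
  } else {
    lapply_flat(journeys, function(j) {
      g <- gold_for(j$patient_id)
      lapply(j$reports, function(r) {
        jr <- journey(j$patient_id, list(r))
        list(facts = extract_journey_facts(jr, dictionary, section_lexicon,
                                           pattern_set),
             gold = g)
      })
    })
  }
}

#' Serialize a fitted rule graph to JSON for audit
#'
#' @param graph A fitted rule graph.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  idx <- which(graph$edges, arr.ind = TRUE)
  edges <- lapply(seq_len(nrow(idx)), function(k) {
    c(graph$vertices[idx[k, 1L]], graph$vertices[idx[k, 2L]])
  })
  out <- list(coding_type = graph$coding_type, vertices = graph$vertices,
              consequences = graph$consequences, edges = edges,
              B = unname(apply(graph$B, 1L, as.numeric, simplify = FALSE)),
              A = if (is.null(graph$A)) NULL else
                unname(apply(graph$A, 1L, as.numeric, simplify = FALSE)),
              w = as.list(graph$w))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
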