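# Independent brute-force oracles. These deliberately re-derive results with
# the most literal possible implementations (repeated-scan closure, explicit
# pair enumeration, per-patient double loops) and share no code with the
# package internals they check.

# naive closure of a propositional base: repeatedly scan rules, adding the
# consequence type whenever all antecedent types are present
oracle_closure <- function(observed, rules) {
  known <- unique(observed)
  repeat {
    grew <- FALSE
    for (r in rules) {
      ants <- vapply(r$antecedents, function(a) a$value, character(1))
      if (all(ants %in% known)) {
        con <- r$consequent[[1]]$type
        if (!con %in% known) {
          known <- c(known, con)
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  sort(known)
}

# literal co-occurrence counting for propositional bases (single coding item):
# every quantity is recomputed from first principles with explicit loops.
# Records: list(list(observed = letters, gold = code)). Returns B, A, w over
# the same vertex labelling build_skeleton() uses.
oracle_graph <- function(rules, records, item) {
  target <- item_coding_type(item)
  ant_of <- function(r) vapply(r$antecedents, function(a) a$value, character(1))
  con_of <- function(r) {
    a <- r$consequent[[1]]
    if (a$type == target) paste0(a$type, "=", a$value) else a$type
  }
  ants <- unique(unlist(lapply(rules, ant_of)))
  cons <- unique(vapply(rules, con_of, character(1)))
  verts <- c(setdiff(ants, cons), cons, paste0("-", cons))
  n <- length(verts)
  B <- matrix(0, n, n, dimnames = list(verts, verts))
  E <- matrix(FALSE, n, n, dimnames = list(verts, verts))
  for (r in rules) {
    a <- unique(ant_of(r)); k <- con_of(r)
    if (length(a) > 1) {
      for (x in a) for (y in a) if (x != y) E[x, y] <- TRUE
    }
    for (x in a) { E[x, k] <- TRUE; E[x, paste0("-", k)] <- TRUE }
  }
  for (rec in records) {
    # closure, so intermediate facts count as observed
    known <- oracle_closure(rec$observed, rules)
    seen_pairs <- character(0)
    for (r in rules) {
      a <- unique(ant_of(r))
      m <- a[a %in% known]
      if (length(m) > 1) {
        for (x in m) for (y in m) {
          if (x >= y) next
          key <- paste(x, y)
          if (key %in% seen_pairs) next
          seen_pairs <- c(seen_pairs, key)
          B[x, y] <- B[x, y] + 1
          B[y, x] <- B[y, x] + 1
        }
      }
      if (all(a %in% known)) { # rule fired
        k <- con_of(r)
        asrt <- r$consequent[[1]]
        if (asrt$type == target) {
          col <- if (identical(asrt$value, rec$gold)) k else paste0("-", k)
        } else {
          col <- k
        }
        for (x in a) B[x, col] <- B[x, col] + 1
      }
    }
  }
  A <- matrix(0, n, n, dimnames = list(verts, verts))
  for (i in seq_len(n)) {
    qi <- sum(B[i, ])
    for (j in seq_len(n)) {
      A[i, j] <- if (i == j && qi != 0) 0 else if (i == j && qi == 0) 1
      else B[i, j] / max(qi, 1) * (qi != 0)
    }
  }
  w <- numeric(n); names(w) <- verts
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (E[j, i]) s <- s + A[j, i]
    w[i] <- s
  }
  list(B = B, A = A, w = w, vertices = verts)
}

# per-patient double-loop scoring oracle
oracle_scores <- function(pred, gold, beta = 1) {
  items <- sort(unique(gold$item))
  out <- list()
  for (it in items) {
    tp <- fp <- fn <- 0L
    for (pid in unique(gold$patient_id)) {
      g <- gold$code[gold$patient_id == pid & gold$item == it]
      if (!length(g)) next
      p <- pred$selected[pred$patient_id == pid & pred$item == it]
      if (!length(p)) p <- "NOT_CODED"
      if (p == g) tp <- tp + 1L
      else if (p == "NOT_CODED") fn <- fn + 1L
      else { fp <- fp + 1L; fn <- fn + 1L }
    }
    if (tp + fn == 0L) next
    P <- if (tp + fp == 0) 0 else tp / (tp + fp)
    R <- tp / (tp + fn)
    f <- if (P + R == 0) 0 else (1 + beta^2) * P * R / (beta^2 * P + R)
    out[[it]] <- c(TP = tp, FP = fp, FN = fn, P = P, R = R, F = f)
  }
  out
}
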