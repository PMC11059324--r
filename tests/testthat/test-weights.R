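# Fixture mirroring the three-rule example base: A&B -> C, C&D&E -> F, C&D -> G
# (F and G are codes of one item; C is an intermediate fact).
example_base <- function() {
  list(prule("r1", c("A", "B"), "C"),
       crule("r2", c("C", "D", "E"), "Widget", "F"),
       crule("r3", c("C", "D"), "Widget", "G"))
}
lab <- function(code) paste0("WIDGET_CODING=", code)

test_that("the skeleton reproduces the printed example neighbourhoods", {
  g <- build_skeleton(example_base(), "Widget")
  expect_setequal(neighborhood(g, lab("F")), c("C", "D", "E"))
  expect_setequal(neighborhood(g, "C"), c("A", "B", "D", "E"))
  expect_setequal(neighborhood(g, "A"), "B")
  expect_setequal(neighborhood(g, "D"), c("C", "E"))
  expect_true(all(c("-C", paste0("-", lab("F")), paste0("-", lab("G"))) %in%
                    g$vertices))
  # non-match vertices are sinks: no outgoing edges
  for (nm in g$nonmatch) expect_equal(sum(g$edges[nm, ]), 0L)
})

test_that("a single-antecedent rule produces only consequence edges", {
  g <- build_skeleton(list(prule("r", "X", "Y")), "Widget")
  expect_equal(sum(g$edges), 2L)  # X->Y and X->-Y
  expect_true(g$edges["X", "Y"])
  expect_true(g$edges["X", "-Y"])
})

test_that("skeletons equal a brute-force pairwise construction on random bases", {
  for (seed in 1:20) {
    base <- random_prop_base(seed, n_rules = 8L)
    sub <- rules_for_coding_type(base$rules, base$item)
    if (!length(sub)) next
    g <- build_skeleton(sub, base$item)
    # brute force: enumerate all within-rule pairs independently
    target <- item_coding_type(base$item)
    expect_edges <- matrix(FALSE, length(g$vertices), length(g$vertices),
                           dimnames = list(g$vertices, g$vertices))
    for (r in sub) {
      ants <- unique(vapply(r$antecedents, function(a) a$value, character(1)))
      a1 <- r$consequent[[1]]
      con <- if (a1$type == target) paste0(a1$type, "=", a1$value) else a1$type
      for (x in ants) for (y in ants) if (x != y) expect_edges[x, y] <- TRUE
      for (x in ants) {
        expect_edges[x, con] <- TRUE
        expect_edges[x, paste0("-", con)] <- TRUE
      }
    }
    expect_identical(g$edges, expect_edges, label = paste("seed", seed))
  }
})

test_that("a matching fired rule counts toward the consequence vertex", {
  rules <- list(crule("r", c("A", "B"), "Widget", "F"))
  g <- build_skeleton(rules, "Widget")
  g <- accumulate_cooccurrence(
    g, list(list(facts = lapply(c("A", "B"), pfact), gold = c(Widget = "F"))))
  expect_equal(g$B["A", "B"], 1)
  expect_equal(g$B["B", "A"], 1)
  expect_equal(g$B["A", lab("F")], 1)
  expect_equal(g$B["B", lab("F")], 1)
  expect_equal(sum(g$B[, paste0("-", lab("F"))]), 0)
})

test_that("a disagreeing fired rule counts toward the non-match twin", {
  rules <- list(crule("r", c("A", "B"), "Widget", "F"))
  g <- build_skeleton(rules, "Widget")
  g <- accumulate_cooccurrence(
    g, list(list(facts = lapply(c("A", "B"), pfact), gold = c(Widget = "G"))))
  expect_equal(g$B["A", paste0("-", lab("F"))], 1)
  expect_equal(g$B["B", paste0("-", lab("F"))], 1)
  expect_equal(g$B["A", lab("F")], 0)
  expect_equal(g$B["A", "B"], 1)  # the pair still co-occurred
})

test_that("an empty training stream leaves the counts at zero", {
  g <- accumulate_cooccurrence(build_skeleton(example_base(), "Widget"), list())
  expect_true(all(g$B == 0))
})

test_that("records without a gold code for the item are skipped", {
  rules <- list(crule("r", c("A", "B"), "Widget", "F"))
  g <- build_skeleton(rules, "Widget")
  g <- accumulate_cooccurrence(
    g, list(list(facts = lapply(c("A", "B"), pfact), gold = c(Gadget = "F"))))
  expect_true(all(g$B == 0))
})

test_that("adjacency rows follow the three-case normalisation", {
  g <- build_skeleton(list(prule("r1", c("i", "j"), "k"),
                           prule("r2", c("i", "j"), "m")), "Widget")
  g$B["i", "j"] <- 3; g$B["i", "k"] <- 1
  g <- compute_adjacency(g)
  expect_equal(g$A["i", "j"], 0.75)
  expect_equal(g$A["i", "k"], 0.25)
  expect_equal(g$A["i", "i"], 0)
  # isolated vertex: unit self-loop
  expect_equal(g$A["m", "m"], 1)
  expect_true(all(g$A["m", setdiff(colnames(g$A), "m")] == 0))
})

test_that("adjacency rows with mass are probability vectors", {
  for (seed in 1:25) {
    base <- random_prop_base(seed, n_rules = 6L)
    sub <- rules_for_coding_type(base$rules, base$item)
    if (!length(sub)) next
    g <- build_skeleton(sub, base$item)
    withr::with_seed(seed, {
      mask <- g$edges
      g$B[mask] <- stats::rpois(sum(mask), 2)
    })
    g <- compute_adjacency(g)
    q <- rowSums(g$B)
    for (i in seq_along(q)) {
      if (q[i] > 0) expect_equal(sum(g$A[i, ]), 1, tolerance = 1e-12)
    }
  }
})

test_that("message passing sums incoming adjacency over the neighbourhood", {
  g <- build_skeleton(example_base(), "Widget")
  n <- length(g$vertices)
  withr::with_seed(99, {
    g$B[g$edges] <- sample(1:5, sum(g$edges), replace = TRUE)
  })
  g <- compute_adjacency(g)
  g <- message_pass(g)
  wf <- g$A["C", lab("F")] + g$A["D", lab("F")] + g$A["E", lab("F")]
  expect_equal(unname(g$w[lab("F")]), wf, tolerance = 1e-12)
  # hand sums for every vertex
  for (v in g$vertices) {
    nb <- neighborhood(g, v)
    expect_equal(unname(g$w[v]), sum(g$A[nb, v]), tolerance = 1e-12)
  }
})

test_that("a vertex with no incoming edges has zero weight", {
  g <- build_skeleton(list(prule("r", "X", "Y")), "Widget")
  g <- message_pass(compute_adjacency(g))
  expect_equal(unname(g$w["X"]), 0)
})

test_that("a four-vertex toy matches hand-computed sums", {
  g <- build_skeleton(list(crule("r1", c("P", "Q"), "Widget", "Z")), "Widget")
  # vertices: P, Q, Z-coding, -Z-coding
  g$B["P", "Q"] <- 2; g$B["Q", "P"] <- 2
  g$B["P", lab("Z")] <- 2; g$B["Q", lab("Z")] <- 6
  g <- compute_adjacency(g)
  g <- message_pass(g)
  expect_equal(unname(g$w[lab("Z")]), 2 / 4 + 6 / 8)
  expect_equal(unname(g$w["P"]), 2 / 8)
  expect_equal(unname(g$w["Q"]), 2 / 4)
})

test_that("B, A and w match the brute-force oracle on random streams", {
  for (seed in 1:100) {
    base <- random_prop_base(seed, n_rules = 6L, pool = LETTERS[1:6])
    sub <- rules_for_coding_type(base$rules, base$item)
    if (!length(sub)) next
    records <- withr::with_seed(seed + 5000, {
      lapply(1:8, function(k) {
        list(observed = sample(LETTERS[1:6], sample(2:4, 1)),
             gold = sample(base$codes, 1))
      })
    })
    g <- build_skeleton(sub, base$item)
    g <- accumulate_cooccurrence(g, lapply(records, function(rec)
      list(facts = lapply(rec$observed, pfact),
           gold = stats::setNames(rec$gold, base$item))))
    g <- message_pass(compute_adjacency(g))
    o <- oracle_graph(sub, records, base$item)
    expect_equal(g$B[o$vertices, o$vertices], o$B, tolerance = 1e-12,
                 label = paste("B seed", seed))
    expect_equal(g$A[o$vertices, o$vertices], o$A, tolerance = 1e-12,
                 label = paste("A seed", seed))
    expect_equal(g$w[o$vertices], o$w, tolerance = 1e-12,
                 label = paste("w seed", seed))
  }
})

test_that("scaling all counts leaves adjacency and weights unchanged", {
  g <- build_skeleton(example_base(), "Widget")
  withr::with_seed(3, g$B[g$edges] <- sample(0:4, sum(g$edges), replace = TRUE))
  g1 <- message_pass(compute_adjacency(g))
  g$B <- g$B * 7L
  g2 <- message_pass(compute_adjacency(g))
  expect_equal(g1$A, g2$A, tolerance = 1e-12)
  expect_equal(g1$w, g2$w, tolerance = 1e-12)
})

test_that("an additional gold-matching record never lowers that rule's weight", {
  rules <- list(crule("good", c("A", "B"), "Widget", "F"),
                crule("bad", c("A", "C"), "Widget", "G"))
  recs <- lapply(1:6, function(k)
    list(facts = lapply(c("A", "B", "C"), pfact),
         gold = c(Widget = if (k <= 4) "F" else "G")))
  fit1 <- learn_weights(rules, recs, items = "Widget")
  w1 <- fit1$rules[[1]]$weight
  recs2 <- c(recs, list(list(facts = lapply(c("A", "B"), pfact),
                             gold = c(Widget = "F"))))
  fit2 <- learn_weights(rules, recs2, items = "Widget")
  expect_gte(fit2$rules[[1]]$weight, w1)
})

test_that("rules sharing a consequence vertex receive equal weights", {
  rules <- list(crule("r1", c("A", "B"), "Widget", "F"),
                crule("r2", c("A", "C"), "Widget", "F"))
  recs <- list(list(facts = lapply(c("A", "B", "C"), pfact),
                    gold = c(Widget = "F")))
  fit <- learn_weights(rules, recs, items = "Widget")
  expect_equal(fit$rules[[1]]$weight, fit$rules[[2]]$weight)
})

test_that("example-base rule weights equal their consequence vertex weights", {
  rules <- example_base()
  recs <- lapply(1:5, function(k)
    list(facts = lapply(c("A", "B", "D", "E"), pfact), gold = c(Widget = "F")))
  g <- build_skeleton(rules, "Widget")
  g <- message_pass(compute_adjacency(accumulate_cooccurrence(g, recs)))
  out <- assign_rule_weights(g, rules)
  expect_equal(out[[2]]$weight, unname(g$w[lab("F")]))
  expect_equal(out[[3]]$weight, unname(g$w[lab("G")]))
  expect_equal(out[[1]]$weight, unname(g$w["C"]))
})

test_that("a 9:1 match ratio ranks the majority rule strictly higher", {
  rules <- list(crule("major", c("A", "B"), "Widget", "F"),
                crule("minor", c("A", "C"), "Widget", "G"))
  recs <- lapply(1:10, function(k)
    list(facts = lapply(c("A", "B", "C"), pfact),
         gold = c(Widget = if (k <= 9) "F" else "G")))
  fit <- learn_weights(rules, recs, items = "Widget")
  expect_gt(fit$rules[[1]]$weight, fit$rules[[2]]$weight)
})

test_that("planted reliable rules are ranked first across seeds", {
  # one item, one planted-correct rule vs one distractor rule; the planted
  # rule matches gold in >= 80% of records
  hits <- 0L
  for (seed in 1:20) {
    ok <- withr::with_seed(seed, {
      rules <- list(crule("planted", c("A", "B"), "Widget", "F"),
                    crule("noise", c("A", "C"), "Widget", "G"))
      recs <- lapply(1:25, function(k)
        list(facts = lapply(c("A", "B", "C"), pfact),
             gold = c(Widget = if (stats::runif(1) < 0.85) "F" else "G")))
      fit <- learn_weights(rules, recs, items = "Widget")
      fit$rules[[1]]$weight > fit$rules[[2]]$weight
    })
    hits <- hits + ok
  }
  expect_gte(hits, 19L)
})

test_that("multi-phase message passing is exposed and stays finite", {
  g <- build_skeleton(example_base(), "Widget")
  withr::with_seed(11, g$B[g$edges] <- sample(1:4, sum(g$edges), replace = TRUE))
  g <- compute_adjacency(g)
  g1 <- message_pass(g, phases = 1L)
  g3 <- message_pass(g, phases = 3L)
  expect_true(all(is.finite(g3$w)))
  expect_false(identical(g1$w, g3$w))
})
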