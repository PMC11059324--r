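mk_gold <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    tibble::tibble(patient_id = r[[1]], item = r[[2]], code = r[[3]])))
}

mk_journey <- function(pid, types, dates = NULL) {
  if (is.null(dates)) dates <- sprintf("2019-01-%02d", seq_along(types))
  journey(pid, lapply(seq_along(types), function(k)
    report(paste0(pid, "-r", k), pid, types[k], dates[k], "Body text.")))
}

test_that("cohort filters drop non-lung, sparse and single-type patients", {
  journeys <- list(
    mk_journey("keep1", c("pathology", "image")),
    mk_journey("keep2", c("pathology", "image", "image")),
    mk_journey("colon", c("pathology", "image")),
    mk_journey("single", "pathology"),
    mk_journey("onetype", c("pathology", "pathology", "pathology",
                            "pathology", "pathology")),
    mk_journey("nolung", c("pathology", "image")))
  gold <- mk_gold(
    list("keep1", "Primary Site", "C341"),
    list("keep2", "Primary Site", "C349"),
    list("colon", "Primary Site", "C180"),
    list("single", "Primary Site", "C342"),
    list("onetype", "Primary Site", "C343"),
    list("nolung", "Primary Site", "C509"))
  out <- filter_cohort(journeys, gold)
  kept <- vapply(out$journeys, `[[`, character(1), "patient_id")
  expect_setequal(kept, c("keep1", "keep2"))
  expect_setequal(out$removed$patient_id,
                  c("colon", "single", "onetype", "nolung"))
  expect_equal(out$removed$reason[out$removed$patient_id == "single"],
               "fewer than 2 reports")
  expect_equal(out$removed$reason[out$removed$patient_id == "onetype"],
               "only one report type")
  expect_setequal(out$gold$patient_id, c("keep1", "keep2"))
})

test_that("a six-patient toy loses one patient per filter", {
  journeys <- list(
    mk_journey("a", c("pathology", "image")),
    mk_journey("b", c("pathology", "image")),
    mk_journey("c", c("pathology", "image")),
    mk_journey("d", c("pathology", "image")),
    mk_journey("e", "image"),
    mk_journey("f", c("image", "image")))
  gold <- mk_gold(list("a", "Primary Site", "C341"),
                  list("b", "Primary Site", "C342"),
                  list("c", "Primary Site", "C343"),
                  list("d", "Primary Site", "C155"),  # not lung
                  list("e", "Primary Site", "C341"),  # one report
                  list("f", "Primary Site", "C341")) # one type
  out <- filter_cohort(journeys, gold)
  expect_length(out$journeys, 3L)
  expect_equal(nrow(out$removed), 3L)
})

test_that("patient splits are disjoint, sized by floor, and seed-stable", {
  pats <- sprintf("p%03d", 1:10)
  sp <- split_patients(pats, 0.8, seed = 4)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), pats)
  expect_identical(sp, split_patients(pats, 0.8, seed = 4))
  expect_false(identical(sp$train, split_patients(pats, 0.8, seed = 5)$train))

  big <- sprintf("q%04d", 1:1000)
  for (seed in 1:50) {
    expect_length(split_patients(big, 0.8, seed = seed)$train, 800L)
  }
  expect_error(split_patients("one", 0.8, 1), "at least 2")
  expect_error(split_patients(pats, 1.2, 1), "ratio")
})

test_that("counts force the textbook precision/recall/F values", {
  gold <- do.call(rbind, lapply(1:10, function(k)
    tibble::tibble(patient_id = paste0("p", k), item = "Histology",
                   code = "8140")))
  pred <- tibble::tibble(
    patient_id = paste0("p", 1:10), item = "Histology",
    selected = c(rep("8140", 8), "8070", "NOT_CODED"))
  s <- score_codes(pred, gold)
  expect_equal(s$TP, 8L); expect_equal(s$FP, 1L); expect_equal(s$FN, 2L)
  expect_equal(s$precision, 8 / 9)
  expect_equal(s$recall, 0.8)

  # TP=8 FP=2 FN=2 -> P=R=F=0.8
  pred2 <- tibble::tibble(
    patient_id = paste0("p", 1:10), item = "Histology",
    selected = c(rep("8140", 8), "8070", "8046"))
  s2 <- score_codes(pred2, gold)
  expect_equal(c(s2$precision, s2$recall, s2$F), rep(0.8, 3))
})

test_that("perfect predictions score one on every metric", {
  gold <- mk_gold(list("p1", "A", "x"), list("p1", "B", "y"),
                  list("p2", "A", "x"))
  pred <- tibble::tibble(patient_id = c("p1", "p1", "p2"),
                         item = c("A", "B", "A"),
                         selected = c("x", "y", "x"))
  s <- score_codes(pred, gold)
  expect_true(all(s$precision == 1 & s$recall == 1 & s$F == 1))
})

test_that("abstention counts as a miss but not a false positive", {
  gold <- mk_gold(list("p1", "A", "x"), list("p2", "A", "x"))
  pred <- tibble::tibble(patient_id = c("p1", "p2"), item = "A",
                         selected = c("x", "NOT_CODED"))
  s <- score_codes(pred, gold)
  expect_equal(s$TP, 1L); expect_equal(s$FP, 0L); expect_equal(s$FN, 1L)
  expect_equal(s$precision, 1)     # no spurious code was produced
  expect_equal(s$recall, 0.5)
})

test_that("patients without a gold value are excluded per item", {
  gold <- mk_gold(list("p1", "A", "x"))
  pred <- tibble::tibble(patient_id = c("p1", "p2"), item = "A",
                         selected = c("x", "z"))
  s <- score_codes(pred, gold)
  expect_equal(s$TP, 1L); expect_equal(s$FP, 0L); expect_equal(s$FN, 0L)
})

test_that("randomized tables match the per-patient comparison oracle", {
  for (seed in 1:5) {
    tab <- withr::with_seed(seed, {
      pids <- sprintf("p%03d", 1:200)
      items <- c("A", "B", "C")
      gold <- do.call(rbind, lapply(items, function(it)
        tibble::tibble(patient_id = pids, item = it,
                       code = sample(c("x", "y", "z"), 200, replace = TRUE))))
      gold <- gold[stats::runif(nrow(gold)) > 0.1, ]  # some items unabstracted
      pred <- do.call(rbind, lapply(items, function(it)
        tibble::tibble(patient_id = pids, item = it,
                       selected = sample(c("x", "y", "z", "NOT_CODED"),
                                         200, replace = TRUE))))
      list(gold = gold, pred = pred)
    })
    s <- score_codes(tab$pred, tab$gold)
    o <- oracle_scores(tab$pred, tab$gold)
    for (it in s$item) {
      expect_equal(unname(s$precision[s$item == it]), unname(o[[it]][["P"]]),
                   info = paste(seed, it))
      expect_equal(unname(s$recall[s$item == it]), unname(o[[it]][["R"]]))
      expect_equal(unname(s$F[s$item == it]), unname(o[[it]][["F"]]))
    }
    # metric bounds and the F interval property
    expect_true(all(s$precision >= 0 & s$precision <= 1))
    expect_true(all(s$F >= pmin(s$precision, s$recall) - 1e-12 |
                      s$precision == 0 | s$recall == 0))
    expect_true(all(s$F <= pmax(s$precision, s$recall) + 1e-12))
    # permuting patients changes nothing
    perm <- withr::with_seed(seed, tab$pred[sample(nrow(tab$pred)), ])
    expect_equal(score_codes(perm, tab$gold), s)
  }
})

test_that("F1 equals P when precision and recall coincide", {
  gold <- do.call(rbind, lapply(1:10, function(k)
    tibble::tibble(patient_id = paste0("p", k), item = "A", code = "x")))
  pred <- tibble::tibble(patient_id = paste0("p", 1:10), item = "A",
                         selected = c(rep("x", 7), rep("y", 3)))
  s <- score_codes(pred, gold)
  expect_equal(s$precision, s$recall)
  expect_equal(s$F, s$precision)
})

test_that("the beta parameter reweights recall as specified", {
  gold <- do.call(rbind, lapply(1:10, function(k)
    tibble::tibble(patient_id = paste0("p", k), item = "A", code = "x")))
  pred <- tibble::tibble(patient_id = paste0("p", 1:10), item = "A",
                         selected = c(rep("x", 6), rep("NOT_CODED", 4)))
  s2 <- score_codes(pred, gold, beta = 2)
  P <- 1; R <- 0.6
  expect_equal(s2$F, 5 * P * R / (4 * P + R))
})

test_that("the mode baseline memorizes the modal training label", {
  train <- do.call(rbind, lapply(1:10, function(k)
    tibble::tibble(patient_id = paste0("p", k), item = "A",
                   code = if (k <= 7) "X" else "Y")))
  mb <- mode_baseline(train)
  expect_equal(mb$modes$code, "X")
  pred <- mb$predict(c("t1", "t2"))
  expect_equal(pred$selected, c("X", "X"))
})

test_that("mode ties resolve to the lexicographically smallest code", {
  train <- mk_gold(list("p1", "A", "B2"), list("p2", "A", "A1"),
                   list("p3", "A", "B2"), list("p4", "A", "A1"))
  mb <- mode_baseline(train)
  expect_equal(mb$modes$code, "A1")
  expect_true(mb$modes$tie)
})

test_that("items unseen in training predict NOT_CODED", {
  mb <- mode_baseline(mk_gold(list("p1", "A", "x")))
  pred <- mb$predict("t1", items_out = c("A", "B"))
  expect_equal(pred$selected[pred$item == "B"], "NOT_CODED")
})

test_that("constant predictors achieve micro accuracy equal to modal frequency", {
  gold <- withr::with_seed(31, do.call(rbind, lapply(1:400, function(k)
    tibble::tibble(patient_id = paste0("p", k), item = "A",
                   code = sample(c("X", "Y"), 1, prob = c(0.85, 0.15))))))
  mb <- mode_baseline(gold)
  s <- score_codes(mb$predict(unique(gold$patient_id)), gold)
  expect_equal(s$F, mean(gold$code == mb$modes$code))
})

test_that("ablation is a no-op when every item has a single unambiguous rule", {
  items <- c("Histology", "SSF 2")
  cfg <- generator_config(n_patients = 10, distractor_rate = 0,
                          items = items, seed = 21)
  co <- generate_cohort(cfg)
  dict <- lung_dictionary(); lex <- section_lexicon()
  training <- prepare_training(co$journeys, co$gold, dict, lex)
  fit <- learn_weights(lung_rule_base(item_profiles()[items]), training,
                       items = items)
  tab <- ablation_report(co$journeys, co$gold, fit$rules, dict, lex,
                         items = items)
  expect_equal(tab$F_unweighted, tab$F_weighted)
  expect_true(all(tab$F_weighted == 1))
})
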