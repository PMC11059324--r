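# Cohort filtering, patient-level splitting, micro-averaged metrics, the mode
# baseline, and the weighted-vs-unweighted ablation report.

#' Read gold registry codes from CSV
#'
#' One row per patient, one column per coding item (column names are item
#' names; `.` substitutions from `read.csv` are undone). Empty cells mean the
#' item was not abstracted for that patient and are excluded per item.
#'
#' @param path CSV file path.
#' @return Long tibble: `patient_id`, `item`, `code`.
#' @export
read_gold <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!"patient_id" %in% names(wide)) {
    stop("gold CSV lacks a patient_id column", call. = FALSE)
  }
  items <- setdiff(names(wide), "patient_id")
  rows <- lapply(items, function(it) {
    tibble::tibble(patient_id = wide$patient_id, item = it, code = wide[[it]])
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$code) & nzchar(out$code), ]
  out[order(out$patient_id, out$item), ]
}

#' Write gold codes to CSV (wide, one row per patient)
#'
#' @param gold Long gold tibble (`patient_id`, `item`, `code`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  pids <- sort(unique(gold$patient_id))
  items <- sort(unique(gold$item))
  wide <- data.frame(patient_id = pids, stringsAsFactors = FALSE,
                     check.names = FALSE)
  for (it in items) {
    sub <- gold[gold$item == it, ]
    wide[[it]] <- sub$code[match(pids, sub$patient_id)]
  }
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the cohort inclusion filters
#'
#' Removes (1) patients whose gold primary site is outside the lung topography
#' value set (codes starting `C34`), (2) patients with fewer than two reports,
#' and (3) patients whose reports are all of one type.
#'
#' @param journeys List of [journey()] objects.
#' @param gold Long gold tibble.
#' @return List with `journeys`, `gold` (both filtered) and `removed`, a
#'   tibble logging each removed patient and the triggering filter.
#' @export
filter_cohort <- function(journeys, gold) {
  pids <- vapply(journeys, function(j) j$patient_id, character(1))
  removed <- tibble::tibble(patient_id = character(), reason = character())
  keep <- rep(TRUE, length(journeys))
  for (i in seq_along(journeys)) {
    j <- journeys[[i]]
    site <- gold$code[gold$patient_id == j$patient_id &
                        gold$item == "Primary Site"]
    reason <- NULL
    if (!length(site) || !any(startsWith(site, "C34"))) {
      reason <- "primary site not lung (C34x)"
    } else if (length(j$reports) < 2L) {
      reason <- "fewer than 2 reports"
    } else {
      types <- unique(vapply(j$reports, function(r) r$report_type, character(1)))
      if (length(types) < 2L) reason <- "only one report type"
    }
    if (!is.null(reason)) {
      keep[i] <- FALSE
      removed <- rbind(removed,
                       tibble::tibble(patient_id = j$patient_id, reason = reason))
    }
  }
  list(journeys = journeys[keep],
       gold = gold[gold$patient_id %in% pids[keep], ],
       removed = removed)
}

#' Split patient ids into train and test sets
#'
#' Patient-granular (no patient on both sides), deterministic under `seed`;
#' the training side receives `floor(ratio * n)` patients.
#'
#' @param patients Character vector of patient ids.
#' @param ratio Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` character vectors.
#' @export
split_patients <- function(patients, ratio = 0.8, seed = 1L) {
  if (length(patients) < 2L) stop("need at least 2 patients to split", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)", call. = FALSE)
  patients <- sort(unique(patients))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  shuffled <- sample(patients)
  n_train <- floor(ratio * length(patients))
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[-seq_len(n_train)]))
}

#' Micro-averaged per-item precision, recall and F-beta
#'
#' Predictions and gold are joined per patient and item; for each item, over
#' the patients that have a gold value: a prediction equal to gold counts TP;
#' a wrong real code counts FP and FN; the `NOT_CODED` sentinel counts FN
#' only. `P = TP/(TP+FP)` (defined as 0 and flagged when the engine coded
#' nothing), `R = TP/(TP+FN)`, `F = (1+beta^2)PR/(beta^2 P + R)` (0 when
#' `P + R = 0`). Items with no gold-bearing patients are skipped.
#'
#' @param predictions Tibble with `patient_id`, `item`, `selected` (e.g. from
#'   [infer_codes()] rows or [selected_codes()]).
#' @param gold Long gold tibble (`patient_id`, `item`, `code`).
#' @param beta F-measure beta (default 1).
#' @return Tibble per item: `item`, `TP`, `FP`, `FN`, `precision`, `recall`,
#'   `F`, `undefined_precision` flag.
#' @export
score_codes <- function(predictions, gold, beta = 1) {
  items <- sort(unique(gold$item))
  rows <- lapply(items, function(it) {
    g <- gold[gold$item == it, ]
    if (!nrow(g)) return(NULL)
    p <- predictions[predictions$item == it, ]
    pred <- p$selected[match(g$patient_id, p$patient_id)]
    pred[is.na(pred)] <- "NOT_CODED"
    tp <- sum(pred == g$code)
    fp <- sum(pred != g$code & pred != "NOT_CODED")
    fn <- sum(pred != g$code)  # wrong code or NOT_CODED both miss the gold
    if (tp + fn == 0L) return(NULL)
    undef <- (tp + fp) == 0L
    prec <- if (undef) 0 else tp / (tp + fp)
    rec <- tp / (tp + fn)
    f <- if (prec + rec == 0) 0 else
      (1 + beta^2) * prec * rec / (beta^2 * prec + rec)
    tibble::tibble(item = it, TP = tp, FP = fp, FN = fn,
                   precision = prec, recall = rec, F = f,
                   undefined_precision = undef)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(tibble::tibble(item = character(), TP = integer(), FP = integer(),
                          FN = integer(), precision = numeric(),
                          recall = numeric(), F = numeric(),
                          undefined_precision = logical()))
  }
  do.call(rbind, rows)
}

#' Narrow inference output to selected codes
#'
#' @param results Tibble from [infer_codes()] / [code_cohort()].
#' @return Tibble `patient_id`, `item`, `selected`.
#' @export
selected_codes <- function(results) {
  tibble::tibble(patient_id = results$patient_id, item = results$item,
                 selected = results$selected)
}

#' Fit the mode baseline
#'
#' Memorises, per item, the most frequent training gold code (ties broken by
#' the lexicographically smallest code, which is logged); the returned
#' predictor emits that code for every test patient, and `NOT_CODED` for items
#' absent from the training gold.
#'
#' @param train_gold Long gold tibble for the training patients.
#' @return List with `modes` (tibble `item`, `code`, `n`, `tie`) and
#'   `predict`, a function mapping a patient-id vector (and optional item
#'   vector) to a predictions tibble.
#' @export
mode_baseline <- function(train_gold) {
  if (!nrow(train_gold)) stop("training gold is empty", call. = FALSE)
  items <- sort(unique(train_gold$item))
  modes <- do.call(rbind, lapply(items, function(it) {
    tab <- table(train_gold$code[train_gold$item == it])
    top <- max(tab)
    winners <- sort(names(tab)[tab == top])
    tibble::tibble(item = it, code = winners[1L], n = as.integer(top),
                   tie = length(winners) > 1L)
  }))
  predict_fn <- function(patient_ids, items_out = items) {
    grid <- expand.grid(patient_id = patient_ids, item = items_out,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    code <- modes$code[match(grid$item, modes$item)]
    code[is.na(code)] <- "NOT_CODED"
    tibble::tibble(patient_id = grid$patient_id, item = grid$item,
                   selected = code)
  }
  list(modes = modes, predict = predict_fn)
}

#' Weighted-vs-unweighted ablation report
#'
#' Runs inference twice over the same journeys — once with every rule weight
#' forced to 1 and once with the supplied (learned) weights — and tabulates
#' per-item precision/recall/F side by side.
#'
#' @param journeys Test journeys.
#' @param gold Long gold tibble for those patients.
#' @param rules Rule base carrying learned weights.
#' @param dictionary,section_lexicon,pattern_set Extraction configuration.
#' @param items Items to evaluate.
#' @return Tibble per item with `P_unweighted`, `R_unweighted`,
#'   `F_unweighted`, `P_weighted`, `R_weighted`, `F_weighted`.
#' @export
ablation_report <- function(journeys, gold, rules, dictionary, section_lexicon,
                            pattern_set = numeric_patterns(),
                            items = registry_items()) {
  unit_rules <- lapply(rules, function(r) { r$weight <- 1; r })
  dictionary <- compile_dictionary(dictionary)
  dbs <- lapply(journeys, extract_journey_facts, dictionary = dictionary,
                section_lexicon = section_lexicon, pattern_set = pattern_set)
  run <- function(rs) {
    preds <- lapply(seq_along(journeys), function(i) {
      infer_codes(dbs[[i]], rs, patient_id = journeys[[i]]$patient_id,
                  items = items)
    })
    selected_codes(do.call(rbind, preds))
  }
  s_u <- score_codes(run(unit_rules), gold)
  s_w <- score_codes(run(rules), gold)
  merged <- merge(
    stats::setNames(s_u[c("item", "precision", "recall", "F")],
                    c("item", "P_unweighted", "R_unweighted", "F_unweighted")),
    stats::setNames(s_w[c("item", "precision", "recall", "F")],
                    c("item", "P_weighted", "R_weighted", "F_weighted")),
    by = "item")
  tibble::as_tibble(merged[order(merged$item), ])
}
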