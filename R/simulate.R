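# Seeded synthetic patient-journey generator. Every other module is testable
# against cohorts from here: journeys mix pathology and imaging reports,
# evidence sentences are planted in the item's characteristic report type,
# gold registry records are emitted alongside, and (optionally) conflicting
# distractor mentions are planted in the other report type so that rule
# weighting has something to decide.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generator configuration
#'
#' Defaults encode the study conditions the engine is built for: a mean of
#' 4.8 pathology reports per patient, image reports filling out a mean total
#' of 14.6 reports, report dates spread over an 18-month window, and per-item
#' label skews from [item_profiles()].
#'
#' @param n_patients Number of patients.
#' @param mean_pathology Mean pathology reports per patient (Poisson, min 1).
#' @param mean_image Mean image reports per patient (Poisson, min 1).
#' @param distractor_rate Per-item probability of planting a conflicting
#'   mention in a report of the non-characteristic type; in `[0, 1)`.
#' @param items Items to generate (default all 30).
#' @param profiles Item profiles (default [item_profiles()]).
#' @param start_date First possible report date.
#' @param window_days Width of the report-date window (default 548, ~18 months).
#' @param seed Integer seed.
#' @return A `regcode_genconfig` list.
#' @export
generator_config <- function(n_patients = 100L, mean_pathology = 4.8,
                             mean_image = 9.8, distractor_rate = 0,
                             items = registry_items(),
                             profiles = item_profiles(),
                             start_date = "2019-01-01", window_days = 548L,
                             seed = 1L) {
  if (distractor_rate < 0 || distractor_rate >= 1) {
    stop("distractor_rate must be in [0, 1)", call. = FALSE)
  }
  for (it in items) {
    p <- profiles[[it]]
    if (is.null(p)) stop("no profile for item '", it, "'", call. = FALSE)
    if (p$kind == "dict" && abs(sum(p$probs) - 1) > 1e-9) {
      stop("label probabilities for '", it, "' do not sum to 1", call. = FALSE)
    }
    if (is.null(p$template)) stop("no template for item '", it, "'", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 mean_pathology = mean_pathology, mean_image = mean_image,
                 distractor_rate = distractor_rate, items = items,
                 profiles = profiles, start_date = as.Date(start_date),
                 window_days = as.integer(window_days), seed = as.integer(seed)),
            class = "regcode_genconfig")
}

.fill <- function(template, ...) {
  subs <- list(...)
  for (nm in names(subs)) {
    template <- gsub(paste0("{", nm, "}"), subs[[nm]], template, fixed = TRUE)
  }
  template
}

#' Generate a synthetic cohort
#'
#' For each patient: draw pathology and image report counts and dates, then
#' per configured item draw a gold code from the item's label distribution and
#' plant a supporting sentence under the item's section in a report of its
#' characteristic type (the earliest such report for date-typed items; one
#' fixed pathology report for single-report items). With probability
#' `distractor_rate` a conflicting code mention is additionally planted in a
#' report of the other type. Deterministic under the config seed.
#'
#' @param config A [generator_config()].
#' @return A `regcode_cohort`: `journeys`, long `gold` tibble, `truth_log`
#'   (which report carries true evidence / distractors), the internal sentence
#'   `plan` (used by [corrupt_cohort()]), and the config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "regcode_genconfig"))
  .with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
  plan <- vector("list", 4096L)
  np <- 0L
  gold <- vector("list", 4096L)
  ng <- 0L
  add_plan <- function(pid, rid, rtype, date, section, text, role, item, code) {
    np <<- np + 1L
    if (np > length(plan)) length(plan) <<- 2L * np
    plan[[np]] <<- c(pid, rid, rtype, as.character(date), section, text, role,
                     item, code)
  }
  add_gold <- function(pid, item, code) {
    ng <<- ng + 1L
    if (ng > length(gold)) length(gold) <<- 2L * ng
    gold[[ng]] <<- c(pid, item, code)
  }
  all_dates <- format(config$start_date + seq_len(config$window_days) - 1L,
                      "%Y-%m-%d")
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    n_path <- max(1L, stats::rpois(1L, config$mean_pathology))
    n_img <- max(1L, stats::rpois(1L, config$mean_image))
    n <- n_path + n_img
    dates <- all_dates[sample.int(config$window_days, n, replace = TRUE)]
    rtypes <- c(rep("pathology", n_path), rep("image", n_img))
    rids <- sprintf("%s-R%02d", pid, seq_len(n))
    # filler keeps every report non-empty and dictionary-silent
    for (k in seq_len(n)) {
      first_sec <- if (rtypes[k] == "pathology") .path_sections[1L] else .image_sections[1L]
      add_plan(pid, rids[k], rtypes[k], dates[k], first_sec,
               "Routine clinical review.", "filler", NA_character_, NA_character_)
    }
    # shared lymph-node counts so the examined/positive sentences agree
    n_ex <- sample(5:40, 1L)
    k_pos <- sample(0:n_ex, 1L)

    path_idx <- seq_len(n_path)
    img_idx <- n_path + seq_len(n_img)
    for (it in config$items) {
      p <- config$profiles[[it]]
      own <- if (p$report_type == "pathology") path_idx else img_idx
      other <- if (p$report_type == "pathology") img_idx else path_idx
      tgt <- if (p$kind == "date") {
        own[order(dates[own])[1L]]  # earliest qualifying report (ISO sort)
      } else if (p$single_report) {
        own[1L]
      } else {
        own[sample.int(length(own), 1L)]
      }
      if (p$kind == "dict") {
        code <- sample(p$values, 1L, prob = p$probs)
        text <- .fill(p$template, surface = p$surfaces[match(code, p$values)])
      } else if (p$kind == "numeric") {
        val <- switch(p$concept,
                      NodesExamined = n_ex,
                      NodesPositive = k_pos,
                      SurgicalMarginsDistance = sample(seq(0.1, 2, by = 0.1), 1L))
        code <- .fact_scalar(val)
        text <- .fill(p$template, n = .fact_scalar(n_ex),
                      k = .fact_scalar(k_pos), x = code)
      } else { # date
        code <- dates[tgt]
        text <- p$template
      }
      add_plan(pid, rids[tgt], rtypes[tgt], dates[tgt], p$section, text,
               "evidence", it, code)
      add_gold(pid, it, code)

      if (!p$single_report && config$distractor_rate > 0 &&
          length(other) > 0L && stats::runif(1L) < config$distractor_rate) {
        dr <- other[sample.int(length(other), 1L)]
        dsec <- if (rtypes[dr] == "pathology") .path_sections[1L] else .image_sections[1L]
        if (p$kind == "dict") {
          dcode <- if (length(p$values) > 1L) {
            alt <- setdiff(p$values, code)
            alt[sample.int(length(alt), 1L)]
          } else code
          dtext <- .fill(p$template, surface = p$surfaces[match(dcode, p$values)])
        } else if (p$kind == "numeric") {
          dval <- switch(p$concept,
                         NodesExamined = sample(setdiff(5:40, n_ex), 1L),
                         NodesPositive = {
                           alt <- setdiff(0:n_ex, k_pos)
                           alt[sample.int(length(alt), 1L)]
                         },
                         SurgicalMarginsDistance = {
                           alt <- setdiff(seq(0.1, 2, by = 0.1),
                                          as.numeric(code))
                           alt[sample.int(length(alt), 1L)]
                         })
          dcode <- .fact_scalar(dval)
          dtext <- .fill(p$template, n = .fact_scalar(n_ex),
                         k = dcode, x = dcode)
          if (p$concept == "NodesExamined") {
            dtext <- .fill(p$template, n = dcode, k = dcode, x = dcode)
          }
        } else { # date distractor: the marker sentence in an other-type report
          dcode <- dates[dr]
          dtext <- p$template
        }
        add_plan(pid, rids[dr], rtypes[dr], dates[dr], dsec, dtext,
                 "distractor", it, dcode)
      }
    }
  }
  pm <- do.call(rbind, plan[seq_len(np)])
  plan_tbl <- tibble::new_tibble(
    list(patient_id = pm[, 1L], report_id = pm[, 2L], report_type = pm[, 3L],
         date = pm[, 4L], section = pm[, 5L], text = pm[, 6L], role = pm[, 7L],
         item = pm[, 8L], code = pm[, 9L]),
    nrow = np)
  gm <- do.call(rbind, gold[seq_len(ng)])
  gold_tbl <- tibble::new_tibble(
    list(patient_id = gm[, 1L], item = gm[, 2L], code = gm[, 3L]), nrow = ng)
  .cohort_from_plan(plan_tbl, gold_tbl, config)
}

.cohort_from_plan <- function(plan, gold, config) {
  journeys <- .plan_to_journeys(plan)
  truth <- plan[plan$role != "filler",
                c("patient_id", "item", "code", "report_id", "report_type",
                  "role")]
  structure(list(journeys = journeys, gold = gold,
                 truth_log = tibble::as_tibble(truth),
                 plan = tibble::as_tibble(plan), config = config),
            class = "regcode_cohort")
}

.plan_to_journeys <- function(plan) {
  sec_order <- c(.path_sections, .image_sections)
  plan$section <- factor(plan$section, levels = sec_order)
  by_report <- split(seq_len(nrow(plan)),
                     factor(plan$report_id, levels = unique(plan$report_id)))
  reports_by_pid <- list()
  for (rid in names(by_report)) {
    idx <- by_report[[rid]]
    idx <- idx[order(plan$section[idx])]
    secs <- as.character(plan$section[idx])
    chunks <- character(0)
    last <- ""
    for (k in seq_along(idx)) {
      if (secs[k] != last) {
        chunks <- c(chunks, paste0(secs[k], ":"))
        last <- secs[k]
      }
      chunks <- c(chunks, plan$text[idx[k]])
    }
    pid <- plan$patient_id[idx[1L]]
    r <- report(report_id = rid, patient_id = pid,
                report_type = plan$report_type[idx[1L]],
                date = plan$date[idx[1L]], text = paste(chunks, collapse = "\n"))
    reports_by_pid[[pid]] <- c(reports_by_pid[[pid]], list(r))
  }
  lapply(names(reports_by_pid), function(pid) journey(pid, reports_by_pid[[pid]]))
}

#' @export
print.regcode_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort: %d patients, %d reports, %d items, distractor rate %.2f>\n",
              length(x$journeys),
              sum(vapply(x$journeys, function(j) length(j$reports), integer(1))),
              length(unique(x$gold$item)), x$config$distractor_rate))
  invisible(x)
}

#' Corrupt a synthetic cohort
#'
#' Robustness fixture: drops planted evidence sentences with probability
#' `missing_rate` and perturbs one letter of surviving evidence sentences with
#' probability `typo_rate`; the truth log is updated accordingly. Rates of
#' zero return an equivalent cohort.
#'
#' @param cohort A `regcode_cohort`.
#' @param missing_rate,typo_rate Probabilities in `[0, 1]` (`missing_rate = 1`
#'   removes every evidence sentence).
#' @param seed Integer seed.
#' @return A new `regcode_cohort` with the same gold records.
#' @export
corrupt_cohort <- function(cohort, missing_rate = 0, typo_rate = 0, seed = 1L) {
  stopifnot(inherits(cohort, "regcode_cohort"))
  .with_seed(seed, {
    plan <- cohort$plan
    ev <- which(plan$role == "evidence")
    drop <- ev[stats::runif(length(ev)) < missing_rate]
    keep_plan <- plan[setdiff(seq_len(nrow(plan)), drop), ]
    if (typo_rate > 0) {
      ev2 <- which(keep_plan$role == "evidence")
      hit <- ev2[stats::runif(length(ev2)) < typo_rate]
      for (i in hit) {
        txt <- keep_plan$text[i]
        pos <- which(strsplit(txt, "")[[1]] %in% letters)
        if (length(pos)) {
          j <- pos[sample.int(length(pos), 1L)]
          substr(txt, j, j) <- "z"
          keep_plan$text[i] <- txt
        }
      }
    }
    .cohort_from_plan(keep_plan, cohort$gold, cohort$config)
  })
}

#' Write a cohort to disk
#'
#' Emits `reports.jsonl` (the report schema [load_journeys()] accepts),
#' `gold.csv` (wide, one row per patient) and `truth_log.csv`.
#'
#' @param cohort A `regcode_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_journeys(cohort$journeys, file.path(dir, "reports.jsonl"))
  write_gold(cohort$gold, file.path(dir, "gold.csv"))
  utils::write.csv(cohort$truth_log, file.path(dir, "truth_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}
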