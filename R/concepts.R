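# Dictionary-based concept recognition and normalization, plus numeric-pattern
# extraction, feeding the fact database of the rule engine.

.num_words <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
                seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11,
                twelve = 12, thirteen = 13, fourteen = 14, fifteen = 15,
                sixteen = 16, seventeen = 17, eighteen = 18, nineteen = 19,
                twenty = 20)

.num_alt <- paste0("\\d+(?:\\.\\d+)?|", paste(names(.num_words), collapse = "|"))

.parse_number <- function(x) {
  x <- tolower(x)
  if (x %in% names(.num_words)) return(unname(.num_words[[x]]))
  as.numeric(x)
}

.is_punct_token <- function(tok) grepl("^[[:punct:]]+$", tok)

.mention_cols <- c("concept_type", "normalized", "surface", "start", "end",
                   "report_id", "sentence_index", "section_label",
                   "report_type", "report_date")

.empty_mentions <- function() {
  tibble::tibble(concept_type = character(), normalized = character(),
                 surface = character(), start = integer(), end = integer(),
                 report_id = character(), sentence_index = integer(),
                 section_label = character(), report_type = character(),
                 report_date = character())
}

.mention_rows_tibble <- function(rows) {
  if (!length(rows)) return(.empty_mentions())
  tibble::tibble(
    concept_type = vapply(rows, `[[`, character(1), "concept_type"),
    normalized = vapply(rows, `[[`, character(1), "normalized"),
    surface = vapply(rows, `[[`, character(1), "surface"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    report_id = vapply(rows, `[[`, character(1), "report_id"),
    sentence_index = vapply(rows, `[[`, integer(1), "sentence_index"),
    section_label = vapply(rows, `[[`, character(1), "section_label"),
    report_type = vapply(rows, `[[`, character(1), "report_type"),
    report_date = vapply(rows, `[[`, character(1), "report_date"))
}

#' Read a concept dictionary
#'
#' Tab-separated file with columns `surface`, `concept_type`, `normalized` and
#' an optional `gap` column (0 or 1) allowing one intervening token inside the
#' surface. `(surface, concept_type)` pairs must be unique.
#'
#' @param path TSV file path.
#' @return A tibble with one row per entry.
#' @export
read_dictionary <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  as_dictionary(d)
}

#' Validate a dictionary data frame
#'
#' @param d Data frame with columns `surface`, `concept_type`, `normalized`
#'   and optionally `gap`.
#' @return A validated tibble.
#' @export
as_dictionary <- function(d) {
  need <- c("surface", "concept_type", "normalized")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("dictionary lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"gap" %in% names(d)) d$gap <- 0L
  if (any(!nzchar(d$surface))) stop("dictionary has empty surfaces", call. = FALSE)
  if (anyDuplicated(d[c("surface", "concept_type")])) {
    stop("dictionary has duplicated (surface, concept_type) pairs", call. = FALSE)
  }
  tibble::as_tibble(d[c("surface", "concept_type", "normalized", "gap")])
}

#' Write a dictionary TSV
#' @param d Dictionary tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compile a dictionary for repeated matching
#'
#' Pre-tokenizes every surface and indexes entries by their first token, so
#' that scanning a sentence only considers entries that can start at the
#' current position. Entries are held in canonical (concept type, surface)
#' order, which makes matching independent of file row order. All the
#' recognition functions accept either a plain dictionary tibble or a
#' compiled one.
#'
#' @param dictionary Dictionary tibble ([as_dictionary()]).
#' @return An object of class `regcode_dictc`.
#' @export
compile_dictionary <- function(dictionary) {
  if (inherits(dictionary, "regcode_dictc")) return(dictionary)
  dictionary <- as_dictionary(dictionary)
  if (nrow(dictionary) == 0L) stop("dictionary is empty", call. = FALSE)
  dictionary <- dictionary[order(dictionary$concept_type, dictionary$surface), ]
  toks <- lapply(dictionary$surface, function(s) {
    et <- tolower(tokenize(s))
    et[!.is_punct_token(et)]
  })
  first <- vapply(toks, `[`, character(1), 1L)
  structure(list(entries = dictionary, toks = toks,
                 by_first = split(seq_along(first), first)),
            class = "regcode_dictc")
}

# Try to match one dictionary entry's token sequence at sentence position i.
# Punctuation tokens in the sentence are skipped for free; up to `gap`
# non-punctuation tokens may be skipped after the first surface token.
.match_entry_at <- function(toks_lower, i, entry_toks, gap) {
  n <- length(toks_lower)
  ei <- 1L; si <- i; gaps_used <- 0L
  while (ei <= length(entry_toks)) {
    if (si > n) return(NA_integer_)
    t <- toks_lower[si]
    if (t == entry_toks[ei]) {
      ei <- ei + 1L; si <- si + 1L
    } else if (ei > 1L && .is_punct_token(t)) {
      si <- si + 1L
    } else if (ei > 1L && gaps_used < gap) {
      gaps_used <- gaps_used + 1L; si <- si + 1L
    } else {
      return(NA_integer_)
    }
  }
  si - 1L
}

# Core scanner over one tokenized sentence; returns a list of mention rows.
.scan_dictionary <- function(comp, toks, toks_lower, ctx) {
  out <- list()
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    cand <- comp$by_first[[toks_lower[i]]]
    if (is.null(cand)) { i <- i + 1L; next }
    best_end <- NA_integer_; best_row <- NA_integer_
    for (k in cand) {
      e <- .match_entry_at(toks_lower, i, comp$toks[[k]], comp$entries$gap[k])
      if (!is.na(e) && (is.na(best_end) || e > best_end)) {
        best_end <- e; best_row <- k
      }
    }
    if (is.na(best_end)) {
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- c(
        list(concept_type = comp$entries$concept_type[best_row],
             normalized = comp$entries$normalized[best_row],
             surface = paste(toks[i:best_end], collapse = " "),
             start = i, end = best_end),
        ctx)
      i <- best_end + 1L
    }
  }
  out
}

.as_sentence <- function(sentence) {
  if (is.data.frame(sentence)) {
    stopifnot(nrow(sentence) == 1L)
    list(tokens = sentence$tokens[[1]], text = sentence$text,
         report_id = sentence$report_id, index = sentence$index,
         section_label = sentence$section_label)
  } else {
    sentence
  }
}

.sentence_ctx <- function(sent, report_type, report_date) {
  list(report_id = as.character(sent$report_id),
       sentence_index = as.integer(sent$index),
       section_label = as.character(sent$section_label),
       report_type = as.character(report_type),
       report_date = as.character(report_date))
}

#' Recognize dictionary concepts in one sentence
#'
#' Case-insensitive longest-match-wins scan over token spans; overlapping
#' matches are resolved leftmost-longest, and the result is independent of
#' dictionary row order.
#'
#' @param sentence One sentence row as produced by [segment_report()]: a list
#'   or one-row tibble with `tokens`, `text`, `report_id`, `index`,
#'   `section_label`.
#' @param dictionary Dictionary tibble or [compile_dictionary()] result.
#' @param report_type,report_date Report context copied onto each mention.
#' @return Mention tibble (possibly empty): `concept_type`, `normalized`,
#'   `surface`, `start`, `end` (1-based token span), sentence and report
#'   context columns.
#' @export
recognize <- function(sentence, dictionary, report_type = NA_character_,
                      report_date = NA_character_) {
  comp <- compile_dictionary(dictionary)
  sent <- .as_sentence(sentence)
  toks <- sent$tokens
  if (length(toks) == 0L) return(.empty_mentions())
  rows <- .scan_dictionary(comp, toks, tolower(toks),
                           .sentence_ctx(sent, report_type, report_date))
  .mention_rows_tibble(rows)
}

#' Default numeric extraction patterns
#'
#' Regex patterns (one capture group for the value; `<num>` expands to digits
#' or the number words one..twenty) for the count/size registry concepts a
#' dictionary cannot enumerate.
#'
#' @return Named list: concept type -> character vector of patterns.
#' @export
numeric_patterns <- function() {
  list(
    NodesExamined = c(
      "(?:a total of )?(<num>)\\s+(?:regional\\s+)?lymph nodes?\\s+(?:were\\s+|was\\s+)?(?:examined|dissected|sampled)",
      "of\\s+(<num>)\\s+lymph nodes?"
    ),
    NodesPositive = c(
      "(<num>)\\s+of\\s+(?:<num>)\\s+lymph nodes?\\s+(?:are\\s+|were\\s+)?(?:positive|involved)",
      "(<num>)\\s+positive\\s+(?:regional\\s+)?lymph nodes?"
    ),
    TumorSize = c(
      "tumou?r\\s+(?:size\\s+|measuring\\s+|measures\\s+)?(<num>)\\s*cm",
      "(<num>)\\s*cm\\s+(?:in\\s+)?(?:greatest\\s+)?(?:dimension|diameter)"
    ),
    SurgicalMarginsDistance = c(
      "margin(?:s)?\\s+distance\\s+(<num>)\\s*cm",
      "(<num>)\\s*cm\\s+(?:from|to)\\s+the\\s+(?:closest\\s+)?(?:surgical\\s+)?margin"
    )
  )
}

#' Read numeric patterns from a JSON file
#' @param path JSON file: object keyed by concept type, values arrays of patterns.
#' @return Named list of pattern vectors.
#' @export
read_numeric_patterns <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(p, as.character)
}

.compile_patterns <- function(pattern_set) {
  if (is.null(pattern_set)) return(NULL)
  lapply(pattern_set, function(ps) {
    vapply(ps, function(p) gsub("<num>", .num_alt, p, fixed = TRUE),
           character(1), USE.NAMES = FALSE)
  })
}

# char offset -> 1-based token index, via a left-to-right cursor over the text
.char_to_token <- function(text, tokens, pos) {
  cursor <- 1L
  for (k in seq_along(tokens)) {
    hit <- regexpr(tokens[k], substring(text, cursor), fixed = TRUE)
    if (hit == -1L) next
    start <- cursor + as.integer(hit) - 1L
    end <- start + nchar(tokens[k]) - 1L
    if (pos >= start && pos <= end) return(k)
    cursor <- end + 1L
    if (cursor > nchar(text)) break
  }
  NA_integer_
}

.scan_numeric <- function(compiled, sent, ctx) {
  text <- sent$text
  if (!grepl("[0-9]", text) &&
      !grepl(paste(names(.num_words), collapse = "|"), tolower(text))) {
    return(list())
  }
  out <- list()
  for (ctype in names(compiled)) {
    seen_pos <- integer(0)
    for (rx in compiled[[ctype]]) {
      m <- gregexpr(rx, text, ignore.case = TRUE, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
      for (k in seq_along(m)) {
        pos <- cs[k, 1L]; len <- cl[k, 1L]
        if (pos < 1L || pos %in% seen_pos) next
        seen_pos <- c(seen_pos, pos)
        val <- .parse_number(substr(text, pos, pos + len - 1L))
        tok <- .char_to_token(text, sent$tokens, pos)
        out[[length(out) + 1L]] <- c(
          list(concept_type = ctype, normalized = .fact_scalar(val),
               surface = substr(text, pos, pos + len - 1L),
               start = tok, end = tok),
          ctx)
      }
    }
  }
  out
}

#' Extract numeric concept mentions from one sentence
#'
#' Applies the pattern set; every capture becomes a mention whose `normalized`
#' value is the literal number as a canonical string (number words one..twenty
#' are converted to digits). Two captures in one sentence both get emitted;
#' disambiguation is the rule layer's job.
#'
#' @inheritParams recognize
#' @param pattern_set Named list of regex vectors, see [numeric_patterns()].
#' @return Mention tibble, same shape as [recognize()].
#' @export
extract_numeric <- function(sentence, pattern_set, report_type = NA_character_,
                            report_date = NA_character_) {
  sent <- .as_sentence(sentence)
  rows <- .scan_numeric(.compile_patterns(pattern_set), sent,
                        .sentence_ctx(sent, report_type, report_date))
  .mention_rows_tibble(rows)
}

#' Convert concept mentions to facts
#'
#' One fact per mention carrying `type`, `value`, `UMLS` (when the normalized
#' code is a CUID), `section`, `reportType` and `date`. Within each sentence,
#' every mention's fact additionally gets a `cooccur<OtherType> = TRUE` flag
#' per distinct other concept type present in that sentence.
#'
#' @param mentions Mention tibble (rows from [recognize()] /
#'   [extract_numeric()], any number of sentences mixed).
#' @return List of [fact()] objects, one per mention row.
#' @export
concepts_to_facts <- function(mentions) {
  if (nrow(mentions) == 0L) return(list())
  key <- paste(mentions$report_id, mentions$sentence_index, sep = "\x1f")
  lapply(seq_len(nrow(mentions)), function(i) {
    attrs <- list(type = mentions$concept_type[i], value = mentions$normalized[i])
    if (grepl("^C[0-9]{7}$", mentions$normalized[i])) {
      attrs$UMLS <- mentions$normalized[i]
    }
    if (!is.na(mentions$section_label[i])) attrs$section <- mentions$section_label[i]
    if (!is.na(mentions$report_type[i])) attrs$reportType <- mentions$report_type[i]
    if (!is.na(mentions$report_date[i])) attrs$date <- mentions$report_date[i]
    others <- setdiff(unique(mentions$concept_type[key == key[i]]),
                      mentions$concept_type[i])
    for (ot in sort(others)) attrs[[paste0("cooccur", ot)]] <- TRUE
    fact(attrs)
  })
}

#' Extract all facts from a patient journey
#'
#' Runs segmentation, dictionary recognition and numeric extraction over every
#' report of a journey and loads the resulting facts into a fresh database
#' (the database is always reset per journey).
#'
#' @param j A [journey()].
#' @param dictionary Dictionary tibble or [compile_dictionary()] result.
#' @param section_lexicon Character vector of headings.
#' @param pattern_set Numeric pattern list, or `NULL` to skip numeric extraction.
#' @return A [fact_db()] of observed facts.
#' @export
extract_journey_facts <- function(j, dictionary, section_lexicon,
                                  pattern_set = numeric_patterns()) {
  stopifnot(inherits(j, "regcode_journey"))
  comp <- compile_dictionary(dictionary)
  pats <- .compile_patterns(pattern_set)
  rows <- list()
  for (r in j$reports) {
    sents <- segment_report(r, section_lexicon)
    for (k in seq_len(nrow(sents))) {
      s <- list(tokens = sents$tokens[[k]], text = sents$text[k],
                report_id = sents$report_id[k], index = sents$index[k],
                section_label = sents$section_label[k])
      ctx <- .sentence_ctx(s, r$report_type, as.character(r$date))
      rows <- c(rows, .scan_dictionary(comp, s$tokens, tolower(s$tokens), ctx))
      if (!is.null(pats)) rows <- c(rows, .scan_numeric(pats, s, ctx))
    }
  }
  if (!length(rows)) return(fact_db())
  facts <- concepts_to_facts(.mention_rows_tibble(rows))
  db <- fact_db()
  for (f in facts) {
    db <- db_add(db, f, source = "observed",
                 support_date = if ("date" %in% names(f)) f[["date"]] else NA_character_)
  }
  db
}
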