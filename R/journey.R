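#' Construct a clinical report
#'
#' A report is the atomic input document: one free-text pathology or imaging
#' report belonging to one patient, dated so that journeys can be ordered.
#'
#' @param report_id Opaque report identifier, unique within a patient.
#' @param patient_id Opaque patient identifier.
#' @param report_type Either `"pathology"` or `"image"`.
#' @param date Report date, ISO-8601 (`"YYYY-MM-DD"`) string or `Date`.
#' @param text Free report text; must be non-empty after whitespace stripping.
#'
#' @return An object of class `regcode_report` (a named list).
#' @export
report <- function(report_id, patient_id, report_type, date, text) {
  report_type <- as.character(report_type)
  if (!report_type %in% c("pathology", "image")) {
    stop("report ", report_id, ": report_type must be 'pathology' or 'image', got '",
         report_type, "'", call. = FALSE)
  }
  # dates are carried as validated ISO-8601 strings (they sort correctly and
  # avoid repeated Date conversions on the hot path)
  if (inherits(date, "Date")) date <- format(date, "%Y-%m-%d")
  if (!is.character(date) || length(date) != 1L ||
      !grepl("^\\d{4}-\\d{2}-\\d{2}$", date) ||
      is.na(as.Date(date, format = "%Y-%m-%d"))) {
    stop("report ", report_id, ": date does not parse as ISO-8601",
         call. = FALSE)
  }
  text <- as.character(text)
  if (length(text) != 1L || !nzchar(trimws(text))) {
    stop("report ", report_id, ": text is empty", call. = FALSE)
  }
  structure(
    list(report_id = as.character(report_id),
         patient_id = as.character(patient_id),
         report_type = report_type,
         date = date,
         text = text),
    class = "regcode_report"
  )
}

#' Construct a patient journey
#'
#' A journey is the unit the coding engine processes: all reports of one
#' patient, ordered ascending by date with ties broken by report id.
#'
#' @param patient_id Patient identifier shared by all reports.
#' @param reports List of [report()] objects.
#'
#' @return An object of class `regcode_journey`.
#' @export
journey <- function(patient_id, reports) {
  patient_id <- as.character(patient_id)
  ids <- vapply(reports, function(r) r$patient_id, character(1))
  if (any(ids != patient_id)) {
    stop("journey ", patient_id, ": reports belong to a different patient",
         call. = FALSE)
  }
  rids <- vapply(reports, function(r) r$report_id, character(1))
  if (anyDuplicated(rids)) {
    stop("journey ", patient_id, ": duplicated report_id '",
         rids[duplicated(rids)][1L], "'", call. = FALSE)
  }
  dates <- vapply(reports, function(r) r$date, character(1))
  ord <- order(dates, rids)  # ISO strings sort chronologically
  structure(list(patient_id = patient_id, reports = reports[ord]),
            class = "regcode_journey")
}

#' @export
print.regcode_journey <- function(x, ...) {
  types <- vapply(x$reports, function(r) r$report_type, character(1))
  cat(sprintf("<patient journey %s: %d reports (%d pathology, %d image)>\n",
              x$patient_id, length(x$reports),
              sum(types == "pathology"), sum(types == "image")))
  invisible(x)
}

# Clinical abbreviations whose trailing period must not end a sentence.
.sentence_abbrev <- c("cm.", "mm.", "No.", "Dr.", "vs.", "approx.", "e.g.", "i.e.")

# Canonical form used for heading comparison: strip trailing ':', trim, casefold.
.canon_heading <- function(x) tolower(gsub("(^[ \t]+)|([ \t]*:?[ \t]*$)", "", x))

#' Tokenize a sentence
#'
#' Whitespace split followed by separation of leading and trailing punctuation
#' into their own tokens, which is sufficient for dictionary span matching.
#'
#' @param text A single string.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  raw <- strsplit(trimws(text), "\\s+")[[1]]
  raw <- raw[nzchar(raw)]
  if (!length(raw)) return(character(0))
  need <- nchar(raw) > 1L &
    (grepl("^[[:punct:]]", raw) | grepl("[[:punct:]]$", raw))
  if (!any(need)) return(raw)
  out <- as.list(raw)
  for (k in which(need)) {
    w <- raw[k]
    lead <- character(0); trail <- character(0)
    while (nchar(w) > 1L && grepl("^[[:punct:]]", w)) {
      lead <- c(lead, substr(w, 1L, 1L)); w <- substring(w, 2L)
    }
    while (nchar(w) > 1L && grepl("[[:punct:]]$", w) &&
           !grepl("^[0-9]+\\.[0-9]+$", w)) {
      trail <- c(substr(w, nchar(w), nchar(w)), trail)
      w <- substr(w, 1L, nchar(w) - 1L)
    }
    out[[k]] <- c(lead, w, trail)
  }
  unlist(out, use.names = FALSE)
}

.split_sentences <- function(line) {
  # Split on ". " followed by an uppercase letter, exempting clinical
  # abbreviations; newline splitting has already happened upstream.
  if (!grepl("[^ \t]", line)) return(character(0))
  if (!grepl(". ", line, fixed = TRUE)) {
    out <- trimws(line)
    return(out[nzchar(out)])
  }
  chars <- strsplit(line, "")[[1]]
  n <- length(chars)
  breaks <- integer(0)
  i <- 1L
  while (i <= n - 2L) {
    if (chars[i] == "." && chars[i + 1L] == " " && grepl("[A-Z]", chars[i + 2L])) {
      # word ending at the period, including the period itself
      j <- i
      while (j > 1L && !grepl("\\s", chars[j - 1L])) j <- j - 1L
      word <- paste(chars[j:i], collapse = "")
      if (!word %in% .sentence_abbrev) breaks <- c(breaks, i)
    }
    i <- i + 1L
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- substring(line, starts, ends)
  out <- trimws(out)
  out[nzchar(out)]
}

#' Segment a report into sentences with section labels
#'
#' The report text is split into lines; a line whose canonical form (trailing
#' `:` stripped, case-folded) equals a lexicon entry is a section heading.
#' Remaining lines are split into sentences on `". "` followed by an uppercase
#' letter (clinical abbreviations exempted). Each sentence is labelled with the
#' most recent heading above it, or `"UNSECTIONED"` when none has occurred.
#'
#' @param report A [report()] object.
#' @param section_lexicon Character vector of recognised heading strings.
#'
#' @return A [tibble::tibble] with one row per sentence: `report_id`,
#'   `section_label`, `index` (0-based ordinal), `text`, and a `tokens`
#'   list-column.
#' @export
segment_report <- function(report, section_lexicon) {
  stopifnot(inherits(report, "regcode_report"))
  if (length(section_lexicon) == 0L) {
    stop("section_lexicon is empty", call. = FALSE)
  }
  if (!nzchar(trimws(report$text))) stop("report text is empty", call. = FALSE)
  lex <- .canon_heading(section_lexicon)
  canon_label <- stats::setNames(as.character(section_lexicon), lex)

  lines <- strsplit(report$text, "\n", fixed = TRUE)[[1]]
  section <- "UNSECTIONED"
  texts <- character(0); labels <- character(0)
  for (line in lines) {
    if (!grepl("[^ \t]", line)) next
    key <- .canon_heading(line)
    if (key %in% lex) {
      section <- unname(canon_label[key])
      next
    }
    sents <- .split_sentences(line)
    texts <- c(texts, sents)
    labels <- c(labels, rep(section, length(sents)))
  }
  tibble::new_tibble(
    list(report_id = rep(report$report_id, length(texts)),
         section_label = labels,
         index = seq_along(texts) - 1L,
         text = texts,
         tokens = lapply(texts, tokenize)),
    nrow = length(texts))
}

#' Read a section-heading lexicon file
#'
#' Plain text, one heading per line; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of headings.
#' @export
read_section_lexicon <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Load patient journeys from disk
#'
#' Accepts either a JSON Lines file (one object per report with keys
#' `report_id`, `patient_id`, `report_type`, `date`, `text`) or a directory of
#' `.txt` files named `<patient_id>__<report_id>__<type>__<date>.txt`.
#' Reports are grouped by patient and date-ordered; malformed records raise an
#' error naming the offending record.
#'
#' @param path Path to a `.jsonl` file or a directory of `.txt` files.
#' @return A list of [journey()] objects, ordered by patient id.
#' @export
load_journeys <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    if (length(files) == 0L) stop("no .txt reports under ", path, call. = FALSE)
    reports <- lapply(files, function(f) {
      parts <- strsplit(sub("\\.txt$", "", basename(f)), "__", fixed = TRUE)[[1]]
      if (length(parts) != 4L) {
        stop("report file name not <patient>__<report>__<type>__<date>.txt: ",
             basename(f), call. = FALSE)
      }
      report(report_id = parts[2L], patient_id = parts[1L],
             report_type = parts[3L], date = parts[4L],
             text = paste(readLines(f, warn = FALSE), collapse = "\n"))
    })
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    reports <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop("line ", i, " of ", path,
                                               ": invalid JSON", call. = FALSE))
      need <- c("report_id", "patient_id", "report_type", "date", "text")
      miss <- setdiff(need, names(rec))
      if (length(miss)) {
        stop("line ", i, " of ", path, ": missing field(s) ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      report(rec$report_id, rec$patient_id, rec$report_type, rec$date, rec$text)
    })
  } else {
    stop("no such file or directory: ", path, call. = FALSE)
  }
  pids <- vapply(reports, function(r) r$patient_id, character(1))
  out <- lapply(sort(unique(pids)), function(p) journey(p, reports[pids == p]))
  out
}

#' Write journeys to a JSON Lines file
#'
#' @param journeys List of [journey()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_journeys <- function(journeys, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (j in journeys) {
    for (r in j$reports) {
      writeLines(jsonlite::toJSON(
        list(report_id = r$report_id, patient_id = r$patient_id,
             report_type = r$report_type, date = as.character(r$date),
             text = r$text),
        auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
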