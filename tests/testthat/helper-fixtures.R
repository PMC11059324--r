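# Shared fixtures: propositional rule bases over single-letter fact types, the
# encoding used for the engine- and graph-level oracle comparisons.

# a propositional fact: just a type
pfact <- function(letter) fact(type = letter)

# intermediate propositional rule: ants (letters) -> con (letter)
prule <- function(id, ants, con) {
  rule(rule_id = id, coding_item = "intermediate",
       antecedents = lapply(ants, function(a)
         list(attribute = "type", op = "eq", value = a)),
       consequent = list(list(type = con, value = "T")))
}

# coding propositional rule: ants (letters) -> code value for one item
crule <- function(id, ants, item, code, weight = 1) {
  rule(rule_id = id, coding_item = item,
       antecedents = lapply(ants, function(a)
         list(attribute = "type", op = "eq", value = a)),
       consequent = list(list(type = item_coding_type(item), value = code)),
       weight = weight)
}

# seeded random propositional base over `letters_pool`; a mix of intermediate
# and coding rules, 1-3 antecedents each
random_prop_base <- function(seed, n_rules = 15L, pool = LETTERS[1:8],
                             item = "Widget", codes = c("x1", "x2", "x3")) {
  withr::with_seed(seed, {
    rules <- lapply(seq_len(n_rules), function(k) {
      ants <- sample(pool, sample(1:3, 1))
      if (stats::runif(1) < 0.5) {
        con <- sample(setdiff(pool, ants), 1)
        prule(paste0("r", k), ants, con)
      } else {
        crule(paste0("r", k), ants, item, sample(codes, 1))
      }
    })
    observed <- sample(pool, sample(2:5, 1))
    list(rules = rules, observed = observed, item = item, codes = codes)
  })
}

# small fixture dictionary used across concept tests
fixture_dictionary <- function() {
  as_dictionary(data.frame(
    surface = c("lung, left upper lobe", "adenocarcinoma", "left upper lobe",
                "pleural effusion"),
    concept_type = c("PrimarySiteLaterality", "Histology", "PrimarySite",
                     "Finding"),
    normalized = c("C1261076", "8140", "C341", "C0032227"),
    stringsAsFactors = FALSE))
}

# one-sentence helper: wrap text into the sentence shape recognize() expects
as_sent <- function(text, report_id = "R1", index = 0L,
                    section_label = "UNSECTIONED") {
  list(tokens = tokenize(text), text = text, report_id = report_id,
       index = index, section_label = section_label)
}
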