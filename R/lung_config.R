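# The shipped lung configuration: per-item profiles tying together the value
# set and label skew, the evidence report type, the section the evidence is
# written under, the surface forms the dictionary recognises, and whether the
# item's evidence is confined to a single report (the site-specific factors
# and other purely pathology-local fields).

.slug <- function(x) tolower(gsub("[^A-Za-z0-9]+", "-", x))

.path_sections <- c("Clinical History", "Diagnosis", "Gross Examination",
                    "Microscopic Examination")
.image_sections <- c("Findings", "Impression")

#' Default section-heading lexicon
#' @return Character vector of pathology and imaging headings.
#' @export
section_lexicon <- function() c(.path_sections, .image_sections)

.profile <- function(item, concept, kind, report_type, section,
                     values = character(0), probs = numeric(0),
                     surfaces = character(0), template = "{surface}",
                     single_report = FALSE) {
  stopifnot(length(values) == length(probs) || kind != "dict",
            length(values) == length(surfaces) || kind != "dict")
  list(item = item, concept = concept, kind = kind, report_type = report_type,
       section = section, values = values, probs = probs, surfaces = surfaces,
       template = template, single_report = single_report)
}

#' Per-item generation and coding profiles
#'
#' One profile per registry item: concept type, value set with label
#' distribution (some items deliberately skewed, mirroring real registry label
#' distributions), evidence report type (pathology or image), evidence
#' section, surface forms, and the single-report-evidence flag.
#'
#' @return Named list of profiles keyed by item name.
#' @export
item_profiles <- function() {
  p <- list(
    .profile("AJCC Edition", "AjccEdition", "dict", "pathology", "Diagnosis",
             c("8", "7"), c(0.95, 0.05),
             c("ajcc 8th edition", "ajcc 7th edition"),
             "Staging assigned per {surface}."),
    .profile("Behavior Code", "BehaviorCode", "dict", "pathology",
             "Microscopic Examination",
             c("3", "2"), c(0.97, 0.03),
             c("invasive malignant behavior", "in situ behavior"),
             "Tumor shows {surface}.", single_report = TRUE),
    .profile("Clinical Other Staging Group", "ClinicalOtherStagingGroup",
             "dict", "pathology", "Diagnosis",
             c("88", "99"), c(0.93, 0.07),
             c("other staging group not applicable",
               "other staging group unknown"),
             "Clinical staging note: {surface}."),
    .profile("Clinical Stage Descriptor", "ClinicalStageDescriptor", "dict",
             "image", "Impression",
             c("0", "Y"), c(0.7, 0.3),
             c("no special clinical stage descriptor",
               "post-therapy clinical staging"),
             "Assessment: {surface}."),
    .profile("Date of First Microscopic Confirmation", "MicroConfirmation",
             "date", "pathology", "Microscopic Examination",
             template = "Malignancy microscopically confirmed on this specimen."),
    .profile("Date of First Surgical Procedure", "SurgicalProcedure", "date",
             "image", "Findings",
             template = "Status post surgical resection of the lung lesion."),
    .profile("Date of Initial Diagnosis", "InitialDiagnosis", "date", "image",
             "Impression",
             template = "Findings establish the initial diagnosis of lung cancer."),
    .profile("Date of Surgical Diagnostic and Staging Procedure",
             "StagingProcedure", "date", "pathology", "Gross Examination",
             template = "Specimen from surgical staging procedure received."),
    .profile("Diagnostic Confirmation", "DiagnosticConfirmation", "dict",
             "pathology", "Diagnosis",
             c("1", "2", "4"), c(0.9, 0.07, 0.03),
             c("positive histology confirmation",
               "positive cytology confirmation",
               "positive imaging confirmation"),
             "Diagnosis basis: {surface}."),
    .profile("Grade Clinical", "GradeClinical", "dict", "pathology",
             "Diagnosis",
             c("1", "2", "3", "4"), c(0.2, 0.35, 0.35, 0.1),
             c("clinically well differentiated",
               "clinically moderately differentiated",
               "clinically poorly differentiated",
               "clinically undifferentiated"),
             "Pre-treatment assessment is {surface}."),
    .profile("Grade Pathological", "GradePathological", "dict", "pathology",
             "Microscopic Examination",
             c("1", "2", "3", "4"), c(0.25, 0.35, 0.3, 0.1),
             c("well differentiated grade i", "moderately differentiated grade ii",
               "poorly differentiated grade iii", "undifferentiated grade iv"),
             "The tumor is {surface}."),
    .profile("Histology", "Histology", "dict", "pathology",
             "Microscopic Examination",
             c("8140", "8070", "8041", "8046"), c(0.5, 0.25, 0.15, 0.1),
             c("adenocarcinoma", "squamous cell carcinoma",
               "small cell carcinoma", "non-small cell carcinoma"),
             "Sections show {surface}."),
    .profile("Laterality", "Laterality", "dict", "image", "Findings",
             c("1", "2", "3"), c(0.5, 0.45, 0.05),
             c("right lung", "left lung", "bilateral lungs"),
             "Mass identified in the {surface}."),
    .profile("Lymph vessels or Vascular Invasion", "LymphovascularInvasion",
             "dict", "pathology", "Microscopic Examination",
             c("0", "1"), c(0.65, 0.35),
             c("no lymphovascular invasion", "lymphovascular invasion present"),
             "There is {surface}."),
    .profile("Nodes Examined", "NodesExamined", "numeric", "pathology",
             "Gross Examination",
             template = "A total of {n} lymph nodes were examined."),
    .profile("Nodes Positive", "NodesPositive", "numeric", "pathology",
             "Microscopic Examination",
             template = "{k} of {n} lymph nodes are positive."),
    .profile("Other Staging System", "OtherStagingSystem", "dict", "pathology",
             "Diagnosis",
             c("0", "9"), c(0.93, 0.07),
             c("ajcc staging system used", "alternative staging system used"),
             "Staging system: {surface}."),
    .profile("Pathologic M", "PathologicM", "dict", "pathology", "Diagnosis",
             c("0", "1"), c(0.8, 0.2),
             c("pm0 no distant metastasis", "pm1 distant metastasis present"),
             "Metastasis status {surface}."),
    .profile("Pathologic N", "PathologicN", "dict", "pathology", "Diagnosis",
             c("0", "1", "2", "3"), c(0.5, 0.25, 0.2, 0.05),
             c("pn0 nodal status", "pn1 nodal status", "pn2 nodal status",
               "pn3 nodal status"),
             "Regional nodes staged as {surface}."),
    .profile("Pathologic Stage Descriptor", "PathStageDescriptor", "dict",
             "pathology", "Diagnosis",
             c("0", "Y"), c(0.94, 0.06),
             c("no special pathologic stage descriptor",
               "post-therapy pathologic staging"),
             "Stage descriptor: {surface}.", single_report = TRUE),
    .profile("Pathologic T", "PathologicT", "dict", "pathology", "Diagnosis",
             c("1a", "1b", "2a", "2b", "3", "4"),
             c(0.2, 0.15, 0.25, 0.1, 0.2, 0.1),
             c("pt1a primary tumor", "pt1b primary tumor", "pt2a primary tumor",
               "pt2b primary tumor", "pt3 primary tumor", "pt4 primary tumor"),
             "Tumor staged as {surface}."),
    .profile("Perineural Invasion", "PerineuralInvasion", "dict", "pathology",
             "Microscopic Examination",
             c("0", "1"), c(0.7, 0.3),
             c("no perineural invasion", "perineural invasion present"),
             "Examination reveals {surface}."),
    .profile("Primary Site", "PrimarySite", "dict", "image", "Findings",
             c("C341", "C342", "C343", "C340", "C349"),
             c(0.5, 0.1, 0.25, 0.05, 0.1),
             c("upper lobe", "middle lobe", "lower lobe", "main bronchus",
               "lung, nos"),
             "Primary lesion located in the {surface}."),
    .profile("Scope of Regional Lymph Node Surgery", "NodeSurgeryScope",
             "dict", "pathology", "Gross Examination",
             c("0", "4", "9"), c(0.5, 0.4, 0.1),
             c("no regional lymph node surgery",
               "regional lymph node dissection performed",
               "lymph node surgery extent unknown"),
             "Operative note: {surface}."),
    .profile("SSF 2", "SSF2", "dict", "pathology", "Microscopic Examination",
             c("000", "010"), c(0.6, 0.4),
             c("no visceral pleural invasion",
               "visceral pleural invasion identified"),
             "Pleura: {surface}.", single_report = TRUE),
    .profile("SSF 5", "SSF5", "dict", "pathology", "Microscopic Examination",
             c("000", "010"), c(0.55, 0.45),
             c("mediastinal nodes not sampled",
               "mediastinal node dissection performed"),
             "N2 assessment: {surface}.", single_report = TRUE),
    .profile("SSF 6", "SSF6", "dict", "pathology", "Microscopic Examination",
             c("010", "020", "988"), c(0.5, 0.35, 0.15),
             c("egfr mutation detected", "egfr wild type",
               "egfr testing not performed"),
             "Molecular report: {surface}.", single_report = TRUE),
    .profile("SSF 7", "SSF7", "dict", "pathology", "Microscopic Examination",
             c("010", "020"), c(0.45, 0.55),
             c("alk translocation positive", "alk translocation negative"),
             "ALK assay: {surface}.", single_report = TRUE),
    .profile("Surgical Margins", "SurgicalMargins", "dict", "pathology",
             "Gross Examination",
             c("0", "1"), c(0.75, 0.25),
             c("surgical margins free of tumor",
               "surgical margins involved by tumor"),
             "Margins: {surface}."),
    .profile("Surgical Margins Distance", "SurgicalMarginsDistance", "numeric",
             "pathology", "Gross Examination",
             template = "Margin distance {x} cm from tumor edge.")
  )
  stats::setNames(p, vapply(p, `[[`, character(1), "item"))
}

#' The shipped lung concept dictionary
#'
#' Surface forms for every dictionary-coded item value, markers for the
#' date-typed procedures, and the UMLS-normalised primary-site/laterality
#' example entry ("lung, left upper lobe" -> C1261076).
#'
#' @param profiles Item profiles (default [item_profiles()]).
#' @return Dictionary tibble (see [as_dictionary()]).
#' @export
lung_dictionary <- function(profiles = item_profiles()) {
  rows <- list()
  for (p in profiles) {
    if (p$kind == "dict") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        surface = p$surfaces, concept_type = p$concept, normalized = p$values,
        gap = 0L)
    } else if (p$kind == "date") {
      # marker surface: the template itself minus the trailing period
      rows[[length(rows) + 1L]] <- tibble::tibble(
        surface = sub("\\.$", "", p$template), concept_type = p$concept,
        normalized = "EVENT", gap = 0L)
    }
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    surface = "lung, left upper lobe", concept_type = "PrimarySiteLaterality",
    normalized = "C1261076", gap = 0L)
  as_dictionary(do.call(rbind, rows))
}

#' The shipped lung rule base
#'
#' Two rules per item: a primary rule that binds a concept fact from the
#' item's characteristic report type (pathology or imaging) and copies its
#' value (or its report date, for date-typed items) into the item's coding
#' fact, and a secondary rule doing the same from the other report type.
#' The two rules have distinct consequence vertices in the weight-learning
#' graph, so training data can discover that evidence from the characteristic
#' report type is the reliable path and demote cross-report distractors.
#'
#' @param profiles Item profiles (default [item_profiles()]).
#' @return List of [rule()] objects covering all 30 items.
#' @export
lung_rule_base <- function(profiles = item_profiles()) {
  rules <- list()
  for (p in profiles) {
    ct <- item_coding_type(p$item)
    src <- if (p$kind == "date") "date" else "value"
    other <- if (p$report_type == "pathology") "image" else "pathology"
    rules[[length(rules) + 1L]] <- rule(
      rule_id = paste0(.slug(p$item), ".primary"),
      coding_item = p$item,
      antecedents = list(
        list(attribute = "type", op = "eq", value = p$concept, fact_ref = "P"),
        list(attribute = "reportType", op = "eq", value = p$report_type,
             fact_ref = "P")),
      consequent = list(list(type = ct, value = paste0("@P.", src))))
    rules[[length(rules) + 1L]] <- rule(
      rule_id = paste0(.slug(p$item), ".secondary"),
      coding_item = p$item,
      antecedents = list(
        list(attribute = "type", op = "eq", value = p$concept, fact_ref = "S"),
        list(attribute = "reportType", op = "eq", value = other,
             fact_ref = "S")),
      consequent = list(list(type = ct, value = paste0("@S.", src))))
  }
  rules
}
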