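---
title: "Weighted rule-based registry coding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted rule-based registry coding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regcode)
```

## The coding problem

Hospital cancer registries abstract each patient's tumour, staging and
treatment information into standardized coding items — primary site and
laterality (ICD-O-3 topography), histology and behavior (morphology codes),
TNM categories, grade, lymph-node counts, surgical margins, key dates, and
site-specific factors such as EGFR or ALK status. The raw material is
free text: pathology reports and imaging reports accumulated over a patient's
treatment journey, typically spanning around eighteen months and mixing a few
pathology reports with a much larger number of imaging reports. `regcode`
models this task as a function from a date-ordered *journey* of reports to one
code per configured item (thirty lung-cancer items in the shipped
configuration).

The pipeline has four stages:

1. **Preprocessing** (`segment_report()`): reports are split into sentences,
   tokenized, and labelled with the most recent section heading
   ("Diagnosis", "Microscopic Examination", "Findings", ...) above them.
2. **Concept extraction** (`recognize()`, `extract_numeric()`): a dictionary
   maps surface forms to typed, normalized concepts (UMLS CUIDs, registry
   value-set codes); regular-expression patterns capture counts and sizes that
   no dictionary can enumerate. Mentions become attribute-value *facts*
   carrying the section, report type, report date, and same-sentence
   co-occurrence flags (`cooccurHistology = TRUE` and the like).
3. **Inference** (`forward_chain()`, `infer_codes()`): weighted production
   rules — AND-joined antecedent tests over fact attributes, consequents that
   assert new facts — are fired to a fixpoint over the journey's fact
   database. For each item the candidate codes are ranked by rule weight and
   the highest-weight code is selected.
4. **Weight learning** (`learn_weights()`): per item, a directed
   co-occurrence graph over rule antecedents and consequences is accumulated
   from coded training journeys, row-normalised into an adjacency matrix, and
   summed by one-hop message passing into vertex weights that become the rule
   weights.

## The inference engine

A fact is a flat map of scalar attributes with a mandatory `type`. The fact
database has set semantics: re-asserting an existing fact is a no-op, which
(together with a finite assertion vocabulary) guarantees that forward chaining
terminates, and makes the fixpoint independent of rule order. Provenance (the
rule ids that asserted each fact) is kept for the audit trail the CLI can dump
per patient.

Antecedents support `eq`, `ne`, `ge`, `le` and `present` over attributes; an
absent attribute never matches. `ge`/`le` compare numerically, or
chronologically when both sides are ISO dates; anything else is a type error
rather than a silent false. Because a journey contains many facts, each
antecedent may by default be satisfied by a *different* fact; antecedents that
must co-refer (for example "a node-count concept *from a pathology report*")
share an explicit `fact_ref` in the rule file. Consequent values of the form
`"@P.value"` or `"@P.date"` copy an attribute from the bound fact, which is
how count-valued and date-valued items are coded without enumerating every
possible number or date in the rule base.

Per item, candidate codes are scored by the maximum weight over the rules that
asserted them (a sum-of-weights mode is available as a configuration switch,
but the selection contract is "the code with the highest weight", so max is
the default). Ties break deterministically: earlier supporting report date
first, then the lexicographically smaller code. Items with no fired rule
select the sentinel `NOT_CODED`, which the evaluator counts as a miss (a
false negative) but not as a spurious code (no false positive) — abstention
is not penalised twice.

## Weight learning

For a coding item $c$, let $R$ be the set of rule antecedents and $Con$ the
set of rule consequences, each deduplicated across rules. The graph skeleton
contains, for every within-rule antecedent pair $(v_i, v_j)$, directed edges
both ways; for every antecedent-consequence pair $(v_i, v_k)$, one edge
$i \to k$ and one edge $i \to k'$, where $v_{k'}$ is the consequence's
*non-match* twin (written `-k`). Non-match vertices are pure sinks: they
receive edges but emit none, and they exist to absorb row mass when a fired
rule's code disagrees with the registrar's gold code. An intermediate
consequence (a fact asserted by one rule and tested by another) is a single
shared vertex, which is what makes the worked neighbourhoods come out right:
with rules $A \wedge B \to C$, $C \wedge D \wedge E \to F$ and
$C \wedge D \to G$, the consequence $F$ aggregates from $\{C, D, E\}$, $C$
from $\{A, B, D, E\}$, and $A$ from $\{B\}$.

Training accumulates an integer co-occurrence matrix $B$ (initialised to
zero), one record per patient journey:

* for every within-rule antecedent pair with *both* antecedents individually
  matched by the (chained) facts, $B_{ij}$ and $B_{ji}$ increase by one —
  once per distinct vertex pair per record;
* for every fired rule, each antecedent's cell toward the consequence
  increases by one when the asserted code equals the patient's gold code for
  the item, and toward the non-match twin when it does not. Intermediate
  consequences have no gold code to disagree with, so a fired intermediate
  rule always counts toward its consequence vertex.

With $q_i$ the $i$-th row sum, the adjacency matrix is

$$A_{ij} = \begin{cases} 0 & i = j,\; q_i \neq 0 \\ 1 & i = j,\; q_i = 0 \\ B_{ij} / q_i & \text{otherwise,} \end{cases}$$

so each informative row is a probability vector over the other vertices.
Vertex weights are the one-hop message-passing sum over in-neighbours,
$w_i = \sum_{j \in N(v_i)} A_{ji}$, and each rule receives the weight of its
consequence vertex. Rules sharing a consequence vertex therefore share a
weight; discrimination happens *between* consequence vertices.

Three points were genuinely open and are resolved as follows:

* **Pair counting** requires only that the two antecedents match, not that
  the whole rule fires — the literal reading of the accumulation step; a
  sensitivity switch was considered and rejected to keep the estimator simple.
* **Message-passing depth** defaults to one phase, the literal update.
  `message_pass(phases = k)` iterates with sum-normalised weights for
  exploration, but all learning in this package uses one phase.
* **Matrix layout**: the non-match columns are appended after the
  consequences (the nominal $(R+Con) \times (R+Con)$ shape has nowhere to
  store $B_{ij'}$), and the matrix is kept square so the same indexing serves
  $B$, $A$ and the edge mask. Non-match rows carry no counts; their diagonal
  is 1 by the isolated-vertex case.
* **Co-occurrence scope** is one patient journey per record, because gold
  codes exist per patient; `prepare_training(scope = "report")` exposes the
  per-report alternative.
* **Normalisation**: vertex weights are used raw, never renormalised per
  item — only their order within an item matters for selection.

## Why weighting helps, mechanically

The shipped lung rule base pairs, for every item, a *primary* rule that binds
a concept from the item's characteristic report type (pathology for
histology, grading, nodes, margins, SSFs; imaging for primary site,
laterality, stage descriptor and the diagnosis/surgery dates) with a
*secondary* rule that accepts the same concept from the other report type.
The two rules copy the concept's value into the same coding fact type but
through differently named references, so they own distinct consequence
vertices. On training data whose reliable evidence lives in the
characteristic report type, the primary vertex accumulates gold-matching
counts while the secondary vertex accumulates non-match mass; after learning,
a cross-report distractor mention loses to the true mention on weight alone.
With unit weights the two candidates tie and the date/lexicographic
tie-break decides — about half the distracted patients get the wrong code,
which is exactly the failure mode the ablation report
(`ablation_report()`) makes visible.

## The synthetic cohort generator

No clinical text ships with (or is needed by) this package. The generator
(`generate_cohort()`) emulates the statistical structure the engine assumes:

* **Volumes**: pathology report counts are Poisson with mean 4.8 and image
  reports Poisson with mean 9.8, so the expected total of 14.6 reports per
  patient matches the cohort the configuration is calibrated for (the two
  figures are configurable because report-volume conventions differ between
  hospitals); dates are uniform over an 18-month window.
* **Evidence placement**: each item's supporting sentence is rendered from a
  template into a report of the item's characteristic type, under its
  characteristic section; date items use the earliest qualifying report, and
  single-report items (the four SSFs, behavior code, pathologic stage
  descriptor) are confined to one fixed pathology report, mirroring fields
  whose evidence appears exactly once in a record.
* **Label skew**: per-item label distributions are skewed where registries
  are skewed (AJCC edition 0.95, behavior 0.97, diagnostic confirmation 0.9,
  staging-system items 0.93), and flatter for T/N/grade/histology.
* **Distractors**: with a configurable rate, a conflicting code mention is
  planted in a report of the *other* type, which is the mechanism that makes
  rule weighting matter at all.
* **Counts**: nodes-examined and nodes-positive are drawn jointly
  (positive ≤ examined) and rendered consistently in both sentences.

The generator emits the gold registry record and a truth log alongside the
text, and the gold for date items comes from the generator's own plan, never
re-derived through the engine — the oracle stays independent of the system
under test. `corrupt_cohort()` drops or perturbs evidence sentences for
robustness fixtures.

What passing tests on these cohorts shows — and what it does not: the
round-trip and ablation results demonstrate that the engine, the learning
rule and the evaluation arithmetic are correct and that the weighting
mechanism recovers cross-report conflicts *when the dictionary recognises the
mentions*. Real clinical text adds recognition errors, negation, synonymy
and section-structure noise that templated English cannot emulate; absolute
scores on synthetic cohorts therefore say nothing about absolute performance
on hospital data, only about the correctness of the symbolic machinery.

## Numerical and procedural choices

* Sentence boundaries: newline, plus `". "` followed by an uppercase letter,
  with a clinical abbreviation list (`cm.`, `No.`, ...) exempted. Heading
  detection is exact after case-folding and trailing-colon stripping —
  deterministic and bit-stable, with a flat last-heading-wins section model.
* Dictionary matching is case-insensitive, punctuation-tolerant,
  leftmost-longest over token spans, with an optional per-entry single-token
  gap; results are independent of dictionary row order.
* The patient-level 80:20 split takes `floor(ratio × n)` training patients
  under a caller-supplied seed; no patient appears on both sides.
* Micro-averaged per-item precision/recall/F follow the standard pooled
  TP/FP/FN definitions at β = 1; patients without a gold value for an item
  are excluded from that item. When the engine codes nothing for an item,
  precision is reported as 0 and flagged rather than left undefined.
* Cohort filtering removes patients whose gold primary site is outside the
  lung topography set (`C34x`), with fewer than two reports, or with a single
  report type.
* All randomness (generation, splitting, corruption) flows through explicit
  integer seeds; two runs with identical inputs and seeds produce identical
  outputs byte for byte.
* Problem sizes used by the shipped test-suite checks: brute-force oracle
  comparisons run on 100 seeded rule bases of up to 8 vertices; round-trip
  recovery uses a 500-patient clean cohort over all 30 items; the
  distractor ablation uses 1000-patient cohorts over 20 seeds with four items
  (two cross-report-distractor items, two single-report items), which keeps
  the weighted-versus-unweighted contrast sharp while exercising both
  behaviours.

## Known limitations

* The concept recognizer is a dictionary with exact-ish matching. The fact
  schema is recognizer-agnostic, so a learned tagger can replace it without
  touching the rule layer, but out of the box unseen surface variants are
  simply missed.
* Negation is not modelled as scope; "absent" findings must be distinct
  dictionary surfaces ("no perineural invasion") with their own codes.
* Weights are shared by rules with a common consequence vertex; evidence
  paths that should be distinguished must assert distinguishable consequents
  (the primary/secondary reference naming in the shipped base is exactly
  that).
* The engine emits one code per item per patient; multiple primaries are not
  represented.
* Backward chaining is not implemented as a query language; the provenance
  trace serves the explanation use-case instead.
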