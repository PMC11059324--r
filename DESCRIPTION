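Package: regcode
Title: Weighted Rule-Based Coding of Cancer Registry Items from Clinical Report Journeys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A symbolic coding engine for hospital cancer-registry abstraction.
    Free-text pathology and imaging reports from a patient's treatment journey
    are segmented, scanned for registry concepts with a dictionary and numeric
    patterns, and converted into an attribute-value fact database. A
    forward-chaining inference engine fires weighted production rules over the
    facts and selects one code per registry item by highest rule weight. Rule
    weights are learned from coded training journeys via a per-item directed
    co-occurrence graph with non-match vertices, row-normalised adjacency and a
    one-hop message-passing sum. Includes patient-level train/test splitting,
    micro-averaged precision/recall/F evaluation, a mode baseline, a
    weighted-versus-unweighted ablation report, and a seeded synthetic
    patient-journey generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
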