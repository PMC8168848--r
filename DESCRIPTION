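Package: squamataxa
Title: Return-on-Investment Prioritization of Taxonomic Research for Conservation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing rigorous taxonomic research with a
    return-on-investment (ROI) framework, as applied to structured expert
    elicitation of taxonomic uncertainty in species groups such as the
    Australian squamate reptiles. Reads and validates expert assessment
    tables (taxonomic confidence, predicted revision outcome, outstanding
    research steps, and conservation-benefit flags), resolves multi-assessor
    conflicts, computes per-species ROI scores and priority cohorts,
    aggregates species range polygons onto equal-area grids (richness,
    weighted mean, and square-root-transformed mean surfaces, including
    fine-scale island subgrids), and produces headline census, family-level,
    research-needs, and conservation summaries. A seeded synthetic-data
    generator emulates both the assessment tables and heavy-tailed range
    polygons so the full pipeline is testable without any external download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
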