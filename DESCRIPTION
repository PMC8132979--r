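Package: strokenlp
Title: Rule-Based Extraction of Stroke Attributes from Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sentence-level, weighted regular-expression information extraction
    for free-text head and neck CT/CTA/CTP radiology reports. Classifies seven
    stroke-related attributes (proximal large vessel occlusion, distal anterior
    circulation occlusion, basilar occlusion, established ischemia, intracranial
    hemorrhage, ASPECTS band, and collateral status), with explicit handling of
    same-sentence negation, hedged ischemia language, and the ASPECT/aspect
    homonym. Includes diagnostic-accuracy evaluation (sensitivity, specificity,
    PPV, NPV, accuracy, percent agreement), a discrepancy report for iterative
    rule refinement, seeded train/validation splitting, and a labeled synthetic
    report generator with configurable prevalences and adversarial hard cases so
    the whole pipeline is testable without access to a clinical corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
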