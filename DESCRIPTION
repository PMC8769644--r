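Package: innexScreen
Title: Screening Gap-Junction Proteins for Extracellular N-Glycosylation Sequons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable screen for innexin-family gap-junction proteins:
    infers the canonical four-transmembrane topology from Kyte-Doolittle
    hydropathy profiles, delineates the two extracellular loops, detects
    N-glycosylation sequons (N-X-S/T, X != P) with a rule-based occupancy
    score, restricts calls to extracellular loops, assesses sequon
    conservation across aligned orthologs, annotates neighbor-joining trees
    with sequon presence, and aggregates presence/absence per taxonomic
    group. Ships a synthetic innexin-like sequence generator with planted
    ground truth so every stage is testable offline, plus a command-line
    interface over the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
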