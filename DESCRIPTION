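Package: urodegradome
Title: Urinary Peptidomics and Degradomics Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of urinary peptidome data: validated
    disease-peptide association tables, bipartite disease-peptide networks
    and signature (degree-1) peptide extraction, physicochemical descriptor
    profiles (length, mass, isoelectric point, GRAVY, amino-acid group
    composition), peptide-centric protease prediction from Schechter-Berger
    P4-P4' cleavage windows matched against MEROPS-style specificity rules,
    hypergeometric enrichment of predicted protease activity over a health
    reference library with Bonferroni correction, and exhaustive search for
    minimal protease sets that uniquely identify a condition. Includes a
    synthetic-study generator with planted signature peptides and planted
    protease-activity differentials for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
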