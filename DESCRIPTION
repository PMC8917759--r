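Package: iapfam
Title: Curation and Characterization of Expanded IAP Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize expanded inhibitor-of-apoptosis (IAP)
    gene families from domain-scan evidence, as found in bivalve genomes.
    Curates candidate gene sets from HMM and InterProScan-style hit tables
    (E-value filtering, CDD BIR confirmation, identical-sequence and
    haplotig collapse, intronless/tandem-array/retroposition flags),
    classifies BIR domains into conserved and novel types by key residues
    at anchored alignment positions, types whole-protein domain
    architectures against a rule table, classifies per-experiment gene
    expression status downstream of differential-expression results, and
    performs weighted co-expression network analysis (biweight
    midcorrelation, signed-hybrid adjacency, topological overlap, module
    eigengenes, module-trait association, direct IAP-apoptosis edge
    extraction). A synthetic-data module generates every input format with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr
Config/testthat/edition: 3
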