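Package: prohoscan
Title: Comparative Prohormone Complement Annotation from Genome and
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Homology-guided prediction of prohormone (neuropeptide
    precursor) proteins from genome and transcriptome assemblies, with
    cross-assembly and cross-species isoform cataloguing, gap-run recovery
    classification, rule-based signal-peptide and cleavage-site prediction,
    and per-isoform evolutionary statistics (MeaPED, Robinson-Foulds
    distances, shared-edge proportions). Includes a fully ground-truthed
    synthetic fish-clade simulator (species tree, evolving gene families,
    duplications, clade-level gene loss, and assembly artifacts such as
    frameshifting indels, premature stop codons, contig breaks, and
    expression dropout) so that every pipeline stage can be validated
    against known truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
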