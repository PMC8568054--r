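Package: ringscreen
Title: RING-Finger Domain Discovery, Subtype Classification and
    Stress-Response Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A survey pipeline for RING-finger (zinc-binding) E3
    ubiquitin-ligase families in plant proteomes. Locates the eight
    zinc-coordinating metal-ligand residues of the RING octet with a
    configurable spacer grammar, classifies domains into the RING-H2,
    HCa, HCb, C2, v and G subtypes, collapses redundant candidate
    proteins by global-alignment identity, calls stress-responsive genes
    from treatment/control expression tables by a twofold log2 rule with
    full Venn decomposition across conditions, and quantifies qPCR
    validation experiments by the 2^-delta-delta-Ct method. Ships
    planted-truth synthetic generators so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
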