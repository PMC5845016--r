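Package: uvphos
Title: UV-Induced p38-MK2 Phosphoproteomics and RNA Pol II Release Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for SILAC phosphoproteomics of UV-light-induced
    p38-MK2 signaling and its chromatin consequences. Implements an
    empirical-Bayes moderated one-sample t-test for SILAC log-ratios,
    hierarchical UV-regulation and kinase-dependency calling, iceLogo-style
    position-specific sequence-motif enrichment with fixed-motif matchers
    (S/TQ, LXRQXS/T, RXXS/TXDXDI) and a rule-based 14-3-3 binding-motif
    scorer, phosphosite occupancy from a phosphatase-reference SILAC design,
    pulldown interactome calling with hypergeometric/Fisher gene-set
    enrichment, and the RNA polymerase II promoter-release ratio (PRR)
    statistic from coverage tracks, including metagene profiles and
    differential release. A seeded synthetic-data generator plants known
    effects in every data type so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
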