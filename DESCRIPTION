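Package: hdrquant
Title: Quantify HDR and NHEJ Editing Outcomes from Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies CRISPR-Cas9 editing outcomes (homology-directed repair,
    non-homologous end joining, unmodified) in paired-end amplicon sequencing
    reads relative to a guide-defined cut site, using NEEDLE-equivalent affine-gap
    global alignment and a +/- 3 bp cut-site indel window. Includes paired-end
    read merging with quality-weighted consensus, per-sample outcome tables and
    HDR/NHEJ ratios, group statistics (mean +/- SD, fold changes, unpaired t
    tests), a marker-based single-cell cell-cycle scorer with an explicit G0
    call, and seeded simulators for MiSeq-like amplicon read pairs and sparse
    single-cell count matrices with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
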