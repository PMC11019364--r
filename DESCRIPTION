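Package: refpanelqc
Title: Reference-Assembly Quality Control from Inbred Genotype Panels
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality-control and strain-genetics computations for reference
    genome assemblies evaluated against multi-sample genotype panels of
    inbred strains. Flags candidate misassembly (collapsed-repeat) regions
    from the segment-wise distribution of heterozygous and missing calls in
    reference-strain samples, using a log-transformed scanning statistic,
    circular-binary-segmentation changepoint detection with permutation
    significance, and a four-rule segment merging procedure. Detects shared
    per-site reference-base anomalies with read-depth evidence, computes
    identity-by-state matrices and UPGMA dendrograms with proxy-strain and
    mislabeled-sample rules, evaluates chain-based coordinate liftover,
    classifies SNP-gene association pairs as cis or trans under two
    references, and computes assembly contiguity statistics (N50/L50).
    Includes a synthetic-data generator that emulates inbred panels with
    planted collapsed repeats, shared error sites and label swaps, so the
    whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    ape,
    vcfR,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
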