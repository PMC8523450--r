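Package: mitopanel
Title: Quality Control and Threshold Variant Calling for Whole-mtDNA Amplicon Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytical workflow for internal validation of whole
    mitochondrial genome sequencing on a two-pool amplicon panel aligned to
    the circular rCRS reference extended by 80 nt. Implements artifact read
    removal by two-cluster analysis of read length and mapping quality with
    a derived length cutoff, per-position pileup construction with
    wrap-around coordinate remapping, threshold-based calling of
    substitutions, point heteroplasmies (IUPAC codes), indels and no-call
    regions, per-position haplotype-purity (VarFreq) profiles with empirical
    cumulative distributions, cross-replicate recurrent-noisy-position
    blacklisting, coverage summaries, run-reliability classification,
    dilution-series sensitivity scoring against simulated ground truth, and
    EMPOP-style haplotype concordance. A seeded amplicon-read simulator with
    template-count-driven stochasticity provides ground truth for every
    injected feature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
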