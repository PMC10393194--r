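Package: mrnpAtlas
Title: Synthetic-Data-Driven Characterization of Nuclear mRNP Particles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize purified nuclear messenger
    ribonucleoprotein (mRNP) particles from sequencing and mass-spectrometry
    derived inputs: metagene coverage profiling with 100-bin scaling,
    splice-junction split/nonsplit read statistics with coverage filtering
    and Wilcoxon comparison, eluate/lysate enrichment via median-of-ratios
    normalization with Spearman correlation against mRNA half-life and
    transcript length, intensity-based absolute quantification (iBAQ) with
    in-silico protease digestion, cross-linking mass-spectrometry link
    classification with homo-oligomer self-link detection and per-residue
    disorder overlay, and an in-silico model of the RNA-annealing /
    RNase T1 protection assay. A synthetic-data generator emulates the
    statistical structure of the experimental data so the whole pipeline is
    testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    dplyr,
    tibble,
    rlang,
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    withr,
    ggplot2
Config/testthat/edition: 3
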