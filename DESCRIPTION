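Package: tgsite
Title: Transgene Integration-Site Discovery and mRNA Decay Quantification
    from Simulated Whole-Genome and FISH Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating a multi-copy transgene's genomic integration
    site from paired-end whole-genome sequencing and for quantifying mRNA
    expression and decay from fluorescence in-situ hybridization (FISH)
    images. The genomics arm covers adapter/quality trimming, a compact
    seed-and-extend read aligner, informative-pair extraction, coverage-gap
    deletion detection, split-read breakpoint resolution with junction
    microhomology, read-depth and delta-delta-Ct copy-number estimation, and
    in-silico PCR confirmation. The imaging arm covers maximum-intensity
    projection, puncta counting, laminar line profiles, region decay ratios,
    and exponential half-life estimation. Synthetic-data generators with
    known ground truth (references, transgenic haplotypes, read pairs, qPCR
    plates, FISH z-stacks, decay series) emulate the study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
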