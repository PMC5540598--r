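Package: tadmod
Title: Hi-C Processing, TAD Detection and Restraint-Based 3D Chromatin
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete toolkit for chromosome conformation capture (Hi-C)
    analysis: restriction-fragment maps and Hi-C-aware FASTQ quality
    control, classification of mapped read pairs by ten ligation-artifact
    criteria, binning into contact matrices with first-mode column masking
    and truncated iterative correction (ICE), replicate comparison by
    per-distance Spearman correlation and leading eigenvectors,
    segmentation of chromosomes into topologically associating domains
    (TADs) by dynamic programming under a BIC-penalised Poisson
    likelihood with a 1-10 border robustness score, alignment of TAD
    borders across experiments, restraint-based 3D modelling of genomic
    regions from z-scored contact frequencies with a simulated-annealing
    optimizer, and structural analysis of the resulting model ensembles
    (clustering, accessibility, density, interactions, angles, chromatin
    colors). Deterministic synthetic-data generators make every stage
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
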