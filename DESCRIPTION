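Package: clonevo
Title: Clonal Selection Dynamics, Barcode Lineage Tracing, and Methylation
    Regions for Experimental Evolution on Engineered Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying clonal evolution of cultured cell
    populations under serial passage on engineered extracellular matrices.
    Implements the deterministic two-clone selection model with nonlinear
    least-squares inference of the initial focal-clone frequency and
    relative fitness from growth-rate trajectories; a DNA-barcode lineage
    tracing pipeline from paired-end amplicon reads (read merging, quality
    filtering, flank-anchored barcode extraction, Levenshtein clustering,
    lineage-retention filters) to clone-dynamics summaries; region-level
    differential-methylation calling from Bismark-style CpG coverage files
    via a binomial generalized linear model likelihood-ratio test; scalar
    phenotype quantification (spreading area, nuclear-to-cytoplasmic
    intensity ratio, RhoA normalization); and a serial-passage clonal
    evolution simulator with multinomial bottlenecks that generates every
    input format the pipeline consumes, with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
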