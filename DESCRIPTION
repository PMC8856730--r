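Package: perimap
Title: Calibrated ChIP-seq and Hi-C Analysis of Loop and Boundary
    Organization at Yeast Pericentromeres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of meiotic chromosome organization from
    spike-in calibrated ChIP-seq and Hi-C data. Implements the occupancy
    ratio (OR) normalization for two-genome calibrated ChIP-seq, oriented
    feature metaprofiles with confidence bands, ChIP-qPCR enrichment from
    delta-Ct, contact-matrix binning and iterative-correction balancing,
    contact probability P(s) versus genomic distance with its log-log
    derivative and a slope-maximum loop-size estimator, mirrored and
    orientation-normalized contact pileups with log2 ratio maps, and
    insulation, dot and stripe scores for boundary strength. A synthetic
    data generator with known ground truth (power-law distance decay,
    positioned loop anchors, insulating boundaries, Poisson sampling,
    two-genome ChIP read counts) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
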