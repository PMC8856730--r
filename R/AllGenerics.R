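#' @rdname GenomeAssembly-class
#' @param x,object an object.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))

#' @rdname ContactMatrix-class
#' @param x a ContactMatrix.
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("isBalanced", function(x) standardGeneric("isBalanced"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("rawCounts", function(x, chrom) standardGeneric("rawCounts"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("balancingWeights", function(x, chrom)
  standardGeneric("balancingWeights"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("validBins", function(x, chrom) standardGeneric("validBins"))

#' Occupancy ratio of a spike-in calibrated ChIP-seq sample
#'
#' Computes \eqn{OR = (W_c \cdot IP_x) / (W_x \cdot IP_c)}, the factor that
#' makes experimental-genome ChIP signal comparable across samples sharing
#' the same calibration spike-in. W denotes input and IP the
#' immunoprecipitate read totals; subscript x the experimental and c the
#' calibration genome.
#'
#' @param sample a [CalibSample-class], or a named numeric vector with
#'   elements Wx, Wc, IPx, IPc.
#' @return The occupancy ratio (dimensionless).
#' @examples
#' occupancyRatio(c(Wx = 1e6, Wc = 2e6, IPx = 3e6, IPc = 1.5e6)) # 4
#' @export
setGeneric("occupancyRatio", function(sample) standardGeneric("occupancyRatio"))

#' @rdname calibrateTrack
#' @export
setGeneric("calibrateTrack", function(sample, or = NULL)
  standardGeneric("calibrateTrack"))

#' @rdname iceBalance
#' @export
setGeneric("iceBalance", function(x, maxIter = 200, tol = 1e-5,
                                  lowCoverageFraction = 0.02)
  standardGeneric("iceBalance"))

#' @rdname cisSubmatrix
#' @export
setGeneric("cisSubmatrix", function(x, chrom, start, end, balanced = TRUE)
  standardGeneric("cisSubmatrix"))

#' @rdname contactProbability
#' @export
setGeneric("contactProbability", function(x, excludeCrossCentromere = TRUE,
                                          binsPerDecade = 16)
  standardGeneric("contactProbability"))

#' @rdname slopeCurve
#' @export
setGeneric("slopeCurve", function(ps, smoothWindow = 3)
  standardGeneric("slopeCurve"))

#' @rdname snipPileup
#' @export
setGeneric("snipPileup", function(x, features, flank, mode = "plain")
  standardGeneric("snipPileup"))

#' @rdname ratioPileup
#' @export
setGeneric("ratioPileup", function(a, b) standardGeneric("ratioPileup"))

#' @rdname insulationScore
#' @export
setGeneric("insulationScore", function(x, chrom, position, window = 20000)
  standardGeneric("insulationScore"))

#' @rdname stripeProfile
#' @export
setGeneric("stripeProfile", function(x, chrom, anchor, maxDistance = 1e5)
  standardGeneric("stripeProfile"))
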