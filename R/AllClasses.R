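#' @import methods
#' @importFrom stats median quantile rgamma rnorm rpois runif sd setNames lm coef
#' @importFrom utils read.table write.table packageVersion
NULL

## ---------------------------------------------------------------------------
## GenomeAssembly
## ---------------------------------------------------------------------------

#' GenomeAssembly: chromosome lengths and centromere intervals
#'
#' The coordinate frame shared by all other objects: an ordered set of
#' chromosomes with lengths (bp) and exactly one centromere interval per
#' chromosome. All coordinates are 0-based, half-open.
#'
#' @slot chromNames character vector of unique chromosome names, in order.
#' @slot chromLengths numeric vector of chromosome lengths (bp), named by
#'   chromosome.
#' @slot centromereStart,centromereEnd numeric vectors (bp, 0-based half-open),
#'   named by chromosome.
#'
#' @seealso [makeGenome()], [centromeres()], [chromLengths()]
#' @export
setClass("GenomeAssembly",
  representation(
    chromNames      = "character",
    chromLengths    = "numeric",
    centromereStart = "numeric",
    centromereEnd   = "numeric"
  )
)

setValidity("GenomeAssembly", function(object) {
  msg <- NULL
  cn <- object@chromNames
  if (anyDuplicated(cn)) msg <- c(msg, "chromosome names must be unique")
  for (slot in c("chromLengths", "centromereStart", "centromereEnd")) {
    v <- slot(object, slot)
    if (length(v) != length(cn) || !identical(names(v), cn))
      msg <- c(msg, sprintf("'%s' must be named by the chromosome names", slot))
  }
  if (is.null(msg)) {
    ok <- object@centromereStart >= 0 &
      object@centromereStart < object@centromereEnd &
      object@centromereEnd <= object@chromLengths
    if (!all(ok))
      msg <- c(msg, paste0(
        "centromere intervals must satisfy 0 <= start < end <= length (",
        paste(cn[!ok], collapse = ", "), ")"))
    if (any(object@chromLengths <= 0))
      msg <- c(msg, "chromosome lengths must be positive")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenomeAssembly
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param centromereStart,centromereEnd named numeric vectors delimiting the
#'   centromere interval of each chromosome (bp, 0-based half-open).
#' @return A [GenomeAssembly-class] object.
#' @examples
#' GenomeAssembly(c(chrI = 2e5), centromereStart = c(chrI = 99500),
#'                centromereEnd = c(chrI = 100500))
#' @export
GenomeAssembly <- function(chromLengths, centromereStart, centromereEnd) {
  cn <- names(chromLengths)
  if (is.null(cn)) stop("'chromLengths' must be named")
  new("GenomeAssembly",
      chromNames = cn,
      chromLengths = chromLengths,
      centromereStart = centromereStart[cn],
      centromereEnd = centromereEnd[cn])
}

## ---------------------------------------------------------------------------
## SyntheticTruth
## ---------------------------------------------------------------------------

#' SyntheticTruth: ground-truth parameters of a simulated contact map
#'
#' Records the generative parameters of [simulateContactMap()] so downstream
#' estimates (loop size, insulation, dot strength) can be checked against
#' known truth.
#'
#' @slot decayExponent positive exponent alpha of the power-law distance decay.
#' @slot loopSize mean anchor spacing L (bp).
#' @slot spacingCV coefficient of variation of anchor gaps (dimensionless).
#' @slot dotStrength fold enrichment (>= 1) applied at consecutive anchor
#'   pairs.
#' @slot stripeStrength fold enrichment (>= 1) extended along one side of each
#'   anchor; 1 disables stripes.
#' @slot boundaryPositions named list (per chromosome) of boundary positions
#'   (bp).
#' @slot boundaryInsulation multiplier in (0, 1] applied to boundary-crossing
#'   contacts.
#' @slot anchorPositions named list (per chromosome) of realized anchor
#'   positions (bp); filled by the simulator.
#' @slot seed integer seed that generated the map.
#' @export
setClass("SyntheticTruth",
  representation(
    decayExponent     = "numeric",
    loopSize          = "numeric",
    spacingCV         = "numeric",
    dotStrength       = "numeric",
    stripeStrength    = "numeric",
    boundaryPositions = "list",
    boundaryInsulation = "numeric",
    anchorPositions   = "list",
    seed              = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- NULL
  if (object@decayExponent <= 0) msg <- c(msg, "decayExponent must be > 0")
  if (object@dotStrength < 1) msg <- c(msg, "dotStrength must be >= 1")
  if (object@stripeStrength < 1) msg <- c(msg, "stripeStrength must be >= 1")
  if (object@boundaryInsulation <= 0 || object@boundaryInsulation > 1)
    msg <- c(msg, "boundaryInsulation must be in (0, 1]")
  if (object@loopSize <= 0) msg <- c(msg, "loopSize must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SyntheticTruth
#'
#' @param decayExponent power-law exponent alpha (> 0); default 1.5.
#' @param loopSize mean anchor spacing (bp); default 10000.
#' @param spacingCV coefficient of variation of the anchor gaps; default 0.1
#'   (a near-regular loop array).
#' @param dotStrength fold enrichment at consecutive anchor pairs (>= 1).
#' @param stripeStrength one-sided stripe fold enrichment (>= 1; 1 = off).
#' @param boundaryPositions named list of per-chromosome boundary positions
#'   (bp), or an empty list for no boundaries.
#' @param boundaryInsulation multiplier in (0, 1] for boundary-crossing
#'   contacts.
#' @param seed integer seed.
#' @return A [SyntheticTruth-class] object.
#' @export
syntheticTruth <- function(decayExponent = 1.5, loopSize = 10000,
                           spacingCV = 0.1, dotStrength = 1,
                           stripeStrength = 1,
                           boundaryPositions = list(),
                           boundaryInsulation = 1, seed = 1L) {
  new("SyntheticTruth",
      decayExponent = decayExponent, loopSize = loopSize,
      spacingCV = spacingCV, dotStrength = dotStrength,
      stripeStrength = stripeStrength,
      boundaryPositions = boundaryPositions,
      boundaryInsulation = boundaryInsulation,
      anchorPositions = list(), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## ContactMatrix
## ---------------------------------------------------------------------------

#' ContactMatrix: binned symmetric cis contact counts
#'
#' Per-chromosome symmetric raw count matrices at a fixed resolution, plus
#' (after [iceBalance()]) per-bin balancing weights and a valid-bin mask.
#' Balanced values are \eqn{b_{ij} = w_i w_j C_{ij}}, defined only where both
#' bins are valid. Raw counts are never modified by balancing.
#'
#' @slot genome the [GenomeAssembly-class] coordinate frame.
#' @slot resolution bin width (bp).
#' @slot counts named list of symmetric integer matrices, one per chromosome.
#' @slot weights named list of per-bin balancing weights (NA where masked);
#'   empty until balanced.
#' @slot validMask named list of per-bin logical vectors.
#' @slot balanced logical flag.
#' @slot transPairs number of inter-chromosomal pairs seen at binning (kept
#'   only as a total).
#' @slot skippedPairs number of input records skipped (unknown chromosome).
#' @export
setClass("ContactMatrix",
  representation(
    genome     = "GenomeAssembly",
    resolution = "numeric",
    counts     = "list",
    weights    = "list",
    validMask  = "list",
    balanced   = "logical",
    transPairs = "numeric",
    skippedPairs = "numeric"
  )
)

setValidity("ContactMatrix", function(object) {
  msg <- NULL
  cn <- object@genome@chromNames
  if (!identical(names(object@counts), cn))
    msg <- c(msg, "'counts' must be named by the genome's chromosomes")
  nb <- nBins(object@genome, object@resolution)
  for (ch in names(object@counts)) {
    m <- object@counts[[ch]]
    if (!is.matrix(m) || nrow(m) != nb[[ch]] || ncol(m) != nb[[ch]]) {
      msg <- c(msg, sprintf("counts[['%s']] has wrong dimensions", ch))
      next
    }
    if (!isSymmetric(unname(m)))
      msg <- c(msg, sprintf("counts[['%s']] is not symmetric", ch))
  }
  if (object@balanced) {
    if (!identical(names(object@weights), cn))
      msg <- c(msg, "balanced matrix must carry weights for every chromosome")
    for (ch in names(object@weights)) {
      w <- object@weights[[ch]]
      v <- object@validMask[[ch]]
      if (length(w) != nb[[ch]] || length(v) != nb[[ch]])
        msg <- c(msg, sprintf("weights/mask[['%s']] have wrong length", ch))
      else if (!identical(is.na(w), !v))
        msg <- c(msg, sprintf(
          "weights[['%s']] must be NA exactly where the bin is masked", ch))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ContactMatrix
#'
#' Low-level constructor; most users will obtain contact matrices from
#' [binPairs()] or [simulateContactMap()].
#'
#' @param genome a [GenomeAssembly-class].
#' @param resolution bin width (bp).
#' @param counts named list of symmetric per-chromosome count matrices.
#' @param weights optional named list of per-bin weights (NA = masked); when
#'   supplied the matrix is marked balanced.
#' @param transPairs,skippedPairs bookkeeping totals.
#' @return A [ContactMatrix-class].
#' @export
ContactMatrix <- function(genome, resolution, counts, weights = NULL,
                          transPairs = 0, skippedPairs = 0) {
  balanced <- !is.null(weights)
  mask <- if (balanced) lapply(weights, function(w) !is.na(w)) else
    lapply(counts, function(m) rep(TRUE, nrow(m)))
  new("ContactMatrix", genome = genome, resolution = resolution,
      counts = counts,
      weights = if (balanced) weights else list(),
      validMask = mask, balanced = balanced,
      transPairs = transPairs, skippedPairs = skippedPairs)
}

## ---------------------------------------------------------------------------
## CalibSample / CalibratedTrack / MetaProfile
## ---------------------------------------------------------------------------

#' CalibSample: spike-in calibrated ChIP-seq read counts
#'
#' Holds the four genome-wide read totals of a spike-in calibrated ChIP-seq
#' sample -- experimental-genome input (Wx), calibration-genome input (Wc),
#' experimental-genome IP (IPx) and calibration-genome IP (IPc) -- together
#' with per-bin experimental-genome IP coverage. The occupancy ratio
#' \eqn{OR = W_c \cdot IP_x / (W_x \cdot IP_c)} is defined when
#' \eqn{W_x > 0} and \eqn{IP_c > 0}.
#'
#' @slot genome the [GenomeAssembly-class] frame of the experimental genome.
#' @slot sampleId sample identifier.
#' @slot totals named numeric vector with elements Wx, Wc, IPx, IPc.
#' @slot binWidth coverage bin width (bp).
#' @slot coverage named list of per-chromosome per-bin IP read counts (NA =
#'   masked bin).
#' @export
setClass("CalibSample",
  representation(
    genome   = "GenomeAssembly",
    sampleId = "character",
    totals   = "numeric",
    binWidth = "numeric",
    coverage = "list"
  )
)

setValidity("CalibSample", function(object) {
  msg <- NULL
  need <- c("Wx", "Wc", "IPx", "IPc")
  if (!all(need %in% names(object@totals)))
    msg <- c(msg, "totals must contain Wx, Wc, IPx, IPc")
  else if (any(object@totals[need] < 0))
    msg <- c(msg, "read totals must be >= 0")
  if (length(object@coverage)) {
    if (!identical(names(object@coverage), object@genome@chromNames))
      msg <- c(msg, "'coverage' must be named by the genome's chromosomes")
    covSum <- sum(unlist(object@coverage), na.rm = TRUE)
    if (all(need %in% names(object@totals)) &&
        abs(covSum - object@totals[["IPx"]]) > 0.5 + 1e-6 * covSum)
      msg <- c(msg, "IPx must equal the sum of the coverage track")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CalibSample
#'
#' @param genome a [GenomeAssembly-class].
#' @param totals named numeric vector with elements Wx, Wc, IPx, IPc.
#' @param coverage named list of per-chromosome per-bin IP read counts; may be
#'   empty when only the occupancy ratio is needed.
#' @param binWidth coverage bin width (bp).
#' @param sampleId sample identifier.
#' @return A [CalibSample-class].
#' @export
CalibSample <- function(genome, totals, coverage = list(), binWidth = 50,
                        sampleId = "sample") {
  new("CalibSample", genome = genome, sampleId = sampleId,
      totals = totals, binWidth = binWidth, coverage = coverage)
}

#' CalibratedTrack: OR-normalized per-bin ChIP signal
#'
#' @slot genome the [GenomeAssembly-class] frame.
#' @slot sampleId sample identifier.
#' @slot binWidth bin width (bp).
#' @slot values named list of per-chromosome calibrated signal (occupancy
#'   units, >= 0; NA = masked).
#' @seealso [calibrateTrack()]
#' @export
setClass("CalibratedTrack",
  representation(
    genome   = "GenomeAssembly",
    sampleId = "character",
    binWidth = "numeric",
    values   = "list"
  )
)

setValidity("CalibratedTrack", function(object) {
  v <- unlist(object@values)
  if (any(v < 0, na.rm = TRUE)) "calibrated values must be >= 0" else TRUE
})

#' MetaProfile: feature-averaged signal with confidence band
#'
#' Mean calibrated signal across features at fixed offsets from the feature
#' midpoints, with the standard error of the mean and a 95% confidence band
#' (mean +/- 1.96 SE).
#'
#' @slot offsets bp relative to feature midpoint.
#' @slot mean,se,ciLow,ciHigh numeric vectors, one value per offset.
#' @slot n number of features contributing at each offset (reduced where
#'   windows were truncated or bins masked).
#' @slot nFeatures number of features requested.
#' @seealso [featureMetaprofile()]
#' @export
setClass("MetaProfile",
  representation(
    offsets   = "numeric",
    mean      = "numeric",
    se        = "numeric",
    ciLow     = "numeric",
    ciHigh    = "numeric",
    n         = "numeric",
    nFeatures = "numeric"
  )
)

setValidity("MetaProfile", function(object) {
  msg <- NULL
  k <- length(object@offsets)
  for (s in c("mean", "se", "ciLow", "ciHigh", "n"))
    if (length(slot(object, s)) != k)
      msg <- c(msg, sprintf("'%s' must have one value per offset", s))
  if (is.null(msg)) {
    ok <- is.na(object@mean) |
      (object@ciLow <= object@mean + 1e-12 &
         object@mean <= object@ciHigh + 1e-12)
    if (!all(ok)) msg <- c(msg, "confidence band must bracket the mean")
    if (any(object@se < 0, na.rm = TRUE)) msg <- c(msg, "se must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## PsCurve
## ---------------------------------------------------------------------------

#' PsCurve: contact probability versus genomic distance
#'
#' Log-binned mean balanced contact per valid pixel as a function of genomic
#' separation, with the pixel count per distance bin and, after
#' [slopeCurve()], the log-log derivative.
#'
#' @slot distances log-spaced distance-bin representatives (bp,
#'   pixel-weighted geometric means), strictly increasing.
#' @slot p mean balanced contact per valid pixel at each distance.
#' @slot nPixels valid pixel count per distance bin.
#' @slot slope d log10(p) / d log10(s) per bin (NA until computed).
#' @slot binsPerDecade log-binning density.
#' @slot resolution matrix resolution (bp) the curve was computed from.
#' @export
setClass("PsCurve",
  representation(
    distances = "numeric",
    p         = "numeric",
    nPixels   = "numeric",
    slope     = "numeric",
    binsPerDecade = "numeric",
    resolution = "numeric"
  )
)

setValidity("PsCurve", function(object) {
  msg <- NULL
  if (is.unsorted(object@distances, strictly = TRUE))
    msg <- c(msg, "distance bins must be strictly increasing")
  if (any(object@p < 0, na.rm = TRUE)) msg <- c(msg, "p must be >= 0")
  if (any(object@nPixels < 0)) msg <- c(msg, "nPixels must be >= 0")
  if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Pileup / RatioPileup
## ---------------------------------------------------------------------------

#' Pileup: feature-centered averaged contact submatrix
#'
#' Element-wise mean of balanced contact-map windows centered on a feature
#' class. Averaging is done in linear space; take log10 only for display.
#' Mirrored pileups contain each feature in both orientations and are exactly
#' symmetric under reversal of both axes.
#'
#' @slot matrix square matrix of mean balanced contacts (NA where no valid
#'   data contributed).
#' @slot nPerPixel number of feature windows contributing per pixel.
#' @slot flank window half-width (bp).
#' @slot resolution bin width (bp).
#' @slot mode one of "plain", "mirrored", "oriented".
#' @slot featureKind feature class the pileup was built from.
#' @slot nFeatures number of features used.
#' @seealso [snipPileup()], [ratioPileup()], [dotScore()]
#' @export
setClass("Pileup",
  representation(
    matrix     = "matrix",
    nPerPixel  = "matrix",
    flank      = "numeric",
    resolution = "numeric",
    mode       = "character",
    featureKind = "character",
    nFeatures  = "numeric"
  )
)

setValidity("Pileup", function(object) {
  msg <- NULL
  if (nrow(object@matrix) != ncol(object@matrix))
    msg <- c(msg, "pileup matrix must be square")
  if (!object@mode %in% c("plain", "mirrored", "oriented"))
    msg <- c(msg, "mode must be plain, mirrored or oriented")
  if (object@mode == "mirrored") {
    m <- object@matrix
    r <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
    if (!identical(unname(m), unname(r)))
      msg <- c(msg, "mirrored pileup must equal its double-axis reversal")
  }
  if (is.null(msg)) TRUE else msg
})

#' RatioPileup: per-pixel log2 ratio of two pileups
#'
#' @slot matrix per-pixel log2(A/B); NA where either input is missing or
#'   non-positive.
#' @slot flank,resolution window geometry, shared by both inputs.
#' @slot mode pileup mode shared by both inputs.
#' @seealso [ratioPileup()]
#' @export
setClass("RatioPileup",
  representation(
    matrix     = "matrix",
    flank      = "numeric",
    resolution = "numeric",
    mode       = "character"
  )
)
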