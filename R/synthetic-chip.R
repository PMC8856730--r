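## Synthetic spike-in calibrated ChIP-seq and ChIP-qPCR data.

#' Simulate two-genome calibrated ChIP-seq read counts
#'
#' Generates the per-bin experimental-genome IP coverage and the four read
#' totals (Wx, Wc, IPx, IPc) of a spike-in calibrated ChIP-seq sample. The
#' per-bin IP material is `background + occupancy * ipEfficiency * kernel`,
#' where the kernel is a Gaussian of width `peakSd` centered at each feature
#' midpoint (height 1 at the center bin).
#'
#' The IP library is sequenced as a competition between experimental and
#' calibration material: a fixed read budget `depthIPx + depthIPc` is split
#' in proportion to the two materials' masses, with the calibration mass
#' chosen so that an occupancy-free sample yields the stated depths exactly.
#' Higher experimental occupancy therefore draws reads away from the
#' calibration genome (lower IPc), exactly the effect the occupancy ratio
#' corrects for -- and what makes the calibrated signal track true
#' occupancy rather than the within-sample read share. Wx and Wc are drawn
#' Poisson at their stated depths; IPx is the realized coverage total
#' (Poisson by additivity, and consistent with the coverage track by
#' construction).
#'
#' @param genome a [GenomeAssembly-class].
#' @param features feature GRanges as from [makeFeatures()].
#' @param occupancy per-feature true occupancy (arbitrary units >= 0);
#'   recycled to the number of features.
#' @param ipEfficiency fold enrichment of occupied sites in the IP (>= 1).
#' @param depthWx,depthWc,depthIPx,depthIPc expected read totals (> 0).
#' @param binWidth coverage bin width (bp); default 50.
#' @param background expected IP reads per bin from unoccupied chromatin
#'   (before depth scaling); default 1.
#' @param peakSd Gaussian peak width (bp); default 100.
#' @param seed integer seed.
#' @param sampleId sample identifier.
#' @return A [CalibSample-class].
#' @export
simulateChipReads <- function(genome, features, occupancy, ipEfficiency = 4,
                              depthWx = 1e6, depthWc = 1e6,
                              depthIPx = 1e6, depthIPc = 1e6,
                              binWidth = 50, background = 1, peakSd = 100,
                              seed = 1L, sampleId = "sim") {
  if (any(c(depthWx, depthWc, depthIPx, depthIPc) <= 0))
    stop("all sequencing depths must be > 0")
  if (ipEfficiency < 1) stop("'ipEfficiency' must be >= 1")
  if (any(occupancy < 0)) stop("'occupancy' must be >= 0")
  if (length(features) == 0 && any(occupancy > 0))
    stop("empty feature list with nonzero occupancy")
  if (length(features)) assertFeatures(features)
  occupancy <- rep_len(occupancy, max(1, length(features)))
  set.seed(as.integer(seed))

  nb <- setNames(as.integer(ceiling(genome@chromLengths / binWidth)),
                 genome@chromNames)
  lambda <- lapply(genome@chromNames, function(ch) {
    rep(background, nb[[ch]])
  })
  names(lambda) <- genome@chromNames
  if (length(features)) {
    mids <- featureMid(features)
    chs <- as.character(seqnames(features))
    for (f in seq_along(features)) {
      ch <- chs[f]
      centers <- (seq_len(nb[[ch]]) - 0.5) * binWidth
      kern <- exp(-(centers - mids[f])^2 / (2 * peakSd^2))
      lambda[[ch]] <- lambda[[ch]] + occupancy[f] * ipEfficiency * kern
    }
  }
  Mx <- sum(unlist(lambda))              # experimental IP material
  Mx0 <- sum(nb) * background            # occupancy-free reference mass
  Mc <- Mx0 * depthIPc / depthIPx        # calibration material
  N <- depthIPx + depthIPc               # IP read budget
  lambda <- lapply(lambda, function(v) v * N / (Mx + Mc))

  coverage <- lapply(lambda, function(v) rpois(length(v), v))
  totals <- c(Wx = as.numeric(rpois(1, depthWx)),
              Wc = as.numeric(rpois(1, depthWc)),
              IPx = as.numeric(sum(unlist(coverage))),
              IPc = as.numeric(rpois(1, N * Mc / (Mx + Mc))))
  CalibSample(genome, totals, coverage, binWidth, sampleId)
}

## expected calibrated signal at a feature's center bin, from the generative
## parameters (closed-form oracle used by tests)
expectedCalibratedPeak <- function(genome, features, occupancy, ipEfficiency,
                                   depthWx, depthWc, depthIPx, depthIPc,
                                   binWidth = 50, background = 1,
                                   peakSd = 100) {
  nb <- setNames(as.integer(ceiling(genome@chromLengths / binWidth)),
                 genome@chromNames)
  occupancy <- rep_len(occupancy, length(features))
  mids <- featureMid(features)
  chs <- as.character(seqnames(features))
  peak <- numeric(length(features))
  for (f in seq_along(features)) {
    cbin <- floor(mids[f] / binWidth) + 1
    cc <- (cbin - 0.5) * binWidth
    peak[f] <- background + occupancy[f] * ipEfficiency *
      exp(-(cc - mids[f])^2 / (2 * peakSd^2))
  }
  ## with the sequencing-competition model the read budget and material
  ## totals cancel: E[calibrated] = m_peak * Wc / (Wx * Mc)
  Mc <- sum(nb) * background * depthIPc / depthIPx
  peak * depthWc / (depthWx * Mc)
}

#' Write and read the ground-truth sidecar of a simulated map
#'
#' Serializes a [SyntheticTruth-class] as JSON alongside the map files it
#' describes, so downstream recovery checks can reload the generative
#' parameters without the R session.
#'
#' @param truth a [SyntheticTruth-class].
#' @param path JSON file path.
#' @export
writeTruthJSON <- function(truth, path) {
  jsonlite::write_json(list(
    decayExponent = truth@decayExponent, loopSize = truth@loopSize,
    spacingCV = truth@spacingCV, dotStrength = truth@dotStrength,
    stripeStrength = truth@stripeStrength,
    boundaryPositions = truth@boundaryPositions,
    boundaryInsulation = truth@boundaryInsulation,
    anchorPositions = truth@anchorPositions, seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthJSON
#' @return `readTruthJSON`: a [SyntheticTruth-class].
#' @export
readTruthJSON <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- syntheticTruth(
    decayExponent = d$decayExponent, loopSize = d$loopSize,
    spacingCV = d$spacingCV, dotStrength = d$dotStrength,
    stripeStrength = d$stripeStrength,
    boundaryPositions = as.list(d$boundaryPositions),
    boundaryInsulation = d$boundaryInsulation, seed = d$seed)
  tr@anchorPositions <- as.list(d$anchorPositions)
  tr
}

#' Simulate a ChIP-qPCR Ct pair with known enrichment
#'
#' Constructs threshold-cycle values whose [qpcrEnrichment()] is exactly
#' `trueEnrichment` when `noiseSd = 0`: the input Ct is `baseCt` and the
#' ChIP Ct is offset by `-log_E(dilution) - log_E(trueEnrichment)` where E
#' is the primer efficiency. Gaussian cycle noise of SD `noiseSd` is added
#' independently to both Ct values.
#'
#' @param trueEnrichment ChIP/Input enrichment to encode (> 0).
#' @param primerEfficiency amplification factor per cycle, in (1, 2].
#' @param inputDilution dilution factor applied to the input before qPCR
#'   (>= 1).
#' @param baseCt input threshold cycle (cycles); default 20.
#' @param noiseSd Gaussian Ct noise (cycles); default 0.
#' @param seed integer seed (used only when `noiseSd > 0`).
#' @return Named numeric vector with elements `ctChip` and `ctInput`.
#' @examples
#' ct <- simulateQpcr(0.01, primerEfficiency = 2)
#' unname(ct["ctChip"] - ct["ctInput"]) # log2(100) = 6.644
#' @export
simulateQpcr <- function(trueEnrichment, primerEfficiency = 2,
                         inputDilution = 1, baseCt = 20, noiseSd = 0,
                         seed = 1L) {
  if (trueEnrichment <= 0) stop("'trueEnrichment' must be > 0")
  if (primerEfficiency <= 1 || primerEfficiency > 2)
    stop("'primerEfficiency' must be in (1, 2]")
  if (inputDilution < 1) stop("'inputDilution' must be >= 1")
  logE <- function(x) log(x) / log(primerEfficiency)
  ctInput <- baseCt
  ctChip <- ctInput - logE(inputDilution) - logE(trueEnrichment)
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    ctChip <- ctChip + rnorm(1, 0, noiseSd)
    ctInput <- ctInput + rnorm(1, 0, noiseSd)
  }
  c(ctChip = ctChip, ctInput = ctInput)
}
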