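## Synthetic Hi-C contact maps with known ground truth.
##
## Expected count model, per chromosome and bin pair (i, j):
##   E[i,j] = k * d_ij^(-alpha) * insul(i,j) * dot(i,j) * stripe(i,j)
## with d_ij the bin-midpoint separation (d = resolution/2 on the diagonal),
## insul = boundaryInsulation^(number of boundaries between i and j),
## dot a Gaussian blob of fold `dotStrength` centered on each consecutive
## anchor pair, and stripe an optional one-sided band along each anchor.
## k scales the total upper-triangle expectation to `depth`. Observed counts
## are Poisson(E), drawn for i <= j and mirrored.

## anchor positions for one chromosome: sequential gaps ~ Gamma(mean L,
## CV spacingCV), clipped below at 2 * resolution
placeAnchors <- function(chromLength, loopSize, spacingCV, resolution) {
  minGap <- 2 * resolution
  pos <- runif(1, 0, loopSize)
  anchors <- numeric(0)
  while (pos < chromLength) {
    anchors <- c(anchors, pos)
    g <- if (spacingCV <= 0) loopSize else {
      shape <- 1 / spacingCV^2
      rgamma(1, shape = shape, rate = shape / loopSize)
    }
    pos <- pos + max(g, minGap)
  }
  anchors
}

## expectation matrix (unscaled) for one chromosome
expectationMatrix <- function(nb, resolution, truth, anchors, boundaries) {
  idx <- seq_len(nb)
  d <- abs(outer(idx, idx, "-")) * resolution
  diag(d) <- resolution / 2
  E <- d^(-truth@decayExponent)

  if (truth@boundaryInsulation < 1 && length(boundaries)) {
    mids <- (idx - 0.5) * resolution
    nLeft <- vapply(mids, function(m) sum(boundaries <= m), numeric(1))
    cross <- abs(outer(nLeft, nLeft, "-"))
    E <- E * truth@boundaryInsulation^cross
  }

  abin <- floor(anchors / resolution) + 1
  abin <- abin[abin >= 1 & abin <= nb]
  if (truth@dotStrength > 1 && length(abin) >= 2) {
    r <- 3L
    off <- -r:r
    w <- exp(-(off^2) / 2)  # sigma = 1 bin
    for (k in seq_len(length(abin) - 1)) {
      ii <- abin[k] + off
      jj <- abin[k + 1] + off
      oi <- ii >= 1 & ii <= nb
      oj <- jj >= 1 & jj <= nb
      fac <- 1 + (truth@dotStrength - 1) * outer(w[oi], w[oj])
      E[ii[oi], jj[oj]] <- E[ii[oi], jj[oj]] * fac
      E[jj[oj], ii[oi]] <- E[jj[oj], ii[oi]] * t(fac)
    }
  }

  if (truth@stripeStrength > 1 && length(abin) >= 1) {
    ## one-sided stripe: from each anchor toward increasing coordinates,
    ## up to the next anchor (or 2 * loopSize)
    ext <- ceiling(2 * truth@loopSize / resolution)
    for (k in seq_along(abin)) {
      jmax <- if (k < length(abin)) abin[k + 1] - 1 else
        min(nb, abin[k] + ext)
      jmax <- min(jmax, abin[k] + ext, nb)
      if (jmax > abin[k]) {
        jj <- (abin[k] + 1):jmax
        E[abin[k], jj] <- E[abin[k], jj] * truth@stripeStrength
        E[jj, abin[k]] <- E[jj, abin[k]] * truth@stripeStrength
      }
    }
  }
  E
}

#' Simulate a binned Hi-C contact map with known truth
#'
#' Generates per-chromosome cis contact maps from a power-law distance-decay
#' background with positioned loop anchors (dots between consecutive
#' anchors), optional insulating boundaries and optional one-sided stripes,
#' then draws Poisson counts at the requested sequencing depth. The
#' expectation is scaled so the total expected cis count (upper triangle,
#' diagonal included) equals `depth` exactly.
#'
#' @param genome a [GenomeAssembly-class].
#' @param truth a [SyntheticTruth-class] holding the generative parameters.
#' @param resolution bin width (bp); must be at most `loopSize/2` so loops
#'   are resolvable.
#' @param depth total expected cis count summed over all chromosomes.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param sample draw Poisson counts (default). With `sample = FALSE` the
#'   scaled expectation matrix itself is returned (non-integer "counts"),
#'   which serves as a noise-free oracle for estimator checks.
#' @return A list with elements `map` (a [ContactMatrix-class], unbalanced)
#'   and `truth` (the input truth with realized `anchorPositions` filled in).
#' @examples
#' g <- makeGenome(1, 3e5, 0.5)
#' tr <- syntheticTruth(loopSize = 2e4, dotStrength = 4)
#' sim <- simulateContactMap(g, tr, resolution = 1000, depth = 1e5, seed = 1)
#' sum(rawCounts(sim$map, "chr01")) > 0
#' @export
simulateContactMap <- function(genome, truth, resolution, depth, seed = 1L,
                               sample = TRUE) {
  if (depth <= 0) stop("'depth' must be > 0")
  if (resolution <= 0) stop("'resolution' must be > 0")
  if (resolution > truth@loopSize / 2)
    stop("resolution > loopSize/2: loops would be unresolvable")
  set.seed(as.integer(seed))
  nb <- nBins(genome, resolution)

  anchorList <- list()
  Es <- list()
  for (ch in genome@chromNames) {
    anchors <- placeAnchors(genome@chromLengths[[ch]], truth@loopSize,
                            truth@spacingCV, resolution)
    anchorList[[ch]] <- anchors
    bnd <- truth@boundaryPositions[[ch]]
    if (is.null(bnd)) bnd <- numeric(0)
    Es[[ch]] <- expectationMatrix(nb[[ch]], resolution, truth, anchors, bnd)
  }

  ## scale total upper-triangle expectation (diagonal included) to depth
  tot <- sum(vapply(Es, function(E) {
    sum(E[upper.tri(E, diag = TRUE)])
  }, numeric(1)))
  k <- depth / tot

  counts <- lapply(Es, function(E) {
    E <- E * k
    if (sample) {
      n <- nrow(E)
      ut <- upper.tri(E, diag = TRUE)
      M <- matrix(0, n, n)
      M[ut] <- rpois(sum(ut), E[ut])
      M[lower.tri(M)] <- t(M)[lower.tri(M)]
      M
    } else {
      E
    }
  })

  truth@anchorPositions <- anchorList
  truth@seed <- as.integer(seed)
  list(map = ContactMatrix(genome, resolution, counts), truth = truth)
}
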