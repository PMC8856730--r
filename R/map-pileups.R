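## Feature-centered contact pileups, ratio maps, and boundary/dot/stripe
## scores.

setMethod("show", "Pileup", function(object) {
  cat(sprintf(
    "Pileup (%s, %s): %dx%d pixels, flank %g bp at %g bp, %d feature(s)\n",
    object@featureKind, object@mode, nrow(object@matrix),
    ncol(object@matrix), object@flank, object@resolution,
    object@nFeatures))
})

setMethod("show", "RatioPileup", function(object) {
  cat(sprintf("RatioPileup (%s): %dx%d pixels, flank %g bp at %g bp\n",
              object@mode, nrow(object@matrix), ncol(object@matrix),
              object@flank, object@resolution))
})

## accumulate one window into running sum/count, skipping NAs
addWindow <- function(acc, M) {
  ok <- !is.na(M)
  acc$sum[ok] <- acc$sum[ok] + M[ok]
  acc$n[ok] <- acc$n[ok] + 1
  acc
}

## balanced window of half-width hw bins centered at bin (ci, cj);
## out-of-chromosome pixels are NA
snipWindow <- function(B, ci, cj, hw) {
  n <- nrow(B)
  ii <- (ci - hw):(ci + hw)
  jj <- (cj - hw):(cj + hw)
  M <- matrix(NA_real_, 2 * hw + 1, 2 * hw + 1)
  oi <- ii >= 1 & ii <= n
  oj <- jj >= 1 & jj <= n
  M[oi, oj] <- B[ii[oi], jj[oj]]
  M
}

#' Feature-centered contact pileup
#'
#' Averages balanced cis windows of `midpoint +/- flank` over a feature set,
#' in linear space (take log10 for display only). Three modes:
#' \describe{
#'   \item{plain}{each feature contributes its window as-is.}
#'   \item{mirrored}{each feature contributes twice, once as-is and once
#'     with both axes reversed; the result is exactly symmetric under
#'     double-axis reversal (used for centromeres, which have no
#'     orientation).}
#'   \item{oriented}{features with `armSide == "right"` are axis-reversed so
#'     the centromere-proximal flank always maps to the lower-right and the
#'     arm flank to the upper-left corner (used for pericentromere
#'     borders).}
#' }
#' Windows reaching past a chromosome end are clipped (reduced per-pixel n);
#' masked bins are skipped per pixel with n tracked.
#'
#' @param x a balanced [ContactMatrix-class].
#' @param features feature GRanges as from [makeFeatures()].
#' @param flank half-window (bp); a multiple of the matrix resolution.
#' @param mode "plain", "mirrored" or "oriented".
#' @return A [Pileup-class].
#' @rdname snipPileup
#' @export
setMethod("snipPileup", "ContactMatrix",
          function(x, features, flank, mode = "plain") {
  assertFeatures(features)
  mode <- match.arg(mode, c("plain", "mirrored", "oriented"))
  if (!x@balanced) stop("matrix is not balanced; run iceBalance() first")
  res <- x@resolution
  if (flank %% res != 0)
    stop("'flank' must be a multiple of the matrix resolution")
  hw <- as.integer(flank / res)
  sz <- 2L * hw + 1L

  chs <- as.character(seqnames(features))
  known <- chs %in% x@genome@chromNames
  if (!all(known)) {
    warning(sprintf("%d feature(s) on chromosomes absent from the matrix %s",
                    sum(!known), "skipped"))
    features <- features[known]
    chs <- chs[known]
  }
  if (length(features) == 0) stop("no usable features")

  acc <- list(sum = matrix(0, sz, sz), n = matrix(0, sz, sz))
  Bcache <- list()
  mids <- featureMid(features)
  side <- features$armSide
  rv <- rev(seq_len(sz))
  for (f in seq_along(features)) {
    ch <- chs[f]
    if (is.null(Bcache[[ch]])) Bcache[[ch]] <- balancedMatrix(x, ch)
    cbin <- floor(mids[f] / res) + 1
    M <- snipWindow(Bcache[[ch]], cbin, cbin, hw)
    if (mode == "mirrored") {
      ## symmetrize per feature before accumulating: pixel (i,j) and its
      ## double-axis mirror then receive bitwise-identical additions, so
      ## the pileup is exactly symmetric by construction
      Mr <- M[rv, rv]
      ok1 <- !is.na(M); ok2 <- !is.na(Mr)
      Ms <- matrix(0, sz, sz)
      Ms[ok1] <- Ms[ok1] + M[ok1]
      Ms[ok2] <- Ms[ok2] + Mr[ok2]
      nS <- ok1 + ok2
      Ms[nS == 0] <- NA_real_
      acc$sum[nS > 0] <- acc$sum[nS > 0] + Ms[nS > 0]
      acc$n <- acc$n + nS
    } else if (mode == "oriented" && !is.na(side[f]) &&
               side[f] == "right") {
      acc <- addWindow(acc, M[rv, rv])
    } else {
      acc <- addWindow(acc, M)
    }
  }
  mean <- acc$sum / acc$n
  mean[acc$n == 0] <- NA_real_
  kinds <- unique(features$kind)
  new("Pileup", matrix = mean, nPerPixel = acc$n, flank = flank,
      resolution = res, mode = mode,
      featureKind = paste(kinds, collapse = "+"),
      nFeatures = length(features))
})

#' Pileup centered on consecutive anchor pairs (dot pileup)
#'
#' Averages windows centered on the off-diagonal pixel (a_k, a_(k+1)) of
#' each consecutive anchor pair, putting the loop-anchor dot at the center
#' pixel. Used with [dotScore()] to quantify positioned-loop strength.
#'
#' @param x a balanced [ContactMatrix-class].
#' @param anchors named list (per chromosome) of anchor positions (bp), as
#'   in the `anchorPositions` slot of a [SyntheticTruth-class].
#' @param flank half-window (bp); a multiple of the matrix resolution.
#' @return A [Pileup-class] with mode "plain" and featureKind "anchorPair".
#' @export
anchorPairPileup <- function(x, anchors, flank) {
  if (!x@balanced) stop("matrix is not balanced; run iceBalance() first")
  res <- x@resolution
  if (flank %% res != 0)
    stop("'flank' must be a multiple of the matrix resolution")
  hw <- as.integer(flank / res)
  sz <- 2L * hw + 1L
  acc <- list(sum = matrix(0, sz, sz), n = matrix(0, sz, sz))
  nPairs <- 0
  for (ch in intersect(names(anchors), x@genome@chromNames)) {
    a <- sort(anchors[[ch]])
    if (length(a) < 2) next
    B <- balancedMatrix(x, ch)
    abin <- floor(a / res) + 1
    for (k in seq_len(length(abin) - 1)) {
      acc <- addWindow(acc, snipWindow(B, abin[k], abin[k + 1], hw))
      nPairs <- nPairs + 1
    }
  }
  if (nPairs == 0) stop("no anchor pairs")
  mean <- acc$sum / acc$n
  mean[acc$n == 0] <- NA_real_
  new("Pileup", matrix = mean, nPerPixel = acc$n, flank = flank,
      resolution = res, mode = "plain", featureKind = "anchorPair",
      nFeatures = nPairs)
}

#' Log2 ratio of two pileups
#'
#' Per-pixel log2(A/B) of two pileups on identical grids (same flank,
#' resolution and mode). Pixels where either input is missing or
#' non-positive are NA. The result negates exactly under swapping A and B.
#'
#' @param a,b [Pileup-class] objects with identical geometry.
#' @return A [RatioPileup-class].
#' @rdname ratioPileup
#' @export
setMethod("ratioPileup", signature("Pileup", "Pileup"), function(a, b) {
  if (a@flank != b@flank || a@resolution != b@resolution ||
      a@mode != b@mode || !all(dim(a@matrix) == dim(b@matrix)))
    stop("pileups have mismatched geometry (flank/resolution/mode)")
  ## computed as a difference of logs so swapping A and B negates the
  ## matrix bitwise
  r <- log2(a@matrix) - log2(b@matrix)
  r[!is.finite(r)] <- NA_real_
  new("RatioPileup", matrix = r, flank = a@flank,
      resolution = a@resolution, mode = a@mode)
})

#' Insulation score at a position
#'
#' log2 of the mean balanced contact among pixel pairs crossing the position
#' over the mean among same-side pairs at matched genomic distances, both
#' restricted to `window` bp on each side. 0 means no insulation; more
#' negative means stronger insulation (a boundary letting through a
#' fraction m of contacts scores ~log2 m).
#'
#' @param x a balanced [ContactMatrix-class].
#' @param chrom chromosome name.
#' @param position boundary position (bp).
#' @param window half-window (bp); default 20000.
#' @return The score (dimensionless), or NA with a warning when fewer than
#'   10 valid pixels exist in either class.
#' @rdname insulationScore
#' @export
setMethod("insulationScore", "ContactMatrix",
          function(x, chrom, position, window = 20000) {
  ch <- matchChrom(x, chrom)
  if (!x@balanced) stop("matrix is not balanced; run iceBalance() first")
  res <- x@resolution
  wB <- as.integer(window / res)
  p <- floor(position / res) + 1
  n <- nrow(x@counts[[ch]])
  if (p - wB < 1 || p + wB > n)
    stop("window does not fit on both sides of the position")
  B <- balancedMatrix(x, ch)

  ## distances (in bins) present in both classes: cross pairs straddling p
  ## exist for d >= 2; same-side pairs within a wB-sized block for
  ## d <= wB - 1
  ## per-distance means, combined with equal weight per distance in both
  ## classes, so the two classes' different distance mixes cannot bias the
  ## ratio (at constant per-distance ratio r the score is exactly log2 r)
  crossMeans <- sameMeans <- numeric(0)
  crossN <- sameN <- 0
  for (d in 2:(wB - 1)) {
    ## cross: i < p < j, j - i = d, within the window
    i <- max(p - wB, p - d + 1):(p - 1)
    j <- i + d
    keep <- j > p & j <= p + wB
    vc <- B[cbind(i[keep], j[keep])]
    ## same side: both in [p-wB, p-1] or both in [p+1, p+wB]
    iL <- (p - wB):(p - 1 - d); vL <- B[cbind(iL, iL + d)]
    iR <- (p + 1):(p + wB - d); vR <- B[cbind(iR, iR + d)]
    vs <- c(vL, vR)
    if (all(is.na(vc)) || all(is.na(vs))) next
    crossMeans <- c(crossMeans, mean(vc, na.rm = TRUE))
    sameMeans <- c(sameMeans, mean(vs, na.rm = TRUE))
    crossN <- crossN + sum(!is.na(vc))
    sameN <- sameN + sum(!is.na(vs))
  }
  if (crossN < 10 || sameN < 10) {
    warning("insufficient valid pixels for insulation score")
    return(NA_real_)
  }
  log2(sum(crossMeans) / sum(sameMeans))
})

#' Dot strength of a pileup
#'
#' Mean of the central `centerSize`^2 pixels divided by the mean of flanking
#' pixels at the same genomic-separation band (two strips along the diagonal
#' direction at Chebyshev radius `(centerSize-1)/2 + ringGap` to `+
#' ringWidth`, keeping only pixels whose separation offset is within the
#' center's). Values > 1 indicate a positioned dot at the center.
#'
#' @param pileup a [Pileup-class] large enough for the center plus ring.
#' @param centerSize central square side (pixels, odd); default 3.
#' @param ringGap gap between center and ring (pixels); default 3.
#' @param ringWidth ring thickness (pixels); default 5.
#' @return Fold enrichment (dimensionless); NA when the center or ring is
#'   fully masked.
#' @export
dotScore <- function(pileup, centerSize = 3, ringGap = 3, ringWidth = 5) {
  M <- pileup@matrix
  sz <- nrow(M)
  r0 <- (centerSize - 1L) / 2
  need <- r0 + ringGap + ringWidth
  if ((sz - 1) / 2 < need)
    stop("pileup too small for the requested center + ring")
  c0 <- (sz + 1L) / 2
  di <- row(M) - c0
  dj <- col(M) - c0
  cheb <- pmax(abs(di), abs(dj))
  center <- cheb <= r0
  ring <- cheb > r0 + ringGap & cheb <= need & abs(di - dj) <= 2 * r0
  cm <- mean(M[center], na.rm = TRUE)
  rm_ <- mean(M[ring], na.rm = TRUE)
  if (!is.finite(cm) || !is.finite(rm_)) return(NA_real_)
  cm / rm_
}

#' Contact profile along the stripe emanating from an anchor
#'
#' Mean balanced contact between the anchor (a 3-bin-thick band around the
#' anchor bin) and positions at increasing distance, separately for each
#' direction along the chromosome. An elevated profile on one side relative
#' to the matched-distance background indicates a one-sided stripe (loop
#' extrusion anchored at one side).
#'
#' @param x a balanced [ContactMatrix-class].
#' @param chrom chromosome name.
#' @param anchor anchor position (bp); its bin must be valid.
#' @param maxDistance maximum distance (bp); truncated with a warning at the
#'   chromosome end.
#' @return A data.frame with columns `distance`, `left`, `right` (mean
#'   balanced contact toward lower/higher coordinates).
#' @rdname stripeProfile
#' @export
setMethod("stripeProfile", "ContactMatrix",
          function(x, chrom, anchor, maxDistance = 1e5) {
  ch <- matchChrom(x, chrom)
  if (!x@balanced) stop("matrix is not balanced; run iceBalance() first")
  res <- x@resolution
  a <- floor(anchor / res) + 1
  n <- nrow(x@counts[[ch]])
  if (a < 1 || a > n) stop("anchor outside chromosome")
  if (!x@validMask[[ch]][a]) stop("anchor bin is masked")
  B <- balancedMatrix(x, ch)
  kMax <- as.integer(maxDistance / res)
  if (a + kMax > n || a - kMax < 1) {
    kMax <- min(n - a, a - 1)
    warning("profile truncated at chromosome end")
  }
  band <- max(1, a - 1):min(n, a + 1)
  left <- right <- rep(NA_real_, kMax)
  for (k in seq_len(kMax)) {
    if (a - k >= 1) left[k] <- mean(B[band, a - k], na.rm = TRUE)
    if (a + k <= n) right[k] <- mean(B[band, a + k], na.rm = TRUE)
  }
  data.frame(distance = seq_len(kMax) * res, left = left, right = right)
})

#' Write a pileup (or ratio pileup) as dense TSV with a JSON sidecar
#'
#' The matrix goes to `<path>` as headerless TSV; geometry metadata (mode,
#' flank, resolution, n features) goes to `<path>.json`.
#'
#' @param pileup a [Pileup-class] or [RatioPileup-class].
#' @param path output TSV path.
#' @export
writePileupTSV <- function(pileup, path) {
  write.table(pileup@matrix, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(mode = pileup@mode, flank = pileup@flank,
               resolution = pileup@resolution)
  if (is(pileup, "Pileup")) {
    meta$featureKind <- pileup@featureKind
    meta$nFeatures <- pileup@nFeatures
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
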