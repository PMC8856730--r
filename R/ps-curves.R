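## Contact probability P(s), its log-log derivative, and the slope-maximum
## loop-size estimate.

setMethod("show", "PsCurve", function(object) {
  hasSlope <- any(!is.na(object@slope))
  cat(sprintf(
    "PsCurve: %d distance bins (%g..%g bp, %g/decade), slope %s\n",
    length(object@distances), min(object@distances), max(object@distances),
    object@binsPerDecade, if (hasSlope) "computed" else "not computed"))
})

#' Contact probability versus genomic distance
#'
#' For every cis pixel (i, j) with both bins valid, the balanced contact
#' value is accumulated into the log-spaced distance bin of the bin-midpoint
#' separation; `p` is the mean balanced value per valid pixel in each bin,
#' pooled across chromosomes (sums of values and of pixel counts, not
#' per-chromosome averages). With `excludeCrossCentromere` the pixels whose
#' bins lie on opposite sides of the centromere interval -- and pixels
#' involving bins inside the interval -- are excluded, so only same-arm
#' contacts contribute.
#'
#' @param x a balanced [ContactMatrix-class].
#' @param excludeCrossCentromere drop contacts across (or within) the
#'   centromere interval; default TRUE.
#' @param binsPerDecade density of the log-spaced distance bins; default 16.
#' @return A [PsCurve-class] (slope not yet filled; see [slopeCurve()]).
#' @rdname contactProbability
#' @export
setMethod("contactProbability", "ContactMatrix",
          function(x, excludeCrossCentromere = TRUE, binsPerDecade = 16) {
  if (!x@balanced) stop("matrix is not balanced; run iceBalance() first")
  res <- x@resolution
  g <- x@genome

  maxOff <- max(vapply(x@counts, nrow, integer(1))) - 1
  binOf <- function(k) floor(log10(k) * binsPerDecade) + 1L  # k in bins
  nBinsTot <- binOf(maxOff) + 1L
  sumV <- numeric(nBinsTot)
  sumN <- numeric(nBinsTot)
  sumLogD <- numeric(nBinsTot)

  for (ch in g@chromNames) {
    B <- balancedMatrix(x, ch)
    n <- nrow(B)
    valid <- x@validMask[[ch]]
    mids <- (seq_len(n) - 0.5) * res
    side <- rep(0L, n)                       # 0 = inside centromere
    side[mids < g@centromereStart[[ch]]] <- 1L
    side[mids >= g@centromereEnd[[ch]]] <- 2L
    for (k in seq_len(n - 1)) {
      i <- seq_len(n - k)
      j <- i + k
      keep <- valid[i] & valid[j]
      if (excludeCrossCentromere)
        keep <- keep & side[i] != 0L & side[i] == side[j]
      if (!any(keep)) next
      v <- B[cbind(i[keep], j[keep])]
      b <- binOf(k)
      sumV[b] <- sumV[b] + sum(v)
      sumN[b] <- sumN[b] + length(v)
      sumLogD[b] <- sumLogD[b] + length(v) * log(k * res)
    }
  }

  keep <- sumN > 0
  new("PsCurve",
      distances = exp(sumLogD[keep] / sumN[keep]),
      p = sumV[keep] / sumN[keep],
      nPixels = sumN[keep],
      slope = rep(NA_real_, sum(keep)),
      binsPerDecade = binsPerDecade,
      resolution = res)
})

## sliding-window least-squares slope of y against x (exact for linear y)
slidingSlope <- function(y, x, window) {
  h <- window %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    idx <- idx[is.finite(y[idx])]
    if (length(idx) < 2L) return(NA_real_)
    xc <- x[idx] - mean(x[idx])
    sum(xc * y[idx]) / sum(xc * xc)
  }, numeric(1))
}

#' Log-log derivative (slope) of a P(s) curve
#'
#' The slope d log10(p) / d log10(s) is estimated per distance bin as the
#' least-squares slope of log10(p) against log10(s) in a centered window of
#' `smoothWindow` bins, which is exact on a power law regardless of the
#' (uneven) log-bin spacing and averages sampling noise. Endpoints use the
#' truncated one-sided window. Bins with p = 0 carry NA.
#'
#' @param ps a [PsCurve-class].
#' @param smoothWindow window width in distance bins (odd); default 3.
#' @return The [PsCurve-class] with the slope filled.
#' @rdname slopeCurve
#' @export
setMethod("slopeCurve", "PsCurve", function(ps, smoothWindow = 3) {
  lp <- ifelse(ps@p > 0, log10(ps@p), NA_real_)
  if (sum(is.finite(lp)) < smoothWindow)
    stop(sprintf("fewer than %d nonzero distance bins", smoothWindow))
  ls <- log10(ps@distances)
  ps@slope <- slidingSlope(lp, ls, smoothWindow)
  ps
})

#' Loop-size estimate from the slope maximum
#'
#' Returns the distance-bin representative at the maximum of the slope curve
#' within `searchRange` (ties broken toward smaller distances). A local
#' enrichment of contacts at the typical anchor spacing lifts the slope
#' there, so the maximum position tracks the average loop size. When the
#' slope curve has no substantial interior peak -- its maximum exceeds the
#' in-range median by less than `prominence` -- the estimate is still
#' returned but flagged `noPeak`.
#'
#' @param ps a [PsCurve-class] with the slope computed.
#' @param searchRange distance interval (bp) searched; default (3000,
#'   200000).
#' @param prominence minimum (max - median) slope excess, in slope units,
#'   for a peak call; default 0.05.
#' @return A list with `estimate` (bp), `slopeAtMax`, and `noPeak` (logical).
#' @export
loopSizeEstimate <- function(ps, searchRange = c(3000, 200000),
                             prominence = 0.05) {
  if (all(is.na(ps@slope)))
    stop("slope not computed; run slopeCurve() first")
  ok <- which(ps@distances >= searchRange[1] &
                ps@distances <= searchRange[2] & !is.na(ps@slope))
  if (length(ok) < 3) stop("search range covers too few distance bins")
  sl <- ps@slope[ok]
  iMax <- ok[which.max(sl)]              # which.max: first = smallest s
  noPeak <- (max(sl) - median(sl)) < prominence
  if (noPeak)
    warning("no interior slope maximum detected (no-peak flag set)")
  list(estimate = ps@distances[iMax],
       slopeAtMax = ps@slope[iMax],
       noPeak = noPeak)
}

#' Single-number log-log slope over a distance range
#'
#' Ordinary least-squares slope of log10(p) on log10(s) over `[from, to]`;
#' a convenience summary used to compare a map against a pure power-law
#' reference.
#'
#' @param ps a [PsCurve-class].
#' @param from,to distance range (bp).
#' @return The fitted slope (dimensionless).
#' @export
fitPsSlope <- function(ps, from, to) {
  keep <- ps@distances >= from & ps@distances <= to & ps@p > 0
  if (sum(keep) < 2) stop("fewer than 2 usable bins in range")
  x <- log10(ps@distances[keep])
  y <- log10(ps@p[keep])
  unname(coef(lm(y ~ x))[2])
}

#' Write a P(s) curve as TSV
#'
#' Columns: distance, p, n_pixels, slope.
#'
#' @param ps a [PsCurve-class].
#' @param path output file.
#' @export
writePsCurveTSV <- function(ps, path) {
  write.table(
    data.frame(distance = ps@distances, p = ps@p,
               n_pixels = ps@nPixels, slope = ps@slope),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
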