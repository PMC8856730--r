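#' @importFrom data.table fread fwrite
NULL

#' @describeIn ContactMatrix-class bin width (bp).
#' @export
setMethod("resolution", "ContactMatrix", function(x) x@resolution)

#' @describeIn ContactMatrix-class whether balancing weights are available.
#' @export
setMethod("isBalanced", "ContactMatrix", function(x) x@balanced)

#' @describeIn ContactMatrix-class raw symmetric count matrix of one
#'   chromosome (never modified by balancing).
#' @param chrom chromosome name.
#' @export
setMethod("rawCounts", "ContactMatrix", function(x, chrom) {
  x@counts[[matchChrom(x, chrom)]]
})

#' @describeIn ContactMatrix-class per-bin balancing weights (NA = masked).
#' @export
setMethod("balancingWeights", "ContactMatrix", function(x, chrom) {
  if (!x@balanced) stop("matrix is not balanced; run iceBalance() first")
  x@weights[[matchChrom(x, chrom)]]
})

#' @describeIn ContactMatrix-class per-bin logical valid mask.
#' @export
setMethod("validBins", "ContactMatrix", function(x, chrom) {
  x@validMask[[matchChrom(x, chrom)]]
})

setMethod("show", "ContactMatrix", function(object) {
  tot <- sum(vapply(object@counts, function(m)
    sum(m[upper.tri(m, diag = TRUE)]), numeric(1)))
  cat(sprintf("ContactMatrix: %d chromosome(s) at %g bp, %.4g cis pairs, %s\n",
              length(object@counts), object@resolution, tot,
              if (object@balanced) "balanced" else "raw"))
  if (object@transPairs > 0 || object@skippedPairs > 0)
    cat(sprintf("  trans pairs: %.0f; skipped records: %.0f\n",
                object@transPairs, object@skippedPairs))
})

matchChrom <- function(x, chrom) {
  g <- if (is(x, "ContactMatrix")) x@genome else x
  if (!chrom %in% g@chromNames)
    stop(sprintf("unknown chromosome '%s'", chrom))
  chrom
}

## ---------------------------------------------------------------------------
## binning valid pairs
## ---------------------------------------------------------------------------

#' Bin valid contact pairs into a ContactMatrix
#'
#' Each cis pair increments the count of bins `floor(pos/resolution)` (and
#' its mirror; pairs falling in one bin are counted once on the diagonal).
#' Trans (inter-chromosomal) pairs are counted only as a total. Records on
#' chromosomes absent from the genome are skipped with a counted warning.
#' Positions are 0-based.
#'
#' @param pairs a data.frame with columns `chrom1, pos1, chrom2, pos2`, or a
#'   path to a 4DN `.pairs`-style text file (see [readPairs()]).
#' @param genome a [GenomeAssembly-class].
#' @param resolution bin width (bp, > 0).
#' @return An unbalanced [ContactMatrix-class].
#' @examples
#' g <- makeGenome(1, 1e4, 0.5)
#' p <- data.frame(chrom1 = "chr01", pos1 = 1500, chrom2 = "chr01",
#'                 pos2 = 3500)
#' m <- binPairs(p, g, 1000)
#' rawCounts(m, "chr01")[2, 4] # 1 (0-based bins 1 and 3)
#' @export
binPairs <- function(pairs, genome, resolution) {
  if (resolution <= 0) stop("'resolution' must be > 0")
  if (is.character(pairs)) pairs <- readPairs(pairs)
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(pairs)))
    stop("'pairs' must have columns chrom1, pos1, chrom2, pos2")
  nb <- nBins(genome, resolution)
  counts <- lapply(genome@chromNames, function(ch)
    matrix(0, nb[[ch]], nb[[ch]]))
  names(counts) <- genome@chromNames

  known <- pairs$chrom1 %in% genome@chromNames &
    pairs$chrom2 %in% genome@chromNames
  skipped <- sum(!known)
  if (skipped > 0)
    warning(sprintf("%d record(s) on unknown chromosomes skipped", skipped))
  pairs <- pairs[known, , drop = FALSE]

  inBounds <- pairs$pos1 >= 0 &
    pairs$pos1 < genome@chromLengths[pairs$chrom1] &
    pairs$pos2 >= 0 & pairs$pos2 < genome@chromLengths[pairs$chrom2]
  if (!all(inBounds)) stop("pair positions outside chromosome bounds")

  cis <- pairs$chrom1 == pairs$chrom2
  transPairs <- sum(!cis)
  pairs <- pairs[cis, , drop = FALSE]

  for (ch in unique(pairs$chrom1)) {
    sel <- pairs$chrom1 == ch
    i <- floor(pairs$pos1[sel] / resolution) + 1
    j <- floor(pairs$pos2[sel] / resolution) + 1
    lo <- pmin(i, j); hi <- pmax(i, j)
    n <- nb[[ch]]
    tab <- tabulate((hi - 1) * n + lo, nbins = n * n)
    M <- matrix(tab, n, n)
    M <- M + t(M)
    diag(M) <- diag(M) / 2      # diagonal pairs counted once
    counts[[ch]] <- counts[[ch]] + M
  }
  ContactMatrix(genome, resolution, counts,
                transPairs = transPairs, skippedPairs = skipped)
}

#' Read and write 4DN pairs-style text
#'
#' Tab-separated text with `#`-prefixed header/comment lines. Files with at
#' least 7 columns are taken in the standard layout (readID, chrom1, pos1,
#' chrom2, pos2, strand1, strand2); 4-column files as chrom1, pos1, chrom2,
#' pos2. Malformed lines abort with the offending line number.
#'
#' @param path file path.
#' @return `readPairs`: data.frame with columns chrom1, pos1, chrom2, pos2.
#' @export
readPairs <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep)) stop(sprintf("'%s' contains no data lines", path))
  d <- tryCatch(
    fread(text = lines[keep], header = FALSE, sep = "\t",
          data.table = FALSE),
    error = function(e) stop(sprintf("failed to parse '%s': %s",
                                     path, conditionMessage(e))))
  if (ncol(d) >= 7) d <- d[, 2:5] else if (ncol(d) == 4) d <- d[, 1:4] else
    stop(sprintf("'%s': expected 4 or >= 7 columns, found %d",
                 path, ncol(d)))
  names(d) <- c("chrom1", "pos1", "chrom2", "pos2")
  bad <- which(!is.finite(d$pos1) | !is.finite(d$pos2))
  if (length(bad))
    stop(sprintf("'%s': malformed position at data line %d", path, bad[1]))
  d$chrom1 <- as.character(d$chrom1)
  d$chrom2 <- as.character(d$chrom2)
  d
}

#' @rdname readPairs
#' @param pairs data.frame with columns chrom1, pos1, chrom2, pos2.
#' @param genome optional [GenomeAssembly-class] used to write `#chromsize`
#'   header lines.
#' @export
writePairs <- function(pairs, path, genome = NULL) {
  con <- file(path, "w")
  writeLines("## pairs format v1.0", con)
  if (!is.null(genome))
    writeLines(sprintf("#chromsize: %s %d", genome@chromNames,
                       as.integer(genome@chromLengths)), con)
  writeLines("#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2", con)
  close(con)
  d <- data.frame(readID = sprintf("r%d", seq_len(nrow(pairs))),
                  pairs[, c("chrom1", "pos1", "chrom2", "pos2")],
                  strand1 = "+", strand2 = "+")
  fwrite(d, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Expand a contact matrix into pair records
#'
#' Emits one record per counted cis contact, with both positions at the
#' centers of their bins; the exact inverse of [binPairs()] up to
#' within-bin position (binning the result reproduces the counts). Useful
#' for writing simulated maps as 4DN pairs-style text via [writePairs()].
#'
#' @param x a [ContactMatrix-class] with integer counts.
#' @return A data.frame with columns chrom1, pos1, chrom2, pos2.
#' @export
matrixToPairs <- function(x) {
  res <- x@resolution
  out <- lapply(names(x@counts), function(ch) {
    C <- x@counts[[ch]]
    ut <- which(upper.tri(C, diag = TRUE) & C > 0, arr.ind = TRUE)
    if (nrow(ut) == 0)
      return(data.frame(chrom1 = character(0), pos1 = numeric(0),
                        chrom2 = character(0), pos2 = numeric(0)))
    n <- C[ut]
    i <- rep(ut[, 1], n); j <- rep(ut[, 2], n)
    data.frame(chrom1 = ch,
               pos1 = pmin((i - 0.5) * res, x@genome@chromLengths[[ch]] - 1),
               chrom2 = ch,
               pos2 = pmin((j - 0.5) * res, x@genome@chromLengths[[ch]] - 1))
  })
  do.call(rbind, out)
}

## ---------------------------------------------------------------------------
## iterative correction
## ---------------------------------------------------------------------------

#' Iterative-correction (ICE) balancing
#'
#' Masks zero-marginal bins and bins in the lowest `lowCoverageFraction` of
#' nonzero marginal counts, then iteratively scales per-bin weights until
#' the coefficient of variation of the balanced marginals drops below `tol`
#' (or `maxIter` is reached). Weights are normalized so the mean balanced
#' marginal over valid bins is 1. Raw counts are left untouched; the weights
#' and mask are stored alongside. Each chromosome is balanced on its cis
#' matrix.
#'
#' @param x an unbalanced (or balanced; the operation is idempotent)
#'   [ContactMatrix-class].
#' @param maxIter maximum iterations; default 200.
#' @param tol relative CV convergence threshold; default 1e-5.
#' @param lowCoverageFraction marginal-count quantile below which bins are
#'   masked; default 0.02.
#' @return The [ContactMatrix-class] with weights and valid mask filled.
#' @rdname iceBalance
#' @export
setMethod("iceBalance", "ContactMatrix",
          function(x, maxIter = 200, tol = 1e-5, lowCoverageFraction = 0.02) {
  weights <- list()
  masks <- list()
  for (ch in names(x@counts)) {
    C <- x@counts[[ch]]
    n <- nrow(C)
    marg <- rowSums(C)
    valid <- marg > 0
    if (any(valid) && lowCoverageFraction > 0) {
      ## strictly-below-quantile masking: a flat marginal profile keeps
      ## every bin
      thr <- quantile(marg[valid], lowCoverageFraction, names = FALSE)
      valid <- marg > 0 & !(marg < thr)
    }
    if (!any(valid))
      stop(sprintf("all bins masked on chromosome '%s'", ch))
    w <- ifelse(valid, 1, NA_real_)
    for (it in seq_len(maxIter)) {
      wv <- w[valid]
      m <- wv * (C[valid, valid, drop = FALSE] %*% wv)[, 1]
      if (any(m == 0)) {           # bin only touching masked bins
        valid[valid][m == 0] <- FALSE
        w[!valid] <- NA_real_
        if (!any(valid)) stop(sprintf(
          "all bins masked on chromosome '%s'", ch))
        next
      }
      mbar <- mean(m)
      cv <- sd(m) / mbar
      if (is.na(cv) || cv < tol) break
      w[valid] <- wv / (m / mbar)
    }
    ## scale so the mean balanced marginal over valid bins equals 1
    wv <- w[valid]
    m <- wv * (C[valid, valid, drop = FALSE] %*% wv)[, 1]
    w[valid] <- wv / sqrt(mean(m))
    weights[[ch]] <- w
    masks[[ch]] <- valid
  }
  x@weights <- weights
  x@validMask <- masks
  x@balanced <- TRUE
  validObject(x)
  x
})

#' Mark a matrix as balanced with unit weights
#'
#' Declares every bin valid with weight 1, so the stored counts are used as
#' balanced values directly. Intended for synthetic expectation matrices
#' (whose generative model already is the "true" balanced map) and for
#' noise-free oracle computations; measured count matrices should go
#' through [iceBalance()] instead.
#'
#' @param x a [ContactMatrix-class].
#' @return The matrix flagged balanced with unit weights.
#' @export
unitBalanced <- function(x) {
  x@weights <- lapply(x@counts, function(m) rep(1, nrow(m)))
  x@validMask <- lapply(x@counts, function(m) rep(TRUE, nrow(m)))
  x@balanced <- TRUE
  validObject(x)
  x
}

## balanced matrix of one chromosome (w_i w_j C_ij, NA at masked bins)
balancedMatrix <- function(x, ch) {
  if (!x@balanced) stop("matrix is not balanced; run iceBalance() first")
  w <- x@weights[[ch]]
  outer(w, w) * x@counts[[ch]]
}

#' Extract a dense cis window
#'
#' Returns the balanced (default) or raw counts of the bins overlapping
#' `[start, end)`, with masked bins as NA ("white stripes" where data was
#' lost).
#'
#' @param x a [ContactMatrix-class].
#' @param chrom chromosome name.
#' @param start,end window (bp, 0-based half-open); must lie within the
#'   chromosome.
#' @param balanced return `w_i w_j C_ij` (requires balancing) or raw counts.
#' @return A dense numeric matrix with NA at masked bins.
#' @rdname cisSubmatrix
#' @export
setMethod("cisSubmatrix", "ContactMatrix",
          function(x, chrom, start, end, balanced = TRUE) {
  ch <- matchChrom(x, chrom)
  len <- x@genome@chromLengths[[ch]]
  if (start < 0 || end > len || start >= end)
    stop("window outside chromosome or empty")
  i0 <- floor(start / x@resolution) + 1
  i1 <- ceiling(end / x@resolution)
  idx <- i0:i1
  M <- if (balanced) balancedMatrix(x, ch)[idx, idx, drop = FALSE]
       else {
         m <- x@counts[[ch]][idx, idx, drop = FALSE]
         bad <- !x@validMask[[ch]][idx]
         m[bad, ] <- NA_real_
         m[, bad] <- NA_real_
         m
       }
  M
})

## ---------------------------------------------------------------------------
## dense TSV round trip
## ---------------------------------------------------------------------------

#' Write and read per-chromosome dense matrix TSV
#'
#' One file per chromosome (raw counts), plus a `<prefix>.bins.tsv` with
#' per-bin weights and the valid mask when the matrix is balanced.
#'
#' @param x a [ContactMatrix-class].
#' @param prefix output path prefix; files are named
#'   `<prefix>.<chrom>.matrix.tsv`.
#' @return `writeContactMatrixTSV`: the vector of files written, invisibly.
#' @export
writeContactMatrixTSV <- function(x, prefix) {
  files <- character(0)
  for (ch in names(x@counts)) {
    f <- sprintf("%s.%s.matrix.tsv", prefix, ch)
    fwrite(as.data.frame(x@counts[[ch]]), f, sep = "\t", col.names = FALSE)
    files <- c(files, f)
  }
  if (x@balanced) {
    f <- sprintf("%s.bins.tsv", prefix)
    d <- do.call(rbind, lapply(names(x@weights), function(ch) {
      nbin <- length(x@weights[[ch]])
      data.frame(chrom = ch, bin = seq_len(nbin) - 1,
                 weight = x@weights[[ch]], valid = x@validMask[[ch]])
    }))
    fwrite(d, f, sep = "\t")
    files <- c(files, f)
  }
  invisible(files)
}

#' @rdname writeContactMatrixTSV
#' @param genome a [GenomeAssembly-class] naming the chromosomes to read.
#' @param resolution bin width (bp) of the stored matrices.
#' @return `readContactMatrixTSV`: a [ContactMatrix-class].
#' @export
readContactMatrixTSV <- function(prefix, genome, resolution) {
  counts <- lapply(genome@chromNames, function(ch) {
    f <- sprintf("%s.%s.matrix.tsv", prefix, ch)
    as.matrix(fread(f, header = FALSE, sep = "\t", data.table = FALSE))
  })
  names(counts) <- genome@chromNames
  counts <- lapply(counts, unname)
  binsFile <- sprintf("%s.bins.tsv", prefix)
  weights <- NULL
  if (file.exists(binsFile)) {
    d <- fread(binsFile, sep = "\t", data.table = FALSE)
    weights <- lapply(genome@chromNames, function(ch)
      d$weight[d$chrom == ch])
    names(weights) <- genome@chromNames
  }
  ContactMatrix(genome, resolution, counts, weights = weights)
}
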