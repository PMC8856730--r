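#' @importFrom GenomicRanges GRanges mcols mcols<- start end strand strand<-
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths Seqinfo
#' @importFrom S4Vectors DataFrame
NULL

#' @describeIn GenomeAssembly-class chromosome names, in order.
#' @export
setMethod("chromNames", "GenomeAssembly", function(x) x@chromNames)

#' @describeIn GenomeAssembly-class named chromosome lengths (bp).
#' @export
setMethod("chromLengths", "GenomeAssembly", function(x) x@chromLengths)

#' @describeIn GenomeAssembly-class centromere intervals as a GRanges
#'   (1-based, as usual for GRanges; converted from the internal 0-based
#'   half-open representation).
#' @export
setMethod("centromeres", "GenomeAssembly", function(x) {
  GRanges(x@chromNames,
          IRanges(start = x@centromereStart + 1, end = x@centromereEnd),
          seqinfo = Seqinfo(x@chromNames, seqlengths = x@chromLengths))
})

setMethod("show", "GenomeAssembly", function(object) {
  cat(sprintf("GenomeAssembly with %d chromosome(s), total %.3g bp\n",
              length(object@chromNames), sum(object@chromLengths)))
  n <- min(5, length(object@chromNames))
  for (i in seq_len(n))
    cat(sprintf("  %s  %.0f bp  centromere [%.0f, %.0f)\n",
                object@chromNames[i], object@chromLengths[i],
                object@centromereStart[i], object@centromereEnd[i]))
  if (length(object@chromNames) > n) cat("  ...\n")
})

## number of bins per chromosome at a given resolution (last partial bin kept)
nBins <- function(genome, resolution) {
  setNames(as.integer(ceiling(genome@chromLengths / resolution)),
           genome@chromNames)
}

## centromere midpoints (bp, 0-based), named by chromosome
centromereMid <- function(genome) {
  (genome@centromereStart + genome@centromereEnd) / 2
}

#' Generate a synthetic genome assembly
#'
#' Builds a genome of `nChrom` equal-length chromosomes with the centromere
#' midpoint placed at `centromereFraction` of each chromosome length. The
#' construction is deterministic; `seed` is accepted for interface symmetry
#' with the other generators.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param chromLength chromosome length (bp).
#' @param centromereFraction position of the centromere midpoint as a
#'   fraction of chromosome length.
#' @param seed integer seed (unused by the deterministic construction).
#' @param centromereWidth width of the centromere interval (bp); default
#'   1000.
#' @return A [GenomeAssembly-class].
#' @examples
#' g <- makeGenome(16, 1e6, 0.3)
#' unname(centromereMidpoints(g))[1] # 3e5
#' @export
makeGenome <- function(nChrom, chromLength, centromereFraction = 0.5,
                       seed = 1L, centromereWidth = 1000) {
  if (nChrom < 1) stop("'nChrom' must be >= 1")
  if (chromLength <= 0) stop("'chromLength' must be positive")
  if (centromereWidth <= 0) stop("'centromereWidth' must be positive")
  if (centromereFraction <= 0 || centromereFraction >= 1)
    stop("'centromereFraction' must be in (0, 1)")
  cn <- sprintf("chr%02d", seq_len(nChrom))
  len <- setNames(rep(chromLength, nChrom), cn)
  mid <- chromLength * centromereFraction
  cs <- setNames(rep(mid - centromereWidth / 2, nChrom), cn)
  ce <- setNames(rep(mid + centromereWidth / 2, nChrom), cn)
  if (any(cs < 0) || any(ce > chromLength))
    stop("centromere interval falls outside the chromosome")
  GenomeAssembly(len, cs, ce)
}

#' Centromere midpoints of a genome
#'
#' @param genome a [GenomeAssembly-class].
#' @return Named numeric vector of centromere midpoints (bp, 0-based).
#' @export
centromereMidpoints <- function(genome) centromereMid(genome)

#' Build centromere, border and arm feature annotations
#'
#' Per chromosome: one centromere feature at the centromere midpoint, two
#' pericentromere-border features at midpoint +/- `borderOffset` (with
#' `armSide` recording which arm they lie on), and `nArmSites` arm features
#' per side at `armSpacing` intervals beyond the borders. Features are
#' returned as a GRanges of 1-bp midpoints with metadata columns `kind`
#' (centromere/border/arm) and `armSide` (left/right, NA for centromeres).
#'
#' @param genome a [GenomeAssembly-class].
#' @param borderOffset distance (bp) from centromere midpoint to each border.
#' @param nArmSites number of arm features per side; 0 for none.
#' @param armSpacing spacing (bp) between successive arm features beyond the
#'   border.
#' @return A GRanges with mcols `kind` and `armSide`.
#' @examples
#' g <- makeGenome(16, 1e6, 0.3)
#' f <- makeFeatures(g, borderOffset = 20000, nArmSites = 1)
#' table(f$kind) # 16 centromeres, 32 borders, 32 arms
#' @export
makeFeatures <- function(genome, borderOffset = 20000, nArmSites = 0,
                         armSpacing = 30000) {
  if (borderOffset <= 0) stop("'borderOffset' must be > 0")
  if (nArmSites > 0 && armSpacing <= 0) stop("'armSpacing' must be > 0")
  mids <- centromereMid(genome)
  chrom <- character(0); pos <- numeric(0)
  kind <- character(0); side <- character(0)
  for (ch in genome@chromNames) {
    m <- mids[[ch]]
    add <- function(p, k, s) {
      chrom <<- c(chrom, ch); pos <<- c(pos, p)
      kind <<- c(kind, k); side <<- c(side, s)
    }
    add(m, "centromere", NA_character_)
    add(m - borderOffset, "border", "left")
    add(m + borderOffset, "border", "right")
    if (nArmSites > 0) {
      for (i in seq_len(nArmSites)) {
        add(m - borderOffset - i * armSpacing, "arm", "left")
        add(m + borderOffset + i * armSpacing, "arm", "right")
      }
    }
    len <- genome@chromLengths[[ch]]
    bad <- pos[chrom == ch] < 0 | pos[chrom == ch] >= len
    if (any(bad))
      stop(sprintf("features fall outside chromosome '%s'", ch))
  }
  gr <- GRanges(chrom, IRanges(start = pos + 1, width = 1),
                seqinfo = Seqinfo(genome@chromNames,
                                  seqlengths = genome@chromLengths))
  mcols(gr) <- DataFrame(kind = kind, armSide = side)
  gr
}

## validate a feature GRanges (kind/armSide contract)
assertFeatures <- function(features) {
  if (length(features) == 0) stop("empty feature list")
  mc <- mcols(features)
  if (!all(c("kind", "armSide") %in% colnames(mc)))
    stop("features must carry 'kind' and 'armSide' metadata columns")
  if (!all(mc$kind %in% c("centromere", "border", "arm")))
    stop("feature 'kind' must be centromere, border or arm")
  needSide <- mc$kind %in% c("border", "arm")
  if (any(is.na(mc$armSide[needSide])))
    stop("border/arm features must have 'armSide' set")
  invisible(features)
}

## feature midpoints (bp, 0-based) from the 1-bp GRanges representation
featureMid <- function(features) start(features) - 1

#' Read and write chrom.sizes files
#'
#' Two-column, tab-separated `name<TAB>length` text. Reading returns only the
#' lengths; centromeres must be supplied separately to build a full
#' [GenomeAssembly-class].
#'
#' @param path file path.
#' @return `readChromSizes`: a named numeric vector of lengths.
#' @export
readChromSizes <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "length"),
                  colClasses = c("character", "numeric"))
  setNames(d$length, d$chrom)
}

#' @rdname readChromSizes
#' @param genome a [GenomeAssembly-class].
#' @export
writeChromSizes <- function(genome, path) {
  write.table(data.frame(genome@chromNames, genome@chromLengths),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write feature annotations as BED6
#'
#' Features are written as 1-bp BED intervals at the midpoint; the BED name
#' column carries the feature kind, the score column is unused (0) and the
#' strand column encodes the arm side (+ = left, - = right, . for
#' centromeres).
#'
#' @param features a feature GRanges as from [makeFeatures()].
#' @param path file path.
#' @export
writeFeaturesBed <- function(features, path) {
  assertFeatures(features)
  gr <- features
  s <- ifelse(is.na(gr$armSide), "*", ifelse(gr$armSide == "left", "+", "-"))
  strand(gr) <- s
  names(gr) <- NULL
  gr$name <- gr$kind
  gr$score <- 0L
  mcols(gr) <- mcols(gr)[, c("name", "score")]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeFeaturesBed
#' @return `readFeaturesBed`: a feature GRanges with mcols `kind`, `armSide`.
#' @export
readFeaturesBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  kind <- gr$name
  s <- as.character(strand(gr))
  side <- ifelse(s == "+", "left", ifelse(s == "-", "right", NA_character_))
  mcols(gr) <- DataFrame(kind = kind, armSide = side)
  assertFeatures(gr)
}
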