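## Spike-in calibrated ChIP-seq: occupancy ratio, calibrated tracks,
## feature metaprofiles, ChIP-qPCR enrichment.

setMethod("show", "CalibSample", function(object) {
  t <- object@totals
  cat(sprintf("CalibSample '%s': Wx %.4g, Wc %.4g, IPx %.4g, IPc %.4g\n",
              object@sampleId, t[["Wx"]], t[["Wc"]], t[["IPx"]], t[["IPc"]]))
  if (length(object@coverage))
    cat(sprintf("  coverage: %d chromosome(s) at %g bp bins\n",
                length(object@coverage), object@binWidth))
  or <- tryCatch(occupancyRatio(object), error = function(e) NA_real_)
  if (!is.na(or)) cat(sprintf("  occupancy ratio: %.4g\n", or))
})

setMethod("show", "CalibratedTrack", function(object) {
  cat(sprintf(
    "CalibratedTrack '%s': %d chromosome(s) at %g bp bins\n",
    object@sampleId, length(object@values), object@binWidth))
})

setMethod("show", "MetaProfile", function(object) {
  cat(sprintf(
    "MetaProfile: %d offsets (%g..%g bp), %d feature(s)\n",
    length(object@offsets), min(object@offsets), max(object@offsets),
    object@nFeatures))
})

orFromTotals <- function(t) {
  t <- vapply(t, as.numeric, numeric(1))   # avoid 32-bit overflow
  if (t[["Wx"]] == 0) stop("occupancy ratio undefined: Wx is zero")
  if (t[["IPc"]] == 0) stop("occupancy ratio undefined: IPc is zero")
  (t[["Wc"]] * t[["IPx"]]) / (t[["Wx"]] * t[["IPc"]])
}

#' @rdname occupancyRatio
#' @export
setMethod("occupancyRatio", "CalibSample", function(sample) {
  orFromTotals(sample@totals)
})

#' @rdname occupancyRatio
#' @export
setMethod("occupancyRatio", "numeric", function(sample) {
  if (!all(c("Wx", "Wc", "IPx", "IPc") %in% names(sample)))
    stop("need named elements Wx, Wc, IPx, IPc")
  orFromTotals(sample)
})

#' OR-normalize a coverage track
#'
#' The calibrated per-bin signal is `coverage * OR / IPx`, i.e. proportional
#' to `coverage * Wc / (Wx * IPc)`. Dividing the coverage by its own total
#' (IPx) and multiplying by the occupancy ratio makes the track invariant to
#' the IP sequencing depth (which scales coverage, IPx and IPc together) --
#' the point of spike-in calibration. Masked (NA) bins propagate.
#'
#' For a non-calibrated sample (no spike-in material), pass a fixed `or` to
#' normalize by sequencing depth alone under a stated constant.
#'
#' @param sample a [CalibSample-class] with a coverage track.
#' @param or optional fixed occupancy ratio overriding the one computed from
#'   the sample's totals.
#' @return A [CalibratedTrack-class].
#' @rdname calibrateTrack
#' @export
setMethod("calibrateTrack", "CalibSample", function(sample, or = NULL) {
  if (length(sample@coverage) == 0)
    stop("sample has no coverage track")
  if (is.null(or)) or <- occupancyRatio(sample)
  ipx <- sample@totals[["IPx"]]
  if (ipx == 0) stop("IPx is zero; calibrated track undefined")
  vals <- lapply(sample@coverage, function(v) v * or / ipx)
  new("CalibratedTrack", genome = sample@genome,
      sampleId = sample@sampleId, binWidth = sample@binWidth,
      values = vals)
})

#' Oriented feature metaprofile with confidence band
#'
#' Extracts the calibrated signal at `midpoint + offset` for every feature
#' and offset in `-flank..flank` (steps of `step`), then averages across
#' features. With `orient = TRUE`, features on the right arm
#' (`armSide == "right"`) are flipped so that the centromere-proximal side
#' always maps to the same side of the profile. Offsets reaching beyond a
#' chromosome end (or masked bins) are dropped from the mean with the
#' per-offset n reduced and a warning. The band is mean +/- 1.96 SE (normal
#' approximation); a single feature yields SE 0.
#'
#' @param track a [CalibratedTrack-class].
#' @param features feature GRanges as from [makeFeatures()]; usually a
#'   single kind (e.g. all borders).
#' @param flank half-window (bp); default 3000.
#' @param step offset step (bp); default 50. Must be a multiple of the track
#'   bin width (coarser tracks are rejected, not interpolated).
#' @param orient flip right-arm features; default TRUE.
#' @return A [MetaProfile-class].
#' @export
featureMetaprofile <- function(track, features, flank = 3000, step = 50,
                               orient = TRUE) {
  assertFeatures(features)
  bw <- track@binWidth
  if (step %% bw != 0)
    stop(sprintf(
      "track bin width (%g bp) must divide the profile step (%g bp)",
      bw, step))
  offsets <- seq(-flank, flank, by = step)
  mids <- featureMid(features)
  chs <- as.character(seqnames(features))
  side <- features$armSide

  sig <- matrix(NA_real_, nrow = length(features), ncol = length(offsets))
  truncated <- FALSE
  for (f in seq_along(features)) {
    flip <- orient && !is.na(side[f]) && side[f] == "right"
    off <- if (flip) -offsets else offsets
    pos <- mids[f] + off
    v <- track@values[[chs[f]]]
    len <- track@genome@chromLengths[[chs[f]]]
    inb <- pos > 0 & pos < len
    if (!all(inb)) truncated <- TRUE
    ## flipped features use the right-closed bin convention, so a position
    ## on a bin edge samples the exact mirror bin of its unflipped twin
    b <- if (flip) ceiling(pos[inb] / bw) else floor(pos[inb] / bw) + 1
    sig[f, inb] <- v[b]
  }
  if (truncated)
    warning("feature window(s) truncated at chromosome end; n reduced")

  n <- colSums(!is.na(sig))
  mu <- colMeans(sig, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  se <- apply(sig, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) <= 1) 0 else sd(col) / sqrt(length(col))
  })
  new("MetaProfile", offsets = offsets, mean = mu, se = se,
      ciLow = mu - 1.96 * se, ciHigh = mu + 1.96 * se,
      n = n, nFeatures = length(features))
}

#' Write a metaprofile as TSV
#'
#' Columns: offset, mean, se, ci_low, ci_high, n.
#'
#' @param profile a [MetaProfile-class].
#' @param path output file.
#' @export
writeMetaProfileTSV <- function(profile, path) {
  write.table(
    data.frame(offset = profile@offsets, mean = profile@mean,
               se = profile@se, ci_low = profile@ciLow,
               ci_high = profile@ciHigh, n = profile@n),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ChIP-qPCR enrichment from threshold cycles
#'
#' Computes the dilution-corrected delta-Ct,
#' `dCt = ctChip - (ctInput - log_E(dilution))`, and returns the ChIP/Input
#' enrichment `E^(-dCt)`, where E is the primer amplification factor per
#' cycle. The input Ct is corrected for its dilution factor so that ChIP and
#' input are compared at equivalent template amounts.
#'
#' @param ctChip,ctInput threshold cycles of the ChIP and (diluted) input
#'   reactions.
#' @param efficiency primer amplification factor per cycle (> 1; a perfect
#'   primer doubles, efficiency 2).
#' @param dilution input dilution factor (>= 1).
#' @return Enrichment (ChIP/Input, dimensionless).
#' @examples
#' qpcrEnrichment(25, 20, efficiency = 2, dilution = 500) # 6.25e-5
#' @export
qpcrEnrichment <- function(ctChip, ctInput, efficiency = 2, dilution = 1) {
  if (efficiency <= 1) stop("'efficiency' must be > 1")
  if (dilution < 1) stop("'dilution' must be >= 1")
  dCt <- ctChip - (ctInput - log(dilution) / log(efficiency))
  efficiency^(-dCt)
}

#' Write and read a sample's four read totals as TSV
#'
#' One row per sample with columns `sample_id, Wx, Wc, IPx, IPc`.
#'
#' @param sample a [CalibSample-class].
#' @param path file path.
#' @export
writeTotalsTSV <- function(sample, path) {
  t <- sample@totals
  write.table(
    data.frame(sample_id = sample@sampleId, Wx = t[["Wx"]],
               Wc = t[["Wc"]], IPx = t[["IPx"]], IPc = t[["IPc"]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTotalsTSV
#' @param genome a [GenomeAssembly-class].
#' @param coveragePath optional bedGraph of per-bin IP coverage (see
#'   [writeBedGraph()]).
#' @param binWidth coverage bin width (bp); default 50.
#' @return `readCalibSampleTSV`: a [CalibSample-class].
#' @export
readCalibSampleTSV <- function(path, genome, coveragePath = NULL,
                               binWidth = 50) {
  d <- read.table(path, sep = "\t", header = TRUE)
  cov <- if (is.null(coveragePath)) list() else
    readBedGraphTrack(coveragePath, genome, binWidth)
  CalibSample(genome,
              c(Wx = as.numeric(d$Wx[1]), Wc = as.numeric(d$Wc[1]),
                IPx = as.numeric(d$IPx[1]), IPc = as.numeric(d$IPc[1])),
              coverage = cov, binWidth = binWidth,
              sampleId = as.character(d$sample_id[1]))
}

#' Apply the qPCR enrichment formula to a Ct table
#'
#' @param ct a data.frame with columns `ct_chip`, `ct_input` and optionally
#'   `efficiency` (default 2) and `dilution` (default 1), e.g. from
#'   [readQpcrTable()].
#' @return The data.frame with `delta_ct` and `enrichment` columns added.
#' @export
qpcrEnrichmentTable <- function(ct) {
  if (!all(c("ct_chip", "ct_input") %in% names(ct)))
    stop("need columns 'ct_chip' and 'ct_input'")
  eff <- if ("efficiency" %in% names(ct)) ct$efficiency else 2
  dil <- if ("dilution" %in% names(ct)) ct$dilution else 1
  ct$delta_ct <- ct$ct_chip - (ct$ct_input - log(dil) / log(eff))
  ct$enrichment <- mapply(qpcrEnrichment, ct$ct_chip, ct$ct_input,
                          eff, dil)
  ct
}

#' @rdname qpcrEnrichmentTable
#' @param path tab-separated Ct table with a header row.
#' @export
readQpcrTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             stringsAsFactors = FALSE)
}

#' Read and write per-bin coverage as bedGraph
#'
#' @param track a [CalibratedTrack-class] or [CalibSample-class] (the
#'   coverage track is written).
#' @param path file path.
#' @export
writeBedGraph <- function(track, path) {
  vals <- if (is(track, "CalibSample")) track@coverage else track@values
  g <- track@genome
  bw <- track@binWidth
  gr <- do.call(c, lapply(g@chromNames, function(ch) {
    v <- vals[[ch]]
    nb <- length(v)
    end <- pmin(seq_len(nb) * bw, g@chromLengths[[ch]])
    GRanges(ch, IRanges(start = (seq_len(nb) - 1) * bw + 1, end = end),
            score = v,
            seqinfo = Seqinfo(g@chromNames, seqlengths = g@chromLengths))
  }))
  rtracklayer::export(gr[!is.na(gr$score)], path, format = "bedGraph")
  invisible(path)
}

#' @rdname writeBedGraph
#' @param genome a [GenomeAssembly-class]; bins are reconstructed on this
#'   frame.
#' @param binWidth bin width (bp) of the stored track.
#' @return `readBedGraphTrack`: a named list of per-chromosome value
#'   vectors (NA where the file has no interval).
#' @export
readBedGraphTrack <- function(path, genome, binWidth) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(genome@chromNames, function(ch) {
    nb <- as.integer(ceiling(genome@chromLengths[[ch]] / binWidth))
    v <- rep(NA_real_, nb)
    sel <- gr[as.character(seqnames(gr)) == ch]
    for (k in seq_along(sel)) {
      ## intervals may span several bins (writers merge equal-score runs)
      b0 <- floor((start(sel)[k] - 1) / binWidth) + 1
      b1 <- ceiling(end(sel)[k] / binWidth)
      v[b0:min(b1, nb)] <- sel$score[k]
    }
    v
  })
  names(vals) <- genome@chromNames
  vals
}
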