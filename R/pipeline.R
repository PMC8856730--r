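## End-to-end orchestration: generate/ingest -> calibrate -> balance ->
## P(s)/slope/loop size -> pileups/ratios/scores -> JSON report.

#' Validate a pipeline configuration
#'
#' Checks the declarative run configuration (a list, or a path to a YAML
#' file) before any computation: required fields, known input mode, and
#' existence of every referenced path. Errors here are "validation errors";
#' the command-line wrapper maps them to exit code 2.
#'
#' @param config a list or YAML file path.
#' @return The normalized config list, invisibly on success.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file '%s' does not exist", config))
    config <- yaml::read_yaml(config)
  }
  mode <- config$mode
  if (is.null(mode) || !mode %in% c("synthetic", "pairs", "matrices"))
    stop("config$mode must be one of: synthetic, pairs, matrices")
  if (is.null(config$outputDir)) stop("config$outputDir is required")
  if (is.null(config$resolution)) stop("config$resolution is required")
  if (is.null(config$seed)) config$seed <- 1L
  if (mode == "synthetic") {
    for (f in c("genome", "hic"))
      if (is.null(config[[f]]))
        stop(sprintf("config$%s is required in synthetic mode", f))
    if (is.null(config$hic$conditions) || !length(config$hic$conditions))
      stop("config$hic$conditions must list at least one condition")
  } else {
    for (f in c("chromSizes", "featuresBed"))
      if (is.null(config[[f]]))
        stop(sprintf("config$%s is required in %s mode", f, mode))
    paths <- c(config$chromSizes, config$featuresBed,
               unlist(lapply(config$samples, `[[`, "path")))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop(sprintf("referenced path(s) do not exist: %s",
                   paste(missing, collapse = ", ")))
  }
  invisible(config)
}

numOr <- function(x, default) if (is.null(x)) default else as.numeric(x)

## run the Hi-C analyses for one balanced map; returns report entries plus
## the pileup objects needed for ratio maps
analyzeMap <- function(map, truth, features, cfg, warningsEnv) {
  ps <- slopeCurve(contactProbability(map),
                   smoothWindow = numOr(cfg$hic$smoothWindow, 3))
  est <- withCallingHandlers(
    loopSizeEstimate(ps, searchRange = c(
      numOr(cfg$hic$searchMin, 3000), numOr(cfg$hic$searchMax, 200000))),
    warning = function(w) {
      warningsEnv$w <- c(warningsEnv$w, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cen <- features[features$kind == "centromere"]
  bor <- features[features$kind == "border"]
  flankCen <- numOr(cfg$hic$flankCentromere, 100000)
  flankBor <- numOr(cfg$hic$flankBorder, 25000)
  pileCen <- snipPileup(map, cen, flank = flankCen, mode = "mirrored")
  pileBor <- snipPileup(map, bor, flank = flankBor, mode = "oriented")
  insul <- vapply(seq_along(cen), function(i) {
    tryCatch(insulationScore(map, as.character(seqnames(cen))[i],
                             featureMid(cen)[i]),
             error = function(e) NA_real_)
  }, numeric(1))
  ## dot strength is measurable against known anchors (synthetic runs)
  dot <- if (!is.null(truth) && length(truth@anchorPositions)) {
    dotScore(anchorPairPileup(map, truth@anchorPositions, flank = 10000))
  } else NA_real_
  ## centromere-anchored stripe profiles, one row per distance per arm
  stripes <- do.call(rbind, lapply(seq_along(cen), function(i) {
    ch <- as.character(seqnames(cen))[i]
    sp <- tryCatch(
      suppressWarnings(stripeProfile(map, ch, featureMid(cen)[i])),
      error = function(e) NULL)
    if (is.null(sp)) NULL else cbind(chrom = ch, sp)
  }))
  list(psCurve = ps,
       loopSize = est$estimate, slopeAtMax = est$slopeAtMax,
       noPeak = est$noPeak,
       centromereInsulation = median(insul, na.rm = TRUE),
       dotScore = dot, stripes = stripes,
       pileups = list(centromere = pileCen, border = pileBor))
}

#' Run the full analysis pipeline
#'
#' Executes all requested stages in dependency order and writes per-sample
#' TSV outputs plus a machine-readable JSON report into
#' `config$outputDir`. In synthetic mode, contact maps (and optionally
#' calibrated ChIP samples) are generated per condition from the configured
#' truth parameters; in `pairs`/`matrices` mode they are read from the
#' referenced files. Identical config and seeds give identical reports.
#'
#' @param config a list or YAML file path; see [validateRunConfig()].
#' @return Invisibly, a list with `report` (what was written as JSON) and
#'   `objects` (the in-memory maps, P(s) curves and pileups, for use with
#'   [compareConditions()]).
#' @export
runPipeline <- function(config) {
  cfg <- validateRunConfig(config)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  warningsEnv <- new.env()
  warningsEnv$w <- character(0)

  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (cfg$mode == "synthetic") {
    genome <- stage("genome", makeGenome(
      nChrom = cfg$genome$nChrom,
      chromLength = cfg$genome$chromLength,
      centromereFraction = numOr(cfg$genome$centromereFraction, 0.5)))
    features <- stage("features", makeFeatures(
      genome,
      borderOffset = numOr(cfg$features$borderOffset, 20000),
      nArmSites = numOr(cfg$features$nArmSites, 1),
      armSpacing = numOr(cfg$features$armSpacing, 30000)))
  } else {
    lens <- readChromSizes(cfg$chromSizes)
    cens <- readFeaturesBed(cfg$featuresBed)
    cmid <- featureMid(cens[cens$kind == "centromere"])
    names(cmid) <- as.character(seqnames(cens[cens$kind == "centromere"]))
    genome <- GenomeAssembly(lens, cmid[names(lens)] - 500,
                             cmid[names(lens)] + 500)
    features <- cens
  }
  writeChromSizes(genome, file.path(cfg$outputDir, "genome.chrom.sizes"))
  writeFeaturesBed(features, file.path(cfg$outputDir, "features.bed"))

  samples <- list()
  objects <- list(genome = genome, features = features, maps = list(),
                  pileups = list(), psCurves = list(), truths = list())

  conditions <- if (cfg$mode == "synthetic") cfg$hic$conditions else
    cfg$samples
  for (cond in conditions) {
    id <- cond$id
    if (cfg$mode == "synthetic") {
      truth <- syntheticTruth(
        decayExponent = numOr(cond$decayExponent, 1.5),
        loopSize = numOr(cond$loopSize, 10000),
        dotStrength = numOr(cond$dotStrength, 4),
        boundaryInsulation = numOr(cond$boundaryInsulation, 1),
        boundaryPositions = if (numOr(cond$boundaryInsulation, 1) < 1)
          as.list(centromereMidpoints(genome)) else list())
      sim <- stage(paste0("simulate:", id), simulateContactMap(
        genome, truth, resolution = cfg$resolution,
        depth = numOr(cfg$hic$depth, 5e6),
        seed = cfg$seed + numOr(cond$seedOffset, 0)))
      map <- sim$map
      objects$truths[[id]] <- sim$truth
    } else if (cfg$mode == "pairs") {
      map <- stage(paste0("bin:", id),
                   binPairs(cond$path, genome, cfg$resolution))
    } else {
      map <- stage(paste0("read:", id),
                   readContactMatrixTSV(cond$path, genome, cfg$resolution))
    }
    map <- stage(paste0("balance:", id), iceBalance(map))
    res <- stage(paste0("analyze:", id),
                 analyzeMap(map, objects$truths[[id]], features, cfg,
                            warningsEnv))
    writePsCurveTSV(res$psCurve,
                    file.path(cfg$outputDir, sprintf("%s.ps.tsv", id)))
    stripeFile <- NULL
    if (!is.null(res$stripes)) {
      stripeFile <- file.path(cfg$outputDir,
                              sprintf("%s.centromere.stripes.tsv", id))
      write.table(res$stripes, stripeFile, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    pileFiles <- list()
    for (pk in names(res$pileups)) {
      f <- file.path(cfg$outputDir, sprintf("%s.pileup.%s.tsv", id, pk))
      writePileupTSV(res$pileups[[pk]], f)
      pileFiles[[pk]] <- f
    }
    objects$maps[[id]] <- map
    objects$pileups[[id]] <- res$pileups
    objects$psCurves[[id]] <- res$psCurve
    samples[[id]] <- list(
      id = id,
      loopSize = res$loopSize, slopeAtMax = res$slopeAtMax,
      noPeak = res$noPeak,
      centromereInsulation = res$centromereInsulation,
      dotScore = res$dotScore,
      stripeFile = stripeFile,
      pileupFiles = pileFiles)
  }

  ## optional calibrated ChIP stage (synthetic mode)
  if (cfg$mode == "synthetic" && !is.null(cfg$chip)) {
    chip <- stage("chip", {
      sites <- features[features$kind != "centromere"]
      sam <- simulateChipReads(
        genome, sites,
        occupancy = numOr(cfg$chip$occupancy, 50),
        ipEfficiency = numOr(cfg$chip$ipEfficiency, 4),
        seed = cfg$seed + 104729)
      track <- calibrateTrack(sam)
      prof <- featureMetaprofile(track,
                                 features[features$kind == "border"])
      writeMetaProfileTSV(prof, file.path(cfg$outputDir,
                                          "chip.border.profile.tsv"))
      writeBedGraph(track, file.path(cfg$outputDir,
                                     "chip.calibrated.bedgraph"))
      list(occupancyRatio = occupancyRatio(sam))
    })
    samples[["chip"]] <- chip
  }

  report <- list(
    package = "perimap",
    version = as.character(packageVersion("perimap")),
    generated = format(t0, "%Y-%m-%d %H:%M:%S"),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "outputDir")],
    samples = samples,
    warnings = warningsEnv$w)
  jsonlite::write_json(report, file.path(cfg$outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("[done] %d condition(s) in %.1f s",
                  length(conditions),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(report = report, objects = objects))
}

#' Compare conditions: ratio pileups and a loop-size ordering table
#'
#' For each requested pair (a, b) builds the log2 ratio of their centromere
#' and border pileups, and tabulates every condition's loop-size estimate
#' ordered from smallest to largest. With an empty pairing only the table
#' is produced.
#'
#' @param run the value of [runPipeline()].
#' @param pairing list of two-element character vectors `c(a, b)`;
#'   conditions must share resolution and features (guaranteed within one
#'   run).
#' @param outputDir optional directory for ratio pileup TSVs.
#' @return A list with `table` (data.frame: id, loopSize, noPeak, rank) and
#'   `ratios` (named list of per-pair [RatioPileup-class] lists).
#' @export
compareConditions <- function(run, pairing = list(), outputDir = NULL) {
  samples <- run$report$samples
  samples <- samples[!vapply(samples, function(s) is.null(s$loopSize),
                             logical(1))]
  tab <- data.frame(
    id = vapply(samples, `[[`, character(1), "id"),
    loopSize = vapply(samples, `[[`, numeric(1), "loopSize"),
    noPeak = vapply(samples, `[[`, logical(1), "noPeak"))
  tab <- tab[order(tab$loopSize), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL

  ratios <- list()
  for (pr in pairing) {
    a <- pr[[1]]; b <- pr[[2]]
    if (is.null(run$objects$pileups[[a]]) ||
        is.null(run$objects$pileups[[b]]))
      stop(sprintf("unknown condition in pairing: %s/%s", a, b))
    key <- paste(a, b, sep = "_vs_")
    ratios[[key]] <- lapply(names(run$objects$pileups[[a]]), function(pk) {
      r <- ratioPileup(run$objects$pileups[[a]][[pk]],
                       run$objects$pileups[[b]][[pk]])
      if (!is.null(outputDir))
        writePileupTSV(r, file.path(outputDir,
                                    sprintf("ratio.%s.%s.tsv", key, pk)))
      r
    })
    names(ratios[[key]]) <- names(run$objects$pileups[[a]])
  }
  list(table = tab, ratios = ratios)
}
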