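test_that("occupancy ratio follows Wc*IPx/(Wx*IPc)", {
  expect_equal(occupancyRatio(c(Wx = 5, Wc = 5, IPx = 7, IPc = 7)), 1)
  expect_equal(
    occupancyRatio(c(Wc = 2e6, Wx = 1e6, IPx = 3e6, IPc = 1.5e6)), 4.0)

  # invariant under joint rescaling of the IP pair and of the input pair
  base <- c(Wx = 1.1e6, Wc = 0.8e6, IPx = 2.2e6, IPc = 0.6e6)
  for (cfac in c(0.5, 3, 10)) {
    scaledIP <- base * c(1, 1, cfac, cfac)
    scaledW <- base * c(cfac, cfac, 1, 1)
    expect_equal(occupancyRatio(scaledIP), occupancyRatio(base))
    expect_equal(occupancyRatio(scaledW), occupancyRatio(base))
  }

  expect_error(occupancyRatio(c(Wx = 0, Wc = 1, IPx = 1, IPc = 1)), "Wx")
  expect_error(occupancyRatio(c(Wx = 1, Wc = 1, IPx = 1, IPc = 0)), "IPc")
})

test_that("calibrated tracks are depth-invariant and propagate masks", {
  g <- makeGenome(1, 1e4, 0.5)
  cov <- list(chr01 = c(0, 3, 10, NA, 4, 0, 1, 2, 5, 175))
  mk <- function(f) CalibSample(
    g, c(Wx = 1e6, Wc = 2e6, IPx = 200 * f, IPc = 1e6 * f),
    lapply(cov, function(v) v * f), binWidth = 1000)

  t1 <- calibrateTrack(mk(1))
  t2 <- calibrateTrack(mk(2))   # IP depth doubled for both genomes
  expect_equal(t1@values, t2@values)
  expect_true(is.na(t1@values$chr01[4]))

  zero <- CalibSample(g, c(Wx = 1e6, Wc = 1e6, IPx = 0, IPc = 1e6),
                      list(chr01 = rep(0, 10)), binWidth = 1000)
  expect_error(calibrateTrack(zero), "IPx")
})

test_that("a 2:1 occupancy ratio is recovered from simulated sample pairs", {
  g <- testGenome()
  f <- makeFeatures(g, 20000, nArmSites = 0)
  borders <- f[f$kind == "border"]
  fbin <- floor((start(borders) - 1) / 50) + 1
  chs <- as.character(GenomeInfoDb::seqnames(borders))

  peakOf <- function(occ, seed) {
    s <- simulateChipReads(g, borders, occupancy = occ, ipEfficiency = 4,
                           seed = seed)
    tr <- calibrateTrack(s)
    mean(vapply(seq_along(borders), function(i)
      tr@values[[chs[i]]][fbin[i]], numeric(1)))
  }
  ratios <- vapply(1:6, function(sd)
    peakOf(100, sd) / peakOf(50, sd + 100), numeric(1))
  expect_lt(abs(median(ratios) - 2) / 2, 0.1)
})

test_that("metaprofiles average, orient and bound correctly", {
  g <- makeGenome(1, 1e5, 0.5)
  nb <- 1e5 / 50
  v <- sin(seq_len(nb) / 7) + 2
  track <- new("CalibratedTrack", genome = g, sampleId = "t",
               binWidth = 50, values = list(chr01 = v))

  one <- makeFeatures(g, 20000, nArmSites = 0)
  one <- one[one$kind == "centromere"]
  prof1 <- featureMetaprofile(track, one, flank = 1000)
  expect_true(all(prof1@se == 0))
  mid <- start(one) - 1
  expect_equal(prof1@mean[prof1@offsets == 0],
               v[floor(mid / 50) + 1])

  # a track mirror-symmetric about the centromere gives identical oriented
  # profiles for left- and right-arm borders
  cmid <- unname(centromereMidpoints(g))
  bins <- (seq_len(nb) - 0.5) * 50
  vsym <- cos((bins - cmid) / 900) + 2
  strack <- new("CalibratedTrack", genome = g, sampleId = "s",
                binWidth = 50, values = list(chr01 = vsym))
  borders <- makeFeatures(g, 10000, nArmSites = 0)
  borders <- borders[borders$kind == "border"]
  pl <- featureMetaprofile(strack, borders[borders$armSide == "left"],
                           flank = 2000)
  pr <- featureMetaprofile(strack, borders[borders$armSide == "right"],
                           flank = 2000)
  expect_equal(pl@mean, pr@mean, tolerance = 1e-12)

  # constant track: constant profile with zero SE
  ctrack <- new("CalibratedTrack", genome = g, sampleId = "c",
                binWidth = 50, values = list(chr01 = rep(3, nb)))
  pc <- featureMetaprofile(ctrack, borders, flank = 2000)
  expect_true(all(pc@mean == 3) && all(pc@se == 0))

  coarse <- new("CalibratedTrack", genome = g, sampleId = "x",
                binWidth = 75, values = list(chr01 = rep(1, 1334)))
  expect_error(featureMetaprofile(coarse, borders), "divide")
  expect_error(featureMetaprofile(track, borders[0]), "empty")
})

test_that("simulated border peaks are found at offset 0 at the true height", {
  g <- testGenome()
  f <- makeFeatures(g, 20000, nArmSites = 0)
  borders <- f[f$kind == "border"]
  s <- simulateChipReads(g, borders, occupancy = 50, ipEfficiency = 4,
                         seed = 11)
  prof <- featureMetaprofile(calibrateTrack(s), borders)
  expect_equal(abs(prof@offsets[which.max(prof@mean)]), 0)

  oracle <- perimap:::expectedCalibratedPeak(
    g, borders, 50, 4, 1e6, 1e6, 1e6, 1e6)[1]
  i0 <- which(prof@offsets == 0)
  expect_lt(abs(prof@mean[i0] - oracle), 3 * prof@se[i0] + 1e-12)
})

test_that("qPCR enrichment implements dilution-corrected delta-Ct", {
  expect_equal(qpcrEnrichment(20, 20, 2, 1), 1.0)

  dCt <- 25 - (20 - log2(500))
  expect_equal(dCt, 13.9658, tolerance = 1e-4)
  expect_equal(qpcrEnrichment(25, 20, 2, 500), 2^(-dCt))
  expect_equal(qpcrEnrichment(25, 20, 2, 500), 6.25e-5, tolerance = 1e-3)

  # one extra ChIP cycle at efficiency 2 halves the enrichment
  expect_equal(qpcrEnrichment(26, 20, 2, 500),
               qpcrEnrichment(25, 20, 2, 500) / 2)
  expect_error(qpcrEnrichment(25, 20, efficiency = 1), "efficiency")
})
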