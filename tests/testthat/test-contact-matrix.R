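test_that("binPairs maps positions to floor(pos/res) bins", {
  g <- makeGenome(1, 1e4, 0.5)
  empty <- binPairs(
    data.frame(chrom1 = character(0), pos1 = numeric(0),
               chrom2 = character(0), pos2 = numeric(0)), g, 1000)
  expect_true(all(rawCounts(empty, "chr01") == 0))

  m <- binPairs(data.frame(chrom1 = "chr01", pos1 = 1500,
                           chrom2 = "chr01", pos2 = 3500), g, 1000)
  C <- rawCounts(m, "chr01")
  expect_equal(C[2, 4], 1)  # 0-based bins 1 and 3
  expect_equal(C[4, 2], 1)
  expect_equal(sum(C), 2)

  # diagonal pair counted once
  md <- binPairs(data.frame(chrom1 = "chr01", pos1 = 1100,
                            chrom2 = "chr01", pos2 = 1900), g, 1000)
  expect_equal(rawCounts(md, "chr01")[2, 2], 1)
})

test_that("binPairs conserves accepted pairs and reports skips", {
  set.seed(42)
  g <- testGenome()
  n <- 1e4
  ch <- sample(chromNames(g), n, replace = TRUE)
  ch2 <- ifelse(runif(n) < 0.9, ch, sample(chromNames(g), n, replace = TRUE))
  pairs <- data.frame(
    chrom1 = ch, pos1 = floor(runif(n, 0, 4e5)),
    chrom2 = ch2, pos2 = floor(runif(n, 0, 4e5)))
  pairs$chrom1[1:25] <- "chrUn"

  expect_warning(m <- binPairs(pairs, g, 1000), "25 record")
  nCis <- sum(pairs$chrom1 == pairs$chrom2 & pairs$chrom1 != "chrUn")
  total <- sum(vapply(chromNames(g), function(c2) {
    C <- rawCounts(m, c2)
    sum(C[upper.tri(C, diag = TRUE)])
  }, numeric(1)))
  expect_equal(total, nCis)
  expect_equal(m@transPairs + total + 25, n)

  bad <- data.frame(chrom1 = "chr01", pos1 = 4e5 + 1,
                    chrom2 = "chr01", pos2 = 10)
  expect_error(binPairs(bad, g, 1000), "bounds")
})

test_that("iterative correction equalizes marginals and is idempotent", {
  g <- makeGenome(1, 5e4, 0.5)

  # a doubly-stochastic-like matrix is a fixed point: weights all equal
  n <- 50
  A <- matrix(1 / n, n, n)
  mA <- iceBalance(ContactMatrix(g, 1000, list(chr01 = A)),
                   lowCoverageFraction = 0)
  wA <- balancingWeights(mA, "chr01")
  expect_lt(diff(range(wA)), 1e-10)

  for (sd in 1:5) {
    set.seed(sd)
    R <- matrix(runif(n * n, 0.2, 3), n, n)
    R <- (R + t(R)) / 2
    m0 <- ContactMatrix(g, 1000, list(chr01 = R))
    mB <- iceBalance(m0, lowCoverageFraction = 0)
    w <- balancingWeights(mB, "chr01")

    marg <- rowSums(outer(w, w) * R)
    expect_lt(sd(marg) / mean(marg), 1e-5)     # convergence contract
    expect_equal(mean(marg), 1, tolerance = 1e-6)

    # raw counts untouched; symmetry preserved
    expect_identical(rawCounts(mB, "chr01"), R)

    # independent brute-force doubly-stochastic oracle
    wOracle <- sinkhornOracle(R)
    ratio <- w / (wOracle / sqrt(mean(rowSums(outer(wOracle, wOracle) * R))))
    expect_lt(max(abs(ratio / mean(ratio) - 1)), 1e-4)

    # idempotence: rebalancing changes weights by < tol
    w2 <- balancingWeights(iceBalance(mB, lowCoverageFraction = 0), "chr01")
    expect_lt(max(abs(w2 / w - 1)), 1e-4)
  }
})

test_that("low-coverage masking is applied and never reverts", {
  g <- makeGenome(1, 5e4, 0.5)
  set.seed(7)
  n <- 50
  R <- matrix(rpois(n * n, 20), n, n); R <- R + t(R)
  R[, 3] <- R[3, ] <- 0                       # dead bin
  R[, 10] <- R[10, ] <- rpois(n, 0.2)         # weak bin
  R[10, ] <- R[, 10]
  m <- iceBalance(ContactMatrix(g, 1000, list(chr01 = R)))
  expect_false(validBins(m, "chr01")[3])
  expect_true(is.na(balancingWeights(m, "chr01")[3]))

  masked0 <- !validBins(m, "chr01")
  m2 <- iceBalance(m)
  expect_true(all(!validBins(m2, "chr01")[masked0]))  # mask monotone

  allZero <- ContactMatrix(g, 1000, list(chr01 = matrix(0, n, n)))
  expect_error(iceBalance(allZero), "all bins masked")
})

test_that("cisSubmatrix windows, masks and errors behave", {
  g <- makeGenome(1, 2e4, 0.5)
  set.seed(1)
  n <- 20
  R <- matrix(rpois(n * n, 30), n, n); R <- R + t(R)
  raw <- ContactMatrix(g, 1000, list(chr01 = R))
  expect_error(cisSubmatrix(raw, "chr01", 0, 2e4, balanced = TRUE),
               "not balanced")

  m <- iceBalance(raw, lowCoverageFraction = 0)
  full <- cisSubmatrix(m, "chr01", 0, 2e4, balanced = FALSE)
  expect_equal(unname(full), unname(R))
  w <- balancingWeights(m, "chr01")
  expect_equal(cisSubmatrix(m, "chr01", 0, 2e4), outer(w, w) * R)

  R2 <- R; R2[, 5] <- R2[5, ] <- 0
  m2 <- iceBalance(ContactMatrix(g, 1000, list(chr01 = R2)))
  win <- cisSubmatrix(m2, "chr01", 2000, 8000)
  expect_true(all(is.na(win[3, ])) && all(is.na(win[, 3])))

  expect_error(cisSubmatrix(m, "chr01", -5, 100), "window")
  expect_error(cisSubmatrix(m, "chr99", 0, 100), "unknown chromosome")
})

test_that("pairs, matrix TSV and annotation files round-trip", {
  tmp <- withr::local_tempdir()
  g <- testGenome()

  set.seed(3)
  pairs <- data.frame(
    chrom1 = sample(chromNames(g), 200, replace = TRUE),
    pos1 = floor(runif(200, 0, 4e5)),
    chrom2 = sample(chromNames(g), 200, replace = TRUE),
    pos2 = floor(runif(200, 0, 4e5)))
  pf <- file.path(tmp, "x.pairs")
  writePairs(pairs, pf, genome = g)
  back <- readPairs(pf)
  expect_equal(back$pos1, pairs$pos1)
  expect_equal(back$chrom2, pairs$chrom2)

  m <- iceBalance(binPairs(pairs, g, 10000))
  writeContactMatrixTSV(m, file.path(tmp, "m"))
  m2 <- readContactMatrixTSV(file.path(tmp, "m"), g, 10000)
  expect_equal(rawCounts(m2, "chr01"), unname(rawCounts(m, "chr01")))
  expect_equal(balancingWeights(m2, "chr02"), balancingWeights(m, "chr02"))

  cs <- file.path(tmp, "g.chrom.sizes")
  writeChromSizes(g, cs)
  expect_equal(readChromSizes(cs), chromLengths(g))

  f <- makeFeatures(g, 20000, nArmSites = 1)
  bf <- file.path(tmp, "f.bed")
  writeFeaturesBed(f, bf)
  f2 <- readFeaturesBed(bf)
  expect_equal(start(f2), start(f))
  expect_equal(f2$kind, f$kind)
  expect_equal(f2$armSide, f$armSide)

  s <- simulateChipReads(g, f[f$kind == "border"], occupancy = 10,
                         depthIPx = 1e5, seed = 2)
  tr <- calibrateTrack(s)
  bg <- file.path(tmp, "t.bedgraph")
  writeBedGraph(tr, bg)
  vals <- readBedGraphTrack(bg, g, 50)
  expect_equal(vals$chr01, tr@values$chr01)

  tf <- file.path(tmp, "totals.tsv")
  covf <- file.path(tmp, "cov.bedgraph")
  writeTotalsTSV(s, tf)
  writeBedGraph(s, covf)
  s2 <- readCalibSampleTSV(tf, g, coveragePath = covf)
  expect_equal(s2@totals, s@totals)
  expect_equal(occupancyRatio(s2), occupancyRatio(s))
  expect_equal(s2@coverage$chr02, s@coverage$chr02)

  qf <- file.path(tmp, "qpcr.tsv")
  write.table(
    data.frame(target = c("a", "b"), ct_chip = c(25, 24),
               ct_input = c(20, 20), efficiency = 2, dilution = 500),
    qf, sep = "\t", quote = FALSE, row.names = FALSE)
  q <- qpcrEnrichmentTable(readQpcrTable(qf))
  expect_equal(q$enrichment[1], 6.25e-5, tolerance = 1e-3)
  expect_equal(q$enrichment[2] / q$enrichment[1], 2)
})

test_that("matrixToPairs inverts binPairs at the bin level", {
  g <- testGenome()
  tr <- syntheticTruth(1.5, 2e4, dotStrength = 4)
  sim <- simulateContactMap(g, tr, 10000, 2e4, seed = 17)
  pairs <- matrixToPairs(sim$map)
  rebinned <- binPairs(pairs, g, 10000)
  for (ch in chromNames(g))
    expect_equal(rawCounts(rebinned, ch), rawCounts(sim$map, ch))

  tmp <- withr::local_tempdir()
  tr2 <- readTruthJSON(writeTruthJSON(sim$truth,
                                      file.path(tmp, "truth.json")))
  expect_equal(tr2@loopSize, sim$truth@loopSize)
  expect_equal(tr2@anchorPositions, sim$truth@anchorPositions)
})
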