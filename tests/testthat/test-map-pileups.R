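balancedSyntheticMap <- function(seed = 5, dotStrength = 4, nChrom = 1,
                                 chromLength = 4e5, depth = 1e6,
                                 sample = FALSE, boundaryInsulation = 1,
                                 boundaryPositions = list(),
                                 stripeStrength = 1, loopSize = 2e4) {
  g <- makeGenome(nChrom, chromLength, 0.3)
  tr <- syntheticTruth(1.5, loopSize, dotStrength = dotStrength,
                       stripeStrength = stripeStrength,
                       boundaryInsulation = boundaryInsulation,
                       boundaryPositions = boundaryPositions)
  sim <- simulateContactMap(g, tr, 1000, depth, seed = seed,
                            sample = sample)
  m <- if (sample) iceBalance(sim$map) else unitBalanced(sim$map)
  list(map = m, truth = sim$truth, genome = g)
}

test_that("a single plain pileup equals the feature's own window", {
  s <- balancedSyntheticMap()
  f <- makeFeatures(s$genome, 20000, nArmSites = 0)
  cen <- f[f$kind == "centromere"]
  p <- snipPileup(s$map, cen, flank = 10000, mode = "plain")
  mid <- start(cen) - 1
  win <- cisSubmatrix(s$map, "chr01", mid - 10000, mid + 11000)
  expect_equal(unname(p@matrix), unname(win))
})

test_that("mirrored pileups are exactly symmetric", {
  s <- balancedSyntheticMap(sample = TRUE, nChrom = 2)
  f <- makeFeatures(s$genome, 20000, nArmSites = 0)
  cen <- f[f$kind == "centromere"]
  p <- snipPileup(s$map, cen, flank = 50000, mode = "mirrored")
  rv <- rev(seq_len(nrow(p@matrix)))
  expect_identical(unname(p@matrix), unname(p@matrix[rv, rv]))
  expect_identical(unname(p@nPerPixel), unname(p@nPerPixel[rv, rv]))
})

test_that("oriented pileups reverse right-arm features", {
  s <- balancedSyntheticMap(sample = TRUE)
  f <- makeFeatures(s$genome, 30000, nArmSites = 0)
  right <- f[f$kind == "border" & f$armSide == "right"]
  pOriented <- snipPileup(s$map, right, flank = 10000, mode = "oriented")
  pPlain <- snipPileup(s$map, right, flank = 10000, mode = "plain")
  rv <- rev(seq_len(nrow(pPlain@matrix)))
  expect_equal(pOriented@matrix, pPlain@matrix[rv, rv])
})

test_that("features on unknown chromosomes are skipped with a warning", {
  s <- balancedSyntheticMap()
  f <- makeFeatures(makeGenome(2, 4e5, 0.3), 20000, nArmSites = 0)
  cen <- f[f$kind == "centromere"]     # chr02 absent from the 1-chrom map
  expect_warning(p <- snipPileup(s$map, cen, flank = 5000), "absent")
  expect_equal(p@nFeatures, 1)
})

test_that("ratio pileups are zero on self and antisymmetric", {
  s1 <- balancedSyntheticMap(seed = 1, sample = TRUE)
  s2 <- balancedSyntheticMap(seed = 2, sample = TRUE)
  f <- makeFeatures(s1$genome, 20000, nArmSites = 0)
  cen <- f[f$kind == "centromere"]
  a <- snipPileup(s1$map, cen, flank = 20000, mode = "mirrored")
  b <- snipPileup(s2$map, cen, flank = 20000, mode = "mirrored")

  self <- ratioPileup(a, a)
  expect_true(all(self@matrix[!is.na(self@matrix)] == 0))

  ab <- ratioPileup(a, b); ba <- ratioPileup(b, a)
  expect_identical(ab@matrix, -ba@matrix)

  small <- snipPileup(s1$map, cen, flank = 10000, mode = "mirrored")
  expect_error(ratioPileup(a, small), "mismatched")
})

test_that("weakened insulation shows up in the cross quadrants of ratios", {
  mk <- function(ins) balancedSyntheticMap(
    seed = 3, dotStrength = 1, boundaryInsulation = ins,
    boundaryPositions = list(chr01 = 120000))
  strong <- mk(0.25); weak <- mk(1.0)
  g <- strong$genome
  f <- makeFeatures(g, 20000, nArmSites = 0)
  cen <- f[f$kind == "centromere"]     # centromere mid = boundary position
  a <- snipPileup(weak$map, cen, flank = 20000, mode = "mirrored")
  b <- snipPileup(strong$map, cen, flank = 20000, mode = "mirrored")
  r <- ratioPileup(a, b)@matrix
  c0 <- (nrow(r) + 1) / 2
  topRight <- r[seq_len(c0 - 1), (c0 + 1):ncol(r)]
  sameSide <- r[(c0 + 1):nrow(r), (c0 + 1):ncol(r)]
  expect_gt(mean(topRight, na.rm = TRUE), 0)
  expect_gt(mean(topRight, na.rm = TRUE),
            mean(sameSide, na.rm = TRUE) + 0.5)
})

test_that("insulation scores uniform maps at zero and recovers log2(m)", {
  u <- uniformMatrix(n = 201)
  expect_equal(insulationScore(u, "chr01", 1e5, window = 20000), 0)

  for (m in c(0.125, 0.25, 0.5)) {
    s <- balancedSyntheticMap(dotStrength = 1, boundaryInsulation = m,
                              boundaryPositions = list(chr01 = 2e5))
    sc <- insulationScore(s$map, "chr01", 2e5)
    expect_lt(abs(sc - log2(m)), 0.3)
  }

  expect_error(insulationScore(u, "chr01", 3000, window = 20000), "fit")
})

test_that("dot scores are 1 on uniform pileups and grow with enrichment", {
  u <- uniformMatrix(n = 41)
  g <- makeGenome(1, 41000, 0.5)
  f <- makeFeatures(g, 5000, nArmSites = 0)
  p <- snipPileup(u, f[f$kind == "centromere"], flank = 15000)
  expect_equal(dotScore(p), 1.0)

  scores <- vapply(c(1, 2, 4, 8), function(D) {
    s <- balancedSyntheticMap(dotStrength = D, seed = 6)
    dp <- anchorPairPileup(s$map, s$truth@anchorPositions, flank = 10000)
    dotScore(dp)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_true(all(scores[-1] > 1 & scores[-1] < c(2, 4, 8)))

  masked <- p
  half <- (nrow(masked@matrix) + 1) / 2
  masked@matrix[half + (-1:1), half + (-1:1)] <- NA_real_
  expect_true(is.na(dotScore(masked)))
  expect_error(dotScore(p, centerSize = 21), "too small")
})

test_that("stripe profiles flag one-sided anchors only", {
  flat <- balancedSyntheticMap(dotStrength = 1, seed = 9)
  a <- flat$truth@anchorPositions$chr01[6]
  sp0 <- stripeProfile(flat$map, "chr01", a, maxDistance = 3e4)
  expect_equal(sp0$right, sp0$left, tolerance = 1e-10)  # pure decay

  striped <- balancedSyntheticMap(dotStrength = 1, stripeStrength = 3,
                                  seed = 9)
  a2 <- striped$truth@anchorPositions$chr01[6]
  sp <- stripeProfile(striped$map, "chr01", a2, maxDistance = 3e4)
  expect_gt(mean(sp$right[1:20] / sp$left[1:20]), 1.2)

  expect_warning(
    stripeProfile(flat$map, "chr01", 395000, maxDistance = 5e4),
    "truncated")
})
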