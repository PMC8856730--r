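test_that("an exact power law has constant slope -alpha", {
  g <- makeGenome(1, 4e5, 0.3)
  for (alpha in c(1.0, 1.5)) {
    m <- powerLawMatrix(g, 1000, alpha)
    ps <- slopeCurve(contactProbability(m, excludeCrossCentromere = FALSE))
    interior <- seq(2, length(ps@distances) - 1)
    # the arithmetic per-pixel mean inside a multi-offset log bin deviates
    # from the power law at the bin representative by O((bin width)^2),
    # which bounds the residual slope wiggle at ~1e-2
    expect_lt(max(abs(ps@slope[interior] + alpha)), 0.01)
  }
})

test_that("a constant matrix has slope 0", {
  m <- uniformMatrix(n = 200)
  ps <- slopeCurve(contactProbability(m, excludeCrossCentromere = FALSE))
  expect_lt(max(abs(ps@slope), na.rm = TRUE), 1e-10)
})

test_that("contacts confined below 10 kb leave distal bins at zero", {
  g <- makeGenome(1, 2e5, 0.5)
  n <- 200
  d <- abs(outer(seq_len(n), seq_len(n), "-")) * 1000
  C <- ifelse(d <= 10000, 5, 0)
  m <- unitBalanced(ContactMatrix(g, 1000, list(chr01 = C)))
  ps <- contactProbability(m, excludeCrossCentromere = FALSE)
  # the log bin straddling 10 kb mixes filled and empty offsets; every bin
  # fully beyond the cutoff (lower edge > 10 kb, i.e. rep > 11.6 kb) is 0
  expect_true(all(ps@p[ps@distances > 11600] == 0))
  expect_true(all(ps@p[ps@distances <= 9000] > 0))
})

test_that("cross-centromere exclusion is a no-op for one-arm chromosomes", {
  # centromere interval at the very chromosome end, past every bin
  # midpoint: all bins lie on one arm
  g <- GenomeAssembly(c(chr01 = 2e5),
                      centromereStart = c(chr01 = 199750),
                      centromereEnd = c(chr01 = 199950))
  set.seed(4)
  n <- 200
  C <- matrix(rpois(n * n, 4), n, n); C <- C + t(C)
  m <- unitBalanced(ContactMatrix(g, 1000, list(chr01 = C)))
  psOn <- contactProbability(m, excludeCrossCentromere = TRUE)
  psOff <- contactProbability(m, excludeCrossCentromere = FALSE)
  expect_equal(psOn@p, psOff@p)
  expect_equal(psOn@nPixels, psOff@nPixels)
})

test_that("cross-centromere pixels are excluded when asked", {
  g <- makeGenome(1, 2e5, 0.5)
  # contacts only across the centromere midpoint
  n <- 200
  left <- seq_len(100); right <- 101:200
  C <- matrix(0, n, n)
  C[left, right] <- 3; C[right, left] <- 3
  m <- unitBalanced(ContactMatrix(g, 1000, list(chr01 = C)))
  psOn <- contactProbability(m, excludeCrossCentromere = TRUE)
  expect_true(all(psOn@p == 0))
  psOff <- contactProbability(m, excludeCrossCentromere = FALSE)
  expect_gt(sum(psOff@p), 0)
})

test_that("slopeCurve needs enough nonzero bins", {
  g <- makeGenome(1, 5e3, 0.5)
  C <- matrix(0, 5, 5); C[1, 2] <- C[2, 1] <- 1
  m <- unitBalanced(ContactMatrix(g, 1000, list(chr01 = C)))
  ps <- contactProbability(m, excludeCrossCentromere = FALSE)
  expect_error(slopeCurve(ps), "nonzero")
})

test_that("loop-size estimator finds the anchor spacing on expectations", {
  g <- testGenome(4, 7e5)
  tr <- syntheticTruth(decayExponent = 1.5, loopSize = 2e4, dotStrength = 4)
  sim <- simulateContactMap(g, tr, 1000, 5e6, seed = 11, sample = FALSE)
  ps <- slopeCurve(contactProbability(unitBalanced(sim$map)))
  est <- loopSizeEstimate(ps)
  expect_false(est$noPeak)
  # within one log-spaced bin (16/decade) of the true 20 kb spacing
  expect_lt(abs(log10(est$estimate / 2e4)), 1.5 / 16)

  # monotone in L on expectation matrices
  estOf <- function(L, seed) {
    trL <- syntheticTruth(1.5, L, dotStrength = 4)
    s <- simulateContactMap(g, trL, 1000, 5e6, seed = seed, sample = FALSE)
    loopSizeEstimate(slopeCurve(contactProbability(unitBalanced(s$map))))
  }
  e10 <- estOf(1e4, 2); e40 <- estOf(4e4, 3)
  expect_lt(e10$estimate, e40$estimate)
})

test_that("pure power-law maps raise the no-peak flag", {
  g <- testGenome(4, 7e5)
  m <- powerLawMatrix(g, 1000, 1.5)
  ps <- slopeCurve(contactProbability(m))
  est <- muffleWarnings(loopSizeEstimate(ps))
  expect_true(est$noPeak)
  expect_warning(loopSizeEstimate(ps), "no-peak")
})

test_that("sampled slope tracks the expectation slope", {
  g <- testGenome(2, 7e5)
  tr <- syntheticTruth(decayExponent = 1.5, loopSize = 2e4, dotStrength = 4)
  simE <- simulateContactMap(g, tr, 1000, 3e6, seed = 8, sample = FALSE)
  simS <- simulateContactMap(g, tr, 1000, 3e6, seed = 8)
  psE <- slopeCurve(contactProbability(unitBalanced(simE$map)))
  psS <- slopeCurve(contactProbability(iceBalance(simS$map)))
  # compare where the sampled curve is well determined (many pixels), and
  # allow each bin its own Poisson slope error: with T expected counts the
  # log10(p) sd is 0.434/sqrt(T), and the window-3 regression over log-bins
  # spaced 1/16 apart scales that by 1/(sqrt(2)/16)
  shared <- which(psE@nPixels > 1e3 & psE@p * psE@nPixels > 100)
  shared <- intersect(shared, seq_along(psS@slope))
  counts <- (psE@p * psE@nPixels)[shared]
  slopeSd <- (0.434 / sqrt(counts)) / (sqrt(2) / 16)
  dev <- abs(psS@slope[shared] - psE@slope[shared])
  expect_true(all(dev < pmax(0.1, 4 * slopeSd), na.rm = TRUE))
})

test_that("P(s) is invariant to uniform count scaling", {
  g <- makeGenome(1, 2e5, 0.3)
  tr <- syntheticTruth(1.5, 2e4, dotStrength = 4)
  sim <- simulateContactMap(g, tr, 1000, 5e5, seed = 13)
  m1 <- iceBalance(sim$map)
  scaled <- ContactMatrix(g, 1000,
                          lapply(sim$map@counts, function(x) x * 7))
  m2 <- iceBalance(scaled)
  p1 <- contactProbability(m1)@p
  p2 <- contactProbability(m2)@p
  expect_equal(p1, p2, tolerance = 1e-6)
})
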