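# shared fixtures and independent oracles, all built in code

# small genome used throughout: 2 chromosomes, centromere at 30%
testGenome <- function(nChrom = 2, chromLength = 4e5, frac = 0.3) {
  makeGenome(nChrom, chromLength, frac)
}

# contact matrix built directly from an exact power law (no sampling, unit
# weights), bypassing the generator: C_ij = d_ij^(-alpha)
powerLawMatrix <- function(genome, resolution, alpha) {
  nb <- ceiling(chromLengths(genome) / resolution)
  counts <- lapply(chromNames(genome), function(ch) {
    n <- nb[[ch]]
    d <- abs(outer(seq_len(n), seq_len(n), "-")) * resolution
    diag(d) <- resolution / 2
    d^(-alpha)
  })
  names(counts) <- chromNames(genome)
  unitBalanced(ContactMatrix(genome, resolution, counts))
}

# independent brute-force doubly-stochastic scaler (bipartite Sinkhorn on
# rows/columns); returns symmetric per-bin weights with balanced marginal 1
sinkhornOracle <- function(C, maxIter = 10000, tol = 1e-12) {
  n <- nrow(C)
  u <- rep(1, n); v <- rep(1, n)
  for (it in seq_len(maxIter)) {
    uNew <- 1 / as.vector(C %*% v)
    vNew <- 1 / as.vector(t(C) %*% uNew)
    if (max(abs(uNew - u), abs(vNew - v)) < tol) {
      u <- uNew; v <- vNew; break
    }
    u <- uNew; v <- vNew
  }
  sqrt(u * v)
}

# uniform (constant) balanced matrix on one chromosome
uniformMatrix <- function(n = 101, value = 1, resolution = 1000,
                          chromLength = NULL) {
  if (is.null(chromLength)) chromLength <- n * resolution
  g <- makeGenome(1, chromLength, 0.5)
  counts <- list(chr01 = matrix(value, n, n))
  unitBalanced(ContactMatrix(g, resolution, counts))
}

muffleWarnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w)
    invokeRestart("muffleWarning"))
}
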