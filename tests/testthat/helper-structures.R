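# Small fixtures built in code; all analytic expectations were computed
# independently (characteristic polynomials / brute-force pseudo-inverse).

# equilateral triangle, side 3.8 A: complete contact graph K3 at cutoff 10
triangleK3 <- function() {
  calphaStructure(3.8 * rbind(c(0, 0, 0), c(1, 0, 0),
                              c(0.5, sqrt(3) / 2, 0)))
}

# collinear 3 points, 3.8 A apart: path graph at cutoff 5
path3 <- function() calphaStructure(cbind(c(0, 3.8, 7.6), 0, 0))

# a random connected structure, alternating chains and dumbbells by seed
randomConnected <- function(seed) {
  if (seed %% 2L == 0L) makeChain(20L + (seed %% 41L), seed = seed)
  else makeDumbbell(10L + (seed %% 16L), 3L, seed = seed)$structure
}

# two conformers of the same dumbbell separated by a large internal bend
wellSeparatedPair <- function(seed, amplitude = 12) {
  a <- makeDumbbell(15L, 3L, seed = seed)$structure
  b <- a
  b@coords <- coords(a) + outer(sin(seq_len(nResidues(a)) / 3),
                                c(amplitude, 0, 0))
  list(a = a, b = b)
}

# Rand index between two hard partitions
randIndex <- function(x, y) {
  n <- length(x)
  sameX <- outer(x, x, `==`)[upper.tri(diag(n))]
  sameY <- outer(y, y, `==`)[upper.tri(diag(n))]
  mean(sameX == sameY)
}

# direct residue-level correlation oracle from the full 3N covariance
covarianceCorrelationOracle <- function(X) {
  n <- ncol(X) / 3L
  D <- sweep(X, 2L, colMeans(X))
  C <- crossprod(D) / nrow(X)
  raw <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    raw[i, j] <- sum(diag(C[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j),
                            drop = FALSE]))
  raw / sqrt(outer(diag(raw), diag(raw)))
}
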