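test_that("Kirchhoff matrices encode the contact topology", {
  # K3: every pair within cutoff
  k <- buildKirchhoff(triangleK3(), cutoff = 10)
  expect_equal(k@gamma, rbind(c(2, -1, -1), c(-1, 2, -1), c(-1, -1, 2)))
  # path: only adjacent pairs within a 5 A cutoff
  kp <- buildKirchhoff(path3(), cutoff = 5)
  expect_equal(diag(kp@gamma), c(1, 2, 1))
  expect_equal(kp@gamma[1, 3], 0)
  # brute-force pairwise distance check on a 50-residue chain
  ch <- makeChain(50, seed = 11)
  kc <- buildKirchhoff(ch, cutoff = 10)
  d <- as.matrix(dist(coords(ch)))
  off <- -(d <= 10) * 1; diag(off) <- 0; dimnames(off) <- NULL
  expect_equal(kc@gamma - diag(diag(kc@gamma)), off)
  expect_equal(rowSums(kc@gamma), rep(0, 50))
})

test_that("decomposition reproduces analytic Laplacian spectra", {
  # K3 Laplacian eigenvalues {0, 3, 3} (characteristic polynomial)
  m <- gnmDecompose(buildKirchhoff(triangleK3(), 10))
  expect_equal(eigenvalues(m), c(0, 3, 3), tolerance = 1e-12)
  expect_identical(nZeroModes(m), 1L)
  # path-3 Laplacian eigenvalues {0, 1, 3}
  mp <- gnmDecompose(buildKirchhoff(path3(), 5))
  expect_equal(eigenvalues(mp), c(0, 1, 3), tolerance = 1e-12)
  # zero-mode eigenvector of a connected graph is uniform up to sign
  expect_equal(eigenvectors(mp)[, 1], rep(1 / sqrt(3), 3), tolerance = 1e-10)
  # two chains out of reach: two zero modes
  far <- calphaStructure(rbind(coords(path3()),
                               coords(path3()) + c(100, 0, 0)),
                         chain = rep(c("A", "B"), each = 3))
  expect_warning(md <- gnmDecompose(buildKirchhoff(far, 5)), "disconnected")
  expect_identical(nZeroModes(md), 2L)
})

test_that("full-range correlations equal the analytic pseudo-inverse", {
  # K3: pinv = (1/3)(I - J/3); raw diag 2/9, off -1/9, normalized off -0.5
  cmK3 <- crossCorrelations(gnmDecompose(buildKirchhoff(triangleK3(), 10)),
                            modeRange(1, 2))
  expect_equal(rawMap(cmK3),
               rbind(c(2, -1, -1), c(-1, 2, -1), c(-1, -1, 2)) / 9,
               tolerance = 1e-12)
  expect_equal(normalizedMap(cmK3),
               rbind(c(1, -0.5, -0.5), c(-0.5, 1, -0.5), c(-0.5, -0.5, 1)),
               tolerance = 1e-12)
  # path-3 raw map from the spectral sum over the two nonzero modes
  cmP <- crossCorrelations(gnmDecompose(buildKirchhoff(path3(), 5)),
                           modeRange(1, 2))
  expect_equal(rawMap(cmP),
               rbind(c(5, -1, -4), c(-1, 2, -1), c(-4, -1, 5)) / 9,
               tolerance = 1e-12)
  expect_equal(normalizedMap(cmP)[1, 3], -0.8, tolerance = 1e-12)
})

test_that("mode-restricted fluctuations match the map diagonal", {
  mp <- gnmDecompose(buildKirchhoff(path3(), 5))
  msf <- meanSquareFluctuations(mp, modeRange(1, 2))
  expect_equal(profileValues(msf), c(5, 2, 5) / 9, tolerance = 1e-12)
  # K3 symmetry: uniform fluctuations
  mk <- gnmDecompose(buildKirchhoff(triangleK3(), 10))
  expect_equal(profileValues(meanSquareFluctuations(mk, modeRange(1, 2))),
               rep(2 / 9, 3), tolerance = 1e-12)
  # MSF = diag(raw) for an arbitrary range on an arbitrary structure
  modes <- gnmDecompose(buildKirchhoff(makeChain(40, seed = 2), 10))
  r <- modeRange(2, 7)
  expect_equal(profileValues(meanSquareFluctuations(modes, r)),
               diag(rawMap(crossCorrelations(modes, r))))
})

test_that("GNM invariants hold on random connected structures", {
  skip_if_not_installed("MASS")
  for (seed in 1:12) {
    st <- randomConnected(seed)
    k <- buildKirchhoff(st, 10)
    modes <- gnmDecompose(k)
    expect_identical(nZeroModes(modes), 1L)
    expect_equal(rowSums(k@gamma), rep(0, nResidues(st)))
    expect_gt(min(eigenvalues(modes)), -1e-10)        # PSD
    n <- nResidues(st)
    full <- crossCorrelations(modes, modeRange(1, n - 1))
    # oracle: brute-force Moore-Penrose pseudo-inverse
    expect_lt(max(abs(rawMap(full) - MASS::ginv(k@gamma))), 1e-8)
    # normalized map bounded with exact unit diagonal
    sub <- crossCorrelations(modes, modeRange(1, min(10, n - 1)))
    expect_lte(max(abs(normalizedMap(sub))), 1 + 1e-12)
    expect_identical(diag(normalizedMap(sub)), rep(1, n))
    # nonzero modes are orthogonal to the uniform vector
    expect_lt(max(abs(colSums(eigenvectors(modes)[, -1]))), 1e-8)
  }
})

test_that("enlarging the mode range never decreases diagonal covariance", {
  modes <- gnmDecompose(buildKirchhoff(makeDumbbell(12, 3,
                                                    seed = 5)$structure, 10))
  prev <- rep(0, length(eigenvalues(modes)))
  for (last in c(1, 3, 6, 10, 20)) {
    cur <- profileValues(meanSquareFluctuations(modes, modeRange(1, last)))
    expect_true(all(cur >= prev - 1e-14))
    prev <- cur
  }
})

test_that("independent elastic-network implementation agrees", {
  # bio3d's GNM as an external cross-check on raw fluctuation covariance
  skip_if_not_installed("bio3d")
  ch <- makeChain(35, seed = 9)
  f <- tempfile(fileext = ".pdb")
  writeCalphaPdb(structureEnsemble(ch), f)
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  ref <- bio3d::gnm(pdb, cutoff = 10)
  modes <- gnmDecompose(buildKirchhoff(readPdbModels(f)[[1]], 10))
  expect_equal(sort(eigenvalues(modes))[-1], sort(ref$L)[-1],
               tolerance = 1e-6)
  full <- crossCorrelations(modes, modeRange(1, 34))
  expect_equal(normalizedMap(full), unname(bio3d::dccm(ref)[, ]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected", {
  expect_error(crossCorrelations(suppressWarnings(gnmDecompose(
    buildKirchhoff(calphaStructure(rbind(c(0, 0, 0), c(50, 0, 0))), 10))),
    modeRange(1, 1)), "connected")
  expect_error(buildKirchhoff(triangleK3(), cutoff = -1))
  st <- triangleK3()
  st@coords[1, 1] <- Inf
  expect_error(buildKirchhoff(st, 10))
  # range beyond the nonzero spectrum starts: error
  modes <- gnmDecompose(buildKirchhoff(path3(), 5))
  expect_error(crossCorrelations(modes, modeRange(5, 6)), "nonzero modes")
  # truncation of an over-long range is recorded
  cm <- crossCorrelations(modes, modeRange(1, 10))
  expect_match(cm@modeRange@label, "truncated")
  expect_identical(cm@modeRange@last, 2L)
})
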