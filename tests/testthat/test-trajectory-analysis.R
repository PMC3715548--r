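test_that("Kabsch superposition removes rigid motions and only those", {
  ch <- makeChain(30, seed = 5)
  th <- pi / 3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- ch
  moved@coords <- coords(ch) %*% R + matrix(c(5, -2, 8), 30, 3, byrow = TRUE)
  fit <- kabschSuperpose(moved, ch)
  expect_lt(fit$rmsd, 1e-8)
  expect_lt(max(abs(coords(fit$structure) - coords(ch))), 1e-7)
  # identity and symmetry
  expect_identical(kabschSuperpose(ch, ch)$rmsd, 0)
  other <- makeChain(30, seed = 6)
  expect_lt(abs(kabschSuperpose(ch, other)$rmsd -
                  kabschSuperpose(other, ch)$rmsd), 1e-10)
  # reflections are not rigid motions: a mirror image keeps RMSD > 0
  mirror <- ch
  mirror@coords <- coords(ch) %*% diag(c(-1, 1, 1))
  expect_gt(kabschSuperpose(mirror, ch)$rmsd, 0.1)
  # displacing one residue by d gives RMSD d / sqrt(N) (closed form; the
  # re-fit correction is O(1/N) and vanishes for large N)
  big <- makeChain(200, seed = 7)
  bumped <- big
  bumped@coords[77, ] <- bumped@coords[77, ] + c(0, 0, 2)
  expect_equal(kabschSuperpose(bumped, big)$rmsd, 2 / sqrt(200),
               tolerance = 0.05)
  expect_error(kabschSuperpose(ch, makeChain(25, seed = 1)),
               "identical residue lists")
})

test_that("Kabsch RMSD agrees with the bio3d reference fit", {
  skip_if_not_installed("bio3d")
  a <- makeDumbbell(12, 3, seed = 2)$structure
  b <- a
  set.seed(31)
  b@coords <- coords(a) + matrix(rnorm(3 * nResidues(a), 0, 1.5),
                                 ncol = 3)
  mine <- kabschSuperpose(b, a)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(coords(a))), as.numeric(t(coords(b))),
                     fit = TRUE)
  expect_equal(mine, ref, tolerance = 1e-4)
})

test_that("RMSD series follow the construction", {
  pair <- wellSeparatedPair(3)
  ts <- makeTwoStateTrajectory(pair$a, pair$b, nFrames = 15,
                               noiseSigma = 0.2, seed = 12)
  r <- rmsdSeries(ts$trajectory, reference = pair$a)
  expect_identical(length(r), 30L)
  sep <- kabschSuperpose(pair$a, pair$b)$rmsd
  # frames in state A stay near 0, frames in state B near the separation
  expect_lt(max(r[ts$labels == 1]), 1)
  expect_lt(max(abs(r[ts$labels == 2] - sep)), 1)
  # constant trajectory: all zeros
  const <- trajectory(rep(list(pair$a), 4))
  expect_equal(rmsdSeries(const), rep(0, 4), tolerance = 1e-10)
})

test_that("radius clustering recovers designed two-state partitions", {
  for (seed in c(1, 7)) {
    pair <- wellSeparatedPair(seed)
    ts <- makeTwoStateTrajectory(pair$a, pair$b, nFrames = 20,
                                 noiseSigma = 0.3, mixing = "random",
                                 seed = seed)
    expect_gte(ts$margin, 10)
    cl <- radiusCluster(ts$trajectory, radius = 3.5)
    expect_identical(length(clusterPopulations(cl)), 2L)
    expect_equal(randIndex(clusterAssignments(cl), ts$labels), 1.0)
    expect_identical(sum(clusterPopulations(cl)), 40L)
    # each best member belongs to its cluster (validity enforces it)
    expect_identical(clusterAssignments(cl)[bestMembers(cl)], 1:2)
  }
})

test_that("the radius controls the cluster count", {
  pair <- wellSeparatedPair(5)
  ts <- makeTwoStateTrajectory(pair$a, pair$b, nFrames = 10,
                               noiseSigma = 0.2, seed = 5)
  # radius beyond the set diameter covers everything
  diam <- max(rmsdSeries(ts$trajectory, reference = pair$a))
  cl1 <- radiusCluster(ts$trajectory, radius = diam + 5)
  expect_identical(length(clusterPopulations(cl1)), 1L)
  expect_identical(clusterPopulations(cl1), 20L)
  # identical frames always give one cluster
  const <- trajectory(rep(list(pair$a), 6))
  expect_identical(clusterPopulations(radiusCluster(const, 1)), 6L)
})

test_that("the recovered partition is frame-order invariant", {
  pair <- wellSeparatedPair(9)
  ts <- makeTwoStateTrajectory(pair$a, pair$b, nFrames = 15,
                               noiseSigma = 0.3, mixing = "block", seed = 9)
  cl1 <- radiusCluster(ts$trajectory, 3.5)
  perm <- c(seq(2, 30, by = 2), seq(1, 29, by = 2))
  shuffled <- trajectory(ts$trajectory@frames[perm])
  cl2 <- radiusCluster(shuffled, 3.5)
  # cluster indices may swap; the partition must not change
  expect_equal(randIndex(clusterAssignments(cl1)[perm],
                         clusterAssignments(cl2)), 1.0)
})

test_that("essential modes find a planted fluctuation direction", {
  st <- makeDumbbell(12, 3, seed = 6)$structure
  n <- nResidues(st)
  set.seed(41)
  d3 <- matrix(rnorm(3 * n), ncol = 3)
  d3 <- d3 / sqrt(sum(d3^2))
  frames <- lapply(1:40, function(t) {
    f <- st; f@coords <- coords(st) + 2 * sin(t / 3) * d3; f@modelId <- t; f
  })
  em <- suppressWarnings(essentialModes(trajectory(frames), 10,
                                        superpose = FALSE))
  ev <- eigenvalues(em)
  expect_identical(sum(ev > 1e-10 * ev[1]), 1L)
  cosine <- abs(sum(eigenvectors(em)[, 1] * as.numeric(t(d3))))
  expect_gt(cosine, 0.999)
  # variance conservation: trace identity
  X <- gnmswitch:::.trajMatrix(trajectory(frames), superpose = FALSE)
  D <- sweep(X, 2, colMeans(X))
  expect_equal(sum(ev), mean(rowSums(D^2)), tolerance = 1e-8)
})

test_that("essential correlations reproduce covariance correlations", {
  pair <- wellSeparatedPair(4)
  ts <- makeTwoStateTrajectory(pair$a, pair$b, nFrames = 12,
                               noiseSigma = 0.4, seed = 13)
  em <- suppressWarnings(essentialModes(ts$trajectory, 999))
  full <- essentialCorrelations(em, em@nModesKept)
  oracle <- covarianceCorrelationOracle(
    gnmswitch:::.trajMatrix(ts$trajectory))
  expect_lt(max(abs(normalizedMap(full) - oracle)), 1e-8)
  expect_identical(diag(normalizedMap(full)), rep(1, nResidues(pair$a)))
})

test_that("rigid blocks moving oppositely are perfectly anticorrelated", {
  st <- makeDumbbell(8, 2, seed = 3)$structure
  n <- nResidues(st)
  dirA <- c(1, 0, 0)
  block <- rep(c(1, -1), c(9, 9))   # domain1+linker1 vs rest
  frames <- lapply(1:30, function(t) {
    f <- st
    f@coords <- coords(st) + outer(block, dirA) * 1.5 * sin(t / 2)
    f@modelId <- t; f
  })
  em <- suppressWarnings(essentialModes(trajectory(frames), 1,
                                        superpose = FALSE))
  ec <- essentialCorrelations(em, 1)
  inter <- normalizedMap(ec)[block == 1, block == -1]
  expect_equal(unname(inter), matrix(-1, 9, 9), tolerance = 1e-9)
  # uniform translation without alignment: everything fully correlated
  framesT <- lapply(1:30, function(t) {
    f <- st; f@coords <- coords(st) + sin(t / 2); f@modelId <- t; f
  })
  emT <- suppressWarnings(essentialModes(trajectory(framesT), 1,
                                         superpose = FALSE))
  expect_equal(normalizedMap(essentialCorrelations(emT, 1)),
               matrix(1, n, n), tolerance = 1e-9)
})

test_that("trajectory MSF matches its statistical expectation", {
  # N large enough that the rigid-body share removed by superposition
  # (about 6 of 3N coordinate variances) stays inside the tolerance
  st <- makeChain(100, seed = 14)
  sigma <- 0.5
  ens <- perturbEnsemble(st, sigma, 2000, seed = 15)
  msf <- msfFromTrajectory(trajectory(members(ens)))
  # i.i.d. noise: per-residue MSF ~ 3 sigma^2 (superposition removes a
  # small rigid-body share)
  expect_lt(abs(mean(profileValues(msf)) - 3 * sigma^2), 0.05 * 3 * sigma^2)
  # constant trajectory: exact zeros
  const <- trajectory(rep(list(st), 3))
  expect_equal(profileValues(msfFromTrajectory(const)), rep(0, 100),
               tolerance = 1e-12)
  # MSF sums to the covariance trace
  X <- gnmswitch:::.trajMatrix(trajectory(members(ens)))
  D <- sweep(X, 2, colMeans(X))
  expect_equal(sum(profileValues(msf)), mean(rowSums(D^2)),
               tolerance = 1e-8)
})

test_that("equilibration frames are discarded", {
  pair <- wellSeparatedPair(2)
  junk <- lapply(1:5, function(t) {
    f <- pair$b; f@coords <- coords(pair$b) * 2; f@modelId <- t; f
  })
  ts <- makeTwoStateTrajectory(pair$a, pair$b, nFrames = 10,
                               noiseSigma = 0.2, seed = 3)
  traj <- trajectory(c(junk, ts$trajectory@frames), equilibration = 5L)
  expect_identical(length(rmsdSeries(traj)), 20L)
  cl <- radiusCluster(traj, 3.5)
  expect_identical(sum(clusterPopulations(cl)), 20L)
  expect_identical(cl@frameOffset, 5L)
})
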