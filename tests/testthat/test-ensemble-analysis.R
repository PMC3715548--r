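test_that("ensemble map of identical members equals the single map", {
  st <- makeDumbbell(10, 3, seed = 4)$structure
  single <- crossCorrelations(gnmDecompose(buildKirchhoff(st, 10)),
                              modeRange(1, 10))
  # 4 members: the elementwise mean of identical terms is bit-exact
  ens <- structureEnsemble(rep(list(st), 4))
  avg <- ensembleCorrelationMap(ens, 10, modeRange(1, 10))
  expect_identical(normalizedMap(avg), normalizedMap(single))
  expect_identical(rawMap(avg), rawMap(single))
  expect_match(avg@label, "4 member")
})

test_that("small perturbations leave the averaged map close to the original", {
  db <- makeDumbbell(25, 3, seed = 8)$structure
  n <- nResidues(db)
  ens <- perturbEnsemble(db, sigma = 0.3, nModels = 10, seed = 21)
  # full-spectrum maps: elementwise stability
  baseFull <- crossCorrelations(gnmDecompose(buildKirchhoff(db, 10)),
                                modeRange(1, n - 1))
  avgFull <- ensembleCorrelationMap(ens, 10, modeRange(1, n - 1))
  expect_lt(max(abs(normalizedMap(avgFull) - normalizedMap(baseFull))), 0.05)
  # slow-mode maps rotate their subspace slightly under perturbation:
  # stable on average, not elementwise
  base10 <- crossCorrelations(gnmDecompose(buildKirchhoff(db, 10)),
                              modeRange(1, 10))
  avg10 <- ensembleCorrelationMap(ens, 10, modeRange(1, 10))
  expect_lt(mean(abs(normalizedMap(avg10) - normalizedMap(base10))), 0.03)
})

test_that("a disconnected member is reported by index", {
  st <- makeDumbbell(8, 2, seed = 1)$structure
  broken <- st
  broken@coords[1:8, ] <- broken@coords[1:8, ] + 300
  ens <- structureEnsemble(list(st, broken, st))
  expect_error(ensembleCorrelationMap(ens, 10), "member 2")
})

test_that("region profiles average map rows", {
  mapK3 <- crossCorrelations(gnmDecompose(buildKirchhoff(triangleK3(), 10)),
                             modeRange(1, 2))
  p <- regionProfile(mapK3, regionSpec("r1", "A", 1, 1))
  expect_equal(profileValues(p), c(1, -0.5, -0.5), tolerance = 1e-12)
  # single-residue region = the matching row of the normalized map
  st <- makeChain(25, seed = 3)
  map <- crossCorrelations(gnmDecompose(buildKirchhoff(st, 10)),
                           modeRange(1, 10))
  p7 <- regionProfile(map, regionSpec("r7", "A", 7, 7))
  expect_equal(profileValues(p7), normalizedMap(map)[7, ])
  # multi-residue region = mean of rows; bounded
  pr <- regionProfile(map, regionSpec("seg", "A", 5, 9))
  expect_equal(profileValues(pr), colMeans(normalizedMap(map)[5:9, ]))
  expect_lte(max(abs(profileValues(pr))), 1)
  expect_error(regionProfile(map, regionSpec("none", "B", 1, 5)), "matches no")
})

test_that("difference maps are antisymmetric and zero on identity", {
  sw <- makeSwitchDimer("on", seed = 5)
  map <- crossCorrelations(gnmDecompose(buildKirchhoff(sw$structure, 10)),
                           modeRange(1, 10))
  self <- differenceCorrelationMap(map, map)
  expect_identical(self@values, self@values * 0)
  other <- crossCorrelations(gnmDecompose(buildKirchhoff(
    makeSwitchDimer("off", seed = 5)$structure, 10)), modeRange(1, 10))
  ab <- differenceCorrelationMap(map, other, labels = c("on", "off"))
  ba <- differenceCorrelationMap(other, map, labels = c("off", "on"))
  expect_identical(ab@values, -ba@values)
  expect_lte(max(abs(ab@values)), 2)
})

test_that("difference maps align on residue keys, not on positions", {
  # maps over overlapping but unequal residue sets
  stA <- makeChain(20, seed = 2)
  stB <- calphaStructure(coords(stA)[5:20, ], chain = "A", resno = 5:20)
  mapA <- crossCorrelations(gnmDecompose(buildKirchhoff(stA, 10)),
                            modeRange(1, 10))
  mapB <- crossCorrelations(gnmDecompose(buildKirchhoff(stB, 10)),
                            modeRange(1, 10))
  d <- differenceCorrelationMap(mapA, mapB)
  expect_identical(residues(d)$resno, 5:20)
  expect_equal(d@values,
               normalizedMap(mapA)[5:20, 5:20] - normalizedMap(mapB))
  # profiles difference on the intersection, and antisymmetry
  msfA <- meanSquareFluctuations(gnmDecompose(buildKirchhoff(stA, 10)),
                                 modeRange(1, 10))
  msfB <- meanSquareFluctuations(gnmDecompose(buildKirchhoff(stB, 10)),
                                 modeRange(1, 10))
  dm <- differenceMsf(msfA, msfB)
  expect_identical(length(dm), 16L)
  expect_equal(dm, -differenceMsf(msfB, msfA))
  expect_equal(unname(differenceMsf(msfA, msfA)), rep(0, 20))
})

test_that("averaging over maps and regions commutes", {
  db <- makeDumbbell(10, 3, seed = 9)$structure
  ens <- perturbEnsemble(db, 0.3, 5, seed = 10)
  region <- regionSpec("hinge", "A", 11, 13)
  avgMap <- ensembleCorrelationMap(ens, 10, modeRange(1, 10))
  profileOfAverage <- profileValues(regionProfile(avgMap, region))
  perMember <- sapply(members(ens), function(m)
    profileValues(regionProfile(crossCorrelations(gnmDecompose(
      buildKirchhoff(m, 10)), modeRange(1, 10)), region)))
  expect_equal(profileOfAverage, rowMeans(perMember), tolerance = 1e-12)
})

test_that("switch scores separate the on and off coupling geometries", {
  for (seed in c(2, 6)) {
    for (state in c("on", "off")) {
      sw <- makeSwitchDimer(state, seed = seed)
      map <- crossCorrelations(gnmDecompose(buildKirchhoff(sw$structure, 10)),
                               modeRange(1, 10))
      rep <- switchScore(map, sw$regions$hinge, sw$regions$campSite,
                         sw$regions$dnaSite, sw$regions$dnaDomain)
      expect_identical(unname(stateLabels(rep)), rep(state, 2))
      expect_lte(max(abs(couplings(rep)$value)), 1)
      # C2 symmetry: the two subunits report identical couplings
      cp <- couplings(rep)
      expect_equal(cp$value[cp$subunit == "A"], cp$value[cp$subunit == "B"],
                   tolerance = 1e-8)
    }
  }
})

test_that("switch scoring validates its regions", {
  sw <- makeSwitchDimer("on", seed = 2)
  map <- crossCorrelations(gnmDecompose(buildKirchhoff(sw$structure, 10)),
                           modeRange(1, 10))
  bad <- list(regionSpec("hinge", "Q", 1, 4), sw$regions$hinge[[2]])
  expect_error(switchScore(map, bad, sw$regions$campSite,
                           sw$regions$dnaSite, sw$regions$dnaDomain),
               "matches no")
})
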