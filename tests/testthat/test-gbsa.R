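test_that("an isolated atom's effective Born radius equals its reduced intrinsic radius", {
  sys <- makeIonPair(rborn = c(1.59, 1.8))
  gp <- gbParams()
  expect_equal(effectiveBornRadii(sys, params = gp, subset = 1L), 1.5)
  expect_equal(effectiveBornRadii(sys, params = gp, subset = 2L), 1.71)
})

test_that("pairwise descreening matches an independent numeric integration", {
  gp <- gbParams()
  for (d in c(1.2, 2.0, 3.5, 6.0)) {
    sys <- makeIonPair(r = d, rborn = c(1.59, 1.8), screen = c(0.8, 0.9))
    R <- effectiveBornRadii(sys, params = gp)
    I1 <- numericDescreenI(1.59 - gp$offset, d, 0.9 * (1.8 - gp$offset))
    I2 <- numericDescreenI(1.8 - gp$offset, d, 0.8 * (1.59 - gp$offset))
    expect_equal(R[1], obcRadiusFromI(I1, 1.59, gp), tolerance = 1e-8)
    expect_equal(R[2], obcRadiusFromI(I2, 1.8, gp), tolerance = 1e-8)
  }
})

test_that("burial monotonically increases the effective radius", {
  # an atom caged by neighbours on an octahedron, tightening
  cage <- function(d) {
    xyz <- rbind(c(0, 0, 0),
                 d * rbind(diag(3), -diag(3)))
    s <- ChaperoneDynamics:::.buildStructure(rep("A", 7), rep(1, 7), "CAG",
                                             paste0("X", 1:7), xyz)
    loadParameters(s, ChaperoneDynamics:::.paramTable(s, 0, 3, 0.1, 1.5, 0.8))
  }
  gp <- gbParams()
  R <- vapply(c(8, 5, 3.2), function(d)
    effectiveBornRadii(cage(d), params = gp)[1], numeric(1))
  expect_true(all(diff(R) > 0))
  expect_gt(R[3], 1.5 - gp$offset)
})

test_that("GB energy recovers the Born ion limit and the two-ion double sum", {
  gp <- gbParams()
  sys <- makeIonPair(q = c(1, 0), rborn = 1.59)
  born <- gbEnergy(sys, params = gp, subset = 1L)
  closed <- -KE / 2 * (1 - 1 / 78.5) / 1.5
  expect_lt(abs(born / closed - 1), 1e-6)
  # zero charges: exactly zero
  expect_equal(gbEnergy(makeIonPair(q = c(0, 0)), params = gp), 0)
  # two-ion hand evaluation of the f_GB double sum
  sys2 <- makeIonPair(r = 3.0)
  R <- effectiveBornRadii(sys2, params = gp)
  f12 <- sqrt(9 + R[1] * R[2] * exp(-9 / (4 * R[1] * R[2])))
  hand <- -KE / 2 * (1 - 1 / 78.5) * (1 / R[1] + 1 / R[2] - 2 / f12)
  expect_lt(abs(gbEnergy(sys2, radii = R, params = gp) - hand), 1e-8)
  # non-positive for any charged system
  expect_lt(gbEnergy(makeIonPair(r = 5, q = c(0.4, 0.4)), params = gp), 0)
})

test_that("GB energy is invariant under rigid-body motion of the frame", {
  toy <- makeToyComplex()
  x <- structureCoords(toy$structure)
  e1 <- gbEnergy(toy$system, x)
  e2 <- gbEnergy(toy$system, rigidTransform(x))
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("Shrake-Rupley areas match analytic sphere results", {
  # isolated sphere within the 960-point sampling tolerance (1%)
  a <- shrakeRupley(matrix(0, 1, 3), 1.7)
  expect_lt(abs(a / (4 * pi * 3.1^2) - 1), 0.01)
  # fully enclosed atom has zero accessible area
  shell <- rbind(c(0, 0, 0), 2.0 * rbind(diag(3), -diag(3)),
                 1.2 * as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))))
  areas <- shrakeRupley(shell, c(0.8, rep(2.5, 14)))
  expect_equal(areas[1], 0)
  # two identical overlapping spheres vs the closed-form accessible area
  d <- 2.5
  two <- shrakeRupley(rbind(c(0, 0, 0), c(d, 0, 0)), 1.7)
  expect_lt(abs(sum(two) / twoSphereAccessibleArea(3.1, d) - 1), 0.01)
  # sampling converges monotonically toward the analytic sphere area
  errs <- vapply(c(60, 240, 960, 3840), function(n)
    abs(shrakeRupley(matrix(0, 1, 3), 1.7, nPoints = n) - 4 * pi * 3.1^2),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("MM-GBSA of non-interacting neutral partners is exactly zero", {
  # two far-apart atoms, no charge, no LJ well: nothing binds
  sys <- makeIonPair(r = 60, q = c(0, 0), epsilon = 0)
  rep <- mmgbsaBinding(sys, structureCoords(sys@structure), 1L, 2L)
  expect_equal(rep@perFrame$total, 0, tolerance = 1e-9)
  expect_equal(rep@perFrame$enp, 0, tolerance = 1e-9)
})

test_that("two-ion MM-GBSA matches a hand-assembled thermodynamic cycle", {
  gp <- gbParams()
  sys <- makeIonPair(r = 3.0)
  x <- structureCoords(sys@structure)
  rep <- mmgbsaBinding(sys, x, 1L, 2L, params = gp)
  pf <- rep@perFrame
  expect_equal(pf$ecoul, -KE / 3.0, tolerance = 1e-9)
  gbC <- gbEnergy(sys, x, params = gp)
  gbR <- gbEnergy(sys, x, params = gp, subset = 1L)
  gbL <- gbEnergy(sys, x, params = gp, subset = 2L)
  expect_equal(pf$egb, gbC - gbR - gbL, tolerance = 1e-9)
  radii <- ChaperoneDynamics:::.sasaRadiiDefault(sys, 1:2)
  dA <- sum(shrakeRupley(x, radii)) -
    sum(shrakeRupley(x[1, , drop = FALSE], radii[1])) -
    sum(shrakeRupley(x[2, , drop = FALSE], radii[2]))
  expect_equal(pf$enp, gp$gammaNP * dA, tolerance = 1e-9)
  expect_equal(pf$total, pf$evdw + pf$ecoul + pf$egb + pf$enp)
  # desolvation opposes the coulombic attraction
  expect_gt(pf$egb, 0)
  expect_error(mmgbsaBinding(sys, x, 1:2, 2L), "overlap")
})

test_that("per-residue decomposition conserves the total and splits symmetrically", {
  gp <- gbParams()
  # symmetric two-ion system: equal split by symmetry
  sys <- makeIonPair(r = 3.0, q = c(1, -1))
  dec <- perResidueGBSA(sys, structureCoords(sys@structure), 1L, 2L, params = gp)
  # the nonpolar term uses a discrete point set that is not exactly
  # mirror-symmetric, so the split is equal to sampling precision
  expect_equal(dec$total[1], dec$total[2], tolerance = 0.01)
  expect_equal(dec$ecoul[1], dec$ecoul[2], tolerance = 1e-9)
  expect_equal(sum(dec$total), attr(dec, "frameTotals")[1], tolerance = 1e-6)
  # toy complex: residue sums reproduce the per-frame totals
  toy <- makeToyComplex(nChains = 2, residuesPerChain = 4)
  tr <- makeGaussianTrajectory(toy$structure, noise = 0.03, nFrames = 2, seed = 3)
  dec2 <- perResidueGBSA(toy$system, tr, toy$receptorSel, toy$ligandSel,
                         params = gp)
  rep2 <- mmgbsaBinding(toy$system, tr, toy$receptorSel, toy$ligandSel,
                        params = gp)
  expect_equal(sum(dec2$total), mean(attr(dec2, "frameTotals")), tolerance = 1e-6)
  expect_equal(mean(attr(dec2, "frameTotals")),
               rep2@summary$mean[rep2@summary$component == "total"],
               tolerance = 1e-9)
  # zero charges: polar contributions vanish
  toyZ <- makeToyComplex(chargePattern = "zero")
  decZ <- perResidueGBSA(toyZ$system, structureCoords(toyZ$structure),
                         toyZ$receptorSel, toyZ$ligandSel, params = gp)
  expect_equal(decZ$ecoul, rep(0, nrow(decZ)))
  expect_equal(decZ$egb, rep(0, nrow(decZ)), tolerance = 1e-12)
})

test_that("binding reports carry per-replica and cross-replica statistics", {
  toy <- makeToyComplex()
  tr <- makeGaussianTrajectory(toy$structure, noise = 0.05, nFrames = 2,
                               nReplicas = 3, seed = 4)
  rep <- mmgbsaBinding(toy$system, tr, toy$receptorSel, toy$ligandSel)
  s <- rep@summary
  tot <- s[s$component == "total", ]
  ms <- rep@replicaStats
  repMeans <- ms$mean[ms$component == "total"]
  expect_equal(tot$mean, mean(repMeans))
  expect_equal(tot$sd, sd(repMeans))
  expect_equal(tot$sem, sd(repMeans) / sqrt(3))
})
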