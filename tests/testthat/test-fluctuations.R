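toySmall <- function() cachedScene("toy1x5", function()
  makeToyComplex(nChains = 1, residuesPerChain = 5))

test_that("frames differing only by rigid motion collapse after fitting", {
  toy <- toySmall()
  x <- structureCoords(toy$structure)
  frames <- rbind(as.vector(t(x)),
                  as.vector(t(rigidTransform(x, angle = 0.9))),
                  as.vector(t(rigidTransform(x, angle = 2.1,
                                             axis = c(1, 1, 0),
                                             shift = c(-3, 2, 8)))))
  tr <- new("Trajectory", xyz = frames, template = toy$structure,
            replica = rep(1L, 3), time = rep(NA_real_, 3))
  fit <- fitFrames(tr)
  spread <- apply(fit@xyz, 2, function(col) max(col) - min(col))
  expect_lt(max(spread), 1e-9)
  # single-frame trajectory: identity transform
  tr1 <- new("Trajectory", xyz = frames[1, , drop = FALSE],
             template = toy$structure, replica = 1L, time = NA_real_)
  expect_equal(fitFrames(tr1)@xyz, frames[1, , drop = FALSE],
               tolerance = 1e-12)
  # degenerate fits are rejected
  expect_error(fitFrames(tr, fitSelection = 1:2), "3 fit atoms")
})

test_that("iterative-mean fitting converges quickly on a Gaussian trajectory", {
  toy <- toySmall()
  tr <- makeGaussianTrajectory(toy$structure, noise = 0.3, nFrames = 200,
                               seed = 11)
  fit <- fitFrames(tr)
  expect_lte(attr(fit, "iterations"), 5)
})

test_that("a static trajectory has zero RMSF and zero B-factor", {
  toy <- toySmall()
  x <- as.vector(t(structureCoords(toy$structure)))
  tr <- new("Trajectory", xyz = rbind(x, x, x), template = toy$structure,
            replica = rep(1L, 3), time = rep(NA_real_, 3))
  prof <- rmsf(tr)
  expect_equal(prof$rmsf, rep(0, natoms(tr)))
  expect_equal(prof$bRaw, rep(0, natoms(tr)))
  expect_error(rmsf(new("Trajectory", xyz = rbind(x), template = toy$structure,
                        replica = 1L, time = NA_real_)), "2 frames")
})

test_that("isotropic Gaussian displacement recovers sigma*sqrt(3) and B = 8 pi^2 sigma^2", {
  toy <- toySmall()
  tr <- makeGaussianTrajectory(toy$structure, noise = 0.5, nFrames = 10000,
                               seed = 7)
  prof <- rmsf(tr)   # isotropic noise: no fitting required for the check
  expect_equal(mean(prof$rmsf), 0.5 * sqrt(3), tolerance = 0.02)
  expect_equal(mean(prof$bRaw), 8 * pi^2 * 0.25, tolerance = 0.04)
  # exact conversion law atom by atom
  expect_equal(prof$bRaw, (8 * pi^2 / 3) * prof$rmsf^2, tolerance = 1e-12)
  # doubling sigma quadruples B
  tr2 <- makeGaussianTrajectory(toy$structure, noise = 1.0, nFrames = 10000,
                                seed = 7)
  expect_equal(mean(rmsf(tr2)$bRaw) / mean(prof$bRaw), 4, tolerance = 0.05)
})

test_that("RMSF is invariant under a rigid motion applied before fitting", {
  toy <- toySmall()
  tr <- makeGaussianTrajectory(toy$structure, noise = 0.4, nFrames = 300,
                               seed = 13)
  prof1 <- rmsf(fitFrames(tr))
  moved <- tr
  moved@xyz <- t(apply(tr@xyz, 1, function(row)
    as.vector(t(rigidTransform(matrix(row, ncol = 3, byrow = TRUE))))))
  prof2 <- rmsf(fitFrames(moved))
  expect_equal(prof1$rmsf, prof2$rmsf, tolerance = 1e-6)
})

test_that("joint B-factor normalization shares one scale and preserves order", {
  p1 <- data.frame(atom = 1:3, rmsf = c(1, 2, 3))
  p1$bRaw <- c(2, 5, 10)
  p2 <- data.frame(atom = 1:3, rmsf = c(1, 2, 3))
  p2$bRaw <- c(8, 20, 40)
  out <- normalizeBFactors(list(p1, p2))
  expect_equal(max(out[[2]]$bNorm), 100)
  expect_equal(max(out[[1]]$bNorm), 25)
  # within-profile ratios preserved exactly
  expect_equal(out[[1]]$bNorm / out[[1]]$bNorm[1], p1$bRaw / p1$bRaw[1])
  expect_identical(order(out[[1]]$bNorm), order(p1$bRaw))
  # single profile: its own max becomes 100
  single <- normalizeBFactors(p1)
  expect_equal(max(single$bNorm), 100)
  # all-zero pooled maximum maps to all zeros
  pz <- p1; pz$bRaw <- c(0, 0, 0)
  expect_equal(normalizeBFactors(pz)$bNorm, c(0, 0, 0))
})

test_that("PCA recovers a planted internal mode and variance ratios", {
  toy <- toySmall()
  s <- toy$structure
  n <- natoms(s)
  d <- makePlantedModes(s, nModes = 2, seed = 11)
  tr <- makeGaussianTrajectory(s, modes = d[, 1, drop = FALSE], sigmas = 1,
                               noise = 0.05, nFrames = 5000, seed = 3)
  ms <- trajectoryPCA(fitFrames(tr), selection = seq_len(n), nModes = 3)
  expect_gte(abs(sum(modeVectors(ms)[, 1] * d[, 1])), 0.99)
  # two orthogonal planted modes with 4:1 variance
  tr2 <- makeGaussianTrajectory(s, modes = d, sigmas = c(2, 1), noise = 0.02,
                                nFrames = 5000, seed = 5)
  ms2 <- trajectoryPCA(fitFrames(tr2), selection = seq_len(n), nModes = 4)
  expect_equal(modeValues(ms2)[1] / modeValues(ms2)[2], 4, tolerance = 0.1 * 4)
})

test_that("PCA bookkeeping: zero variance, Parseval identity, rank truncation", {
  toy <- toySmall()
  x <- as.vector(t(structureCoords(toy$structure)))
  static <- new("Trajectory", xyz = rbind(x, x, x), template = toy$structure,
                replica = rep(1L, 3), time = rep(NA_real_, 3))
  msz <- suppressWarnings(
    trajectoryPCA(static, selection = seq_len(natoms(toy$structure))))
  expect_equal(modeValues(msz), rep(0, length(modeValues(msz))))
  tr <- makeGaussianTrajectory(toy$structure, noise = 0.2, nFrames = 50,
                               seed = 19)
  fit <- fitFrames(tr)
  ms <- suppressWarnings(
    trajectoryPCA(fit, selection = seq_len(natoms(toy$structure))))
  totalVar <- sum(apply(fit@xyz, 2, function(c) mean((c - mean(c))^2)))
  expect_lt(abs(sum(modeValues(ms)) - totalVar), 1e-8)
  expect_equal(sum(varianceFractions(ms)), 1)
  # eigenvectors orthonormal
  V <- modeVectors(ms)
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  # more modes than rank: truncated with a warning
  short <- new("Trajectory", xyz = tr@xyz[1:3, ], template = toy$structure,
               replica = rep(1L, 3), time = rep(NA_real_, 3))
  expect_warning(trajectoryPCA(short, selection = seq_len(natoms(toy$structure)),
                               nModes = 10), "rank")
})

test_that("mode animation export is self-consistent and respects its arguments", {
  toy <- toySmall()
  d <- makePlantedModes(toy$structure, nModes = 1, seed = 23)
  tr <- makeGaussianTrajectory(toy$structure, modes = d, sigmas = 1.5,
                               noise = 0.05, nFrames = 2000, seed = 29)
  ms <- trajectoryPCA(fitFrames(tr), selection = seq_len(natoms(toy$structure)),
                      nModes = 2)
  f <- tempfile(fileext = ".pdb")
  anim <- exportModeTrajectory(ms, toy$structure, f, k = 1, nSteps = 11,
                               amplitude = 2)
  expect_equal(nframes(anim), 11)
  # the animation's own PCA recovers the exported mode as PC1
  ms2 <- trajectoryPCA(anim, selection = seq_len(natoms(anim)), nModes = 1)
  expect_gte(abs(sum(modeVectors(ms2)[, 1] * modeVectors(ms)[, 1])), 0.999)
  # amplitude zero: every frame equals the mean structure
  flat <- exportModeTrajectory(ms, toy$structure, f, k = 1, nSteps = 3,
                               amplitude = 0)
  expect_lt(max(abs(sweep(flat@xyz, 2, ms@center))), 1e-12)
  # nSteps = 2 gives exactly the two extremes
  ext <- exportModeTrajectory(ms, toy$structure, f, k = 1, nSteps = 2,
                              amplitude = 1)
  expect_equal(ext@xyz[1, ], ms@center - sqrt(modeValues(ms)[1]) * modeVectors(ms)[, 1])
  expect_equal(ext@xyz[2, ], ms@center + sqrt(modeValues(ms)[1]) * modeVectors(ms)[, 1])
})
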