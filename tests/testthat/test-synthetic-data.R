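test_that("ground truth draws are standard normal and normalize exactly", {
  gt <- drawGroundTruth(10000, seed = 4)
  expect_equal(mean(abs(contrastVector(gt))), 1, tolerance = 1e-12)
  # normalization rescales both condition amplitudes by the same factor
  expect_equal(conditionMeans(gt)[, 1] - conditionMeans(gt)[, 2],
               contrastVector(gt), tolerance = 1e-12)
  raw <- drawGroundTruth(10000, seed = 4, normalize = FALSE)
  expect_equal(sd(conditionMeans(raw)[, 1]), 1, tolerance = 0.05)
  expect_error(drawGroundTruth(0), "nVoxels")
})

test_that("zero noise reproduces the noiseless design-by-means signal", {
  d <- makeBlockDesign()
  gt <- drawGroundTruth(25, seed = 2)
  y <- simulateParticipant(d, gt,
                           noiseSpec(attentionSd = 0, thermalSd = 0,
                                     physScale = 0), seed = 9)
  for (k in 1:4)
    expect_equal(y[[k]], subrunDesign(d, k) %*% t(conditionMeans(gt)),
                 tolerance = 1e-12)
})

test_that("thermal noise has the specified per-timepoint SD", {
  d <- makeBlockDesign()
  gt <- drawGroundTruth(80, seed = 3)
  ns <- noiseSpec(attentionSd = 0, thermalSd = 1.8, physScale = 0)
  y <- simulateParticipant(d, gt, ns, seed = 21)
  resid <- unlist(lapply(1:4, function(k)
    y[[k]] - subrunDesign(d, k) %*% t(conditionMeans(gt))))
  expect_equal(sd(resid), 1.8, tolerance = 0.02)
  expect_equal(mean(resid), 0, tolerance = 0.02)
})

test_that("attention noise is block-constant and boxcar-modulated", {
  d <- makeBlockDesign()
  gt <- zeroTruth(10)
  y <- simulateParticipant(d, gt,
                           noiseSpec(attentionSd = 1, thermalSd = 0,
                                     physScale = 0), seed = 5)
  bl <- blockTable(d)
  b1 <- bl[bl$subrun == 1, ]
  seg <- y[[1]][b1$start[1]:b1$end[1], ]
  # constant within a block, per voxel
  expect_true(all(apply(seg, 2, function(v) diff(range(v)) == 0)))
  # different across blocks and voxels
  amps <- t(sapply(seq_len(nrow(b1)), function(b) y[[1]][b1$start[b], ]))
  expect_gt(sd(amps), 0.5)
})

test_that("physiological projection is participant-stable but its timecourses are independent across subruns", {
  # long subruns so the spatial covariance estimate is stable
  d <- makeBlockDesign(16, 16, 2, 1, 0)
  V <- 12
  ns <- noiseSpec(attentionSd = 0, thermalSd = 0, physScale = 1)
  y <- simulateParticipant(d, zeroTruth(V), ns, seed = 31)
  # raw timecourses across subruns are uncorrelated
  cc <- vapply(seq_len(V), function(v) cor(y[[1]][, v], y[[2]][, v]),
               numeric(1))
  expect_lt(mean(abs(cc)), 0.15)
  # but both subruns share the projection weights, so their voxel-space
  # covariances estimate the same W'W
  off <- upper.tri(diag(V))
  expect_gt(cor(cov(y[[1]])[off], cov(y[[2]])[off]), 0.6)
})

test_that("physiological noise adds voxel-correlated noise growing with physScale", {
  d <- makeBlockDesign()
  V <- 30
  meanAbsOff <- vapply(c(0.5, 1, 2), function(ps) {
    y <- simulateParticipant(d, zeroTruth(V),
                             noiseSpec(attentionSd = 0, thermalSd = 1.8,
                                       physScale = ps), seed = 77)
    C <- cor(do.call(rbind, y))
    mean(abs(C[upper.tri(C)]))
  }, numeric(1))
  expect_true(all(diff(meanAbsOff) > 0))
})

test_that("datasets regenerate bit-identically from the same seed", {
  d <- makeBlockDesign()
  a <- simulateDataset(d, noiseSpec(), nParticipants = 2, nVoxels = 15,
                       seed = 123)
  b <- simulateDataset(d, noiseSpec(), nParticipants = 2, nVoxels = 15,
                       seed = 123)
  expect_identical(a@data, b@data)
  expect_identical(contrastVector(groundTruth(a, 1)),
                   contrastVector(groundTruth(b, 1)))
  # a different noise-seed offset changes the noise but not the truths
  c <- simulateDataset(d, noiseSpec(), nParticipants = 2, nVoxels = 15,
                       seed = 123, noiseSeedOffset = 1L)
  expect_identical(contrastVector(groundTruth(a, 1)),
                   contrastVector(groundTruth(c, 1)))
  expect_false(identical(a@data, c@data))
})

test_that("participants differ from each other within a dataset", {
  d <- makeBlockDesign()
  ds <- simulateDataset(d, noiseSpec(), nParticipants = 3, nVoxels = 10,
                        seed = 8)
  expect_false(identical(participantData(ds, 1), participantData(ds, 2)))
  expect_false(identical(contrastVector(groundTruth(ds, 1)),
                         contrastVector(groundTruth(ds, 2))))
})
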