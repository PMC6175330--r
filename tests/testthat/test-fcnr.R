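# exact-arithmetic fixture: residuals orthogonal to the design with
# df-corrected SD scaled to exactly `sdn`
orthoResiduals <- function(B, nvox, df, sdn = 1, seed = 1) {
  set.seed(seed)
  E <- qr.resid(qr(B), matrix(rnorm(nrow(B) * nvox), nrow(B), nvox))
  sweep(E, 2, sqrt(colSums(E^2) / df) / sdn, "/")
}

test_that("stimulus fCNR equals |beta| x peak / residual SD", {
  on <- rep(rep(c(0, 1), each = 8), 4)
  e <- orthoResiduals(matrix(on, ncol = 1), 2, df = length(on) - 1)
  y <- cbind(2 * on + e[, 1], -2 * on + e[, 2])
  r <- computeFcnrStimulus(y, on, drift = FALSE)
  expect_equal(r@perVoxel, c(2, 2), tolerance = 1e-10)  # sign-symmetric
  expect_equal(r@meanOverRoi, 2, tolerance = 1e-10)
  expect_equal(r@nUndefined, 0L)
})

test_that("zero-residual voxels are flagged undefined, not dropped silently", {
  on <- rep(rep(c(0, 1), each = 4), 4)
  y <- cbind(2 * on, 2 * on + rnorm(length(on)))
  r <- computeFcnrStimulus(y, on, drift = FALSE)
  expect_true(is.na(r@perVoxel[1]))
  expect_equal(r@nUndefined, 1L)
  expect_true(is.finite(r@meanOverRoi))
})

test_that("simulation fCNR under the residual definition matches direct substitution", {
  d <- makeBlockDesign()
  V <- 6
  A <- cbind(rep(1.8, V), rep(0, V))     # contrast exactly 1.8 per voxel
  gt <- fixedTruth(A[, 1], A[, 2])
  Tn <- 64; t <- seq_len(Tn)
  df <- Tn - 5                            # 2 condition + 3 drift regressors
  y <- lapply(1:4, function(k) {
    X <- subrunDesign(d, k)
    B <- cbind(X, 1, t - mean(t), sin(2 * pi * t / Tn), cos(2 * pi * t / Tn))
    X %*% t(A) + orthoResiduals(B, V, df = df, seed = k)
  })
  r <- computeSimFcnr(y, d, noise = "residual")
  expect_equal(r@perVoxel, rep(1.8, V), tolerance = 1e-8)
  expect_equal(r@meanOverRoi, 1.8, tolerance = 1e-8)
})

test_that("simulation fCNR is invariant to a common positive rescaling", {
  d <- makeBlockDesign()
  y <- simulateParticipant(d, drawGroundTruth(20, seed = 2),
                           noiseSpec(physScale = 1), seed = 3)
  for (noise in c("contrast_se", "residual")) {
    a <- computeSimFcnr(y, d, noise = noise)
    b <- computeSimFcnr(lapply(y, function(m) 3 * m), d, noise = noise)
    expect_equal(a@perVoxel, b@perVoxel, tolerance = 1e-10)
  }
})

test_that("zero-noise data trip the undefined-fCNR guard", {
  d <- makeBlockDesign()
  y <- simulateParticipant(d, drawGroundTruth(5, seed = 1),
                           noiseSpec(0, 0, physScale = 0), seed = 1)
  expect_error(computeSimFcnr(y, d), "undefined")
})

test_that("measured fCNR decreases monotonically with the physiological scale", {
  d <- makeBlockDesign()
  vals <- vapply(c(0.5, 1, 2), function(ps) {
    ds <- simulateDataset(d, noiseSpec(physScale = ps), nParticipants = 2,
                          nVoxels = 100, seed = 99)
    mean(vapply(1:2, function(p)
      computeSimFcnr(participantData(ds, p), d)@meanOverRoi, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("calibration converges, and unreachable targets report the bound", {
  d <- makeBlockDesign()
  ns <- calibrateNoiseToFcnr(d, noiseSpec(), 2.5, nVoxels = 80,
                             nMeasure = 3, seed = 5)
  expect_equal(attr(ns, "achievedFcnr"), 2.5, tolerance = 0.02 * 2.5)
  expect_gt(physScale(ns), 0)
  expect_error(
    calibrateNoiseToFcnr(d, noiseSpec(), 50, nVoxels = 40, nMeasure = 2,
                         seed = 5),
    "achievable")
  expect_error(
    calibrateNoiseToFcnr(d, noiseSpec(attentionSd = 0, thermalSd = 0), 1),
    "zero")
})
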