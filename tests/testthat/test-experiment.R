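quickConfig <- function(...) {
  experimentConfig(nDatasets = 5, nParticipants = 5, nVoxels = 40,
                   seed = 17, ...)
}

test_that("cohorts are bit-identical under a repeated seed", {
  cfg <- quickConfig()
  a <- runCohort(cfg, physScale = 1.2, seed = 100)
  b <- runCohort(cfg, physScale = 1.2, seed = 100)
  expect_identical(a, b)
  expect_named(a, c("participant", "ldcNormalized", "svmAccuracy"))
  c <- runCohort(cfg, physScale = 1.2, seed = 101)
  expect_false(identical(a$ldcNormalized, c$ldcNormalized))
})

test_that("matched cohorts share ground truths but not noise", {
  cfg <- quickConfig()
  a <- runCohort(cfg, physScale = 1.0, seed = 7, methods = "ldc",
                 noiseSeedOffset = 1L)
  b <- runCohort(cfg, physScale = 2.0, seed = 7, truth = attr(a, "truth"),
                 methods = "ldc", noiseSeedOffset = 2L)
  expect_identical(lapply(attr(a, "truth"), contrastVector),
                   lapply(attr(b, "truth"), contrastVector))
  expect_false(identical(a$ldcNormalized, b$ldcNormalized))
})

test_that("null cohorts center the group-mean LDC on zero", {
  cfg <- experimentConfig(nParticipants = 40, nVoxels = 100, seed = 23)
  co <- runCohort(cfg, physScale = 1.5, seed = 1, nullEffect = TRUE,
                  methods = "ldc")
  se <- sd(co$ldcNormalized) / sqrt(nrow(co))
  expect_lt(abs(mean(co$ldcNormalized)), 3 * se)
})

test_that("high-contrast cohorts push SVM accuracy toward ceiling", {
  cfg <- quickConfig()
  co <- runCohort(cfg, physScale = 0.2, seed = 2, methods = "svm")
  expect_gt(mean(co$svmAccuracy), 0.9)
})

test_that("rejectionProbability returns a proportion with its p-values", {
  cfg <- quickConfig()
  r <- rejectionProbability(cfg, 1.0, NULL, method = "ldc", nDatasets = 4)
  expect_true(r >= 0 && r <= 1)
  expect_length(attr(r, "pValues"), 4)
  expect_equal(attr(r, "nDatasets"), 4)
})

test_that("the smallest grid is symmetric, complete and resumable", {
  cfg <- experimentConfig(fcnrLevels = c(1.5, 2.5), nDatasets = 3,
                          nParticipants = 4, nVoxels = 30, seed = 5,
                          methods = "ldc")
  dir <- tempfile("grid")
  g <- buildGrid(cfg, physScales = c(2.0, 0.8), progressDir = dir)
  cells <- rejectionCells(g)
  expect_equal(dim(cells), c(2, 2, 1))
  expect_false(anyNA(cells))
  expect_equal(cells[1, 2, 1], cells[2, 1, 1])
  expect_length(list.files(dir, pattern = "^cell_.*json$"), 3)
  # a second build reuses the persisted cells
  g2 <- buildGrid(cfg, physScales = c(2.0, 0.8), progressDir = dir)
  expect_equal(rejectionCells(g2), cells, tolerance = 1e-9)
})

test_that("rejection grows with the fCNR separation along grid rows", {
  cfg <- experimentConfig(fcnrLevels = c(1.2, 1.8, 2.6), nDatasets = 15,
                          nParticipants = 10, nVoxels = 100, seed = 31,
                          methods = "ldc")
  # physScales chosen by one calibration pass at this voxel count
  ps <- calibrateLevels(cfg, nMeasure = 3)
  g <- rejectionCells(buildGrid(cfg, physScales = ps))[, , 1]
  bySep <- vapply(0:2, function(s)
    mean(g[abs(row(g) - col(g)) == s]), numeric(1))
  # averages over rows: separation 0 (null) < larger separations
  expect_lt(bySep[1], 0.3)
  expect_gt(bySep[3], bySep[1])
  expect_gt(bySep[2] + 0.15, bySep[1])    # allow binomial noise
  expect_gt(bySep[3] + 0.15, bySep[2])
})
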