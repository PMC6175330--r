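test_that("identity whitening gives the closed-form LDC", {
  P <- 3
  # three 20-row training blocks are pooled per fold
  res <- lapply(1:4, function(k)
    identityResiduals(20, P, seed = k, scale = sqrt((3 * 20 - 1) / 3)))
  contrasts <- matrix(rep(c(1, 0, 0), each = 4), 4, P)  # e1 in every subrun
  r <- computeLdc(contrasts, res)
  expect_equal(perFold(r), rep(1, 4), tolerance = 1e-10)
  expect_equal(normalizedLdc(r), 1 / sqrt(P), tolerance = 1e-10)
})

test_that("opposing train and test contrasts give minus the squared norm", {
  cvec <- c(2, -1, 0.5)
  res <- lapply(1:2, function(k) identityResiduals(20, 3, seed = 10 + k))
  r <- computeLdc(rbind(cvec, -cvec), res)
  expect_equal(perFold(r), rep(-sum(cvec^2), 2), tolerance = 1e-10)
})

test_that("computeLdc matches a hand-rolled dense oracle on tiny instances", {
  set.seed(42)
  for (rep in 1:3) {
    contrasts <- matrix(rnorm(2 * 3), 2, 3)
    res <- lapply(1:2, function(k) matrix(rnorm(15 * 3), 15, 3))
    got <- computeLdc(contrasts, res)
    want <- ldcOracle(contrasts, res)
    expect_equal(perFold(got), want$perFold, tolerance = 1e-10)
    expect_equal(normalizedLdc(got), want$normalized, tolerance = 1e-10)
  }
})

test_that("LDC scales quadratically with the contrast magnitude", {
  set.seed(7)
  contrasts <- matrix(rnorm(4 * 6), 4, 6)
  res <- lapply(1:4, function(k) matrix(rnorm(40 * 6), 40, 6))
  r1 <- computeLdc(contrasts, res)
  r2 <- computeLdc(2 * contrasts, res)   # same covariance, doubled contrast
  expect_equal(perFold(r2), 4 * perFold(r1), tolerance = 1e-10)
})

test_that("LDC mean is invariant to subrun order", {
  set.seed(8)
  contrasts <- matrix(rnorm(4 * 5), 4, 5)
  res <- lapply(1:4, function(k) matrix(rnorm(30 * 5), 30, 5))
  perm <- c(3, 1, 4, 2)
  a <- computeLdc(contrasts, res)
  b <- computeLdc(contrasts[perm, ], res[perm])
  expect_equal(a@mean, b@mean, tolerance = 1e-12)
  expect_equal(sort(perFold(a)), sort(perFold(b)), tolerance = 1e-12)
})

test_that("fewer than two subruns is rejected", {
  expect_error(computeLdc(matrix(1, 1, 3),
                          list(matrix(rnorm(30), 10, 3))), "2 subruns")
})

test_that("perfectly separated clouds decode at ceiling with 1/8 granularity", {
  set.seed(1)
  b <- matrix(rnorm(32 * 10, sd = 0.1), 32, 10)
  cond <- rep(rep(1:2, each = 4), 4)
  sub <- rep(1:4, each = 8)
  b[, 1] <- b[, 1] + ifelse(cond == 1, 5, -5)
  r <- svmDecode(b, cond, sub)
  expect_equal(meanAccuracy(r), 1)
  expect_equal(r@nTestPerFold, 8L)
  g <- perFold(r) * 8
  expect_equal(g, round(g))
})

test_that("null patterns decode at chance over many participants", {
  d <- makeBlockDesign()
  ns <- noiseSpec(physScale = 1)
  acc <- vapply(1:60, function(p) {
    y <- simulateParticipant(d, nullGroundTruth(25, seed = 4000 + p), ns,
                             seed = 6000 + p)
    meanAccuracy(svmForParticipant(y, d))
  }, numeric(1))
  se <- sd(acc) / sqrt(length(acc))
  expect_lt(abs(mean(acc) - 0.5), 3 * se + 0.02)
})

test_that("decoding accuracy rises as thermal noise falls", {
  d <- makeBlockDesign()
  gt <- fixedTruth(c(2, rep(0, 19)), c(-2, rep(0, 19)))  # one informative voxel
  acc <- vapply(c(6, 3, 1.5), function(th) {
    mean(vapply(1:10, function(p) {
      y <- simulateParticipant(d, gt,
                               noiseSpec(attentionSd = 1, thermalSd = th,
                                         physScale = 0), seed = 300 + p)
      meanAccuracy(svmForParticipant(y, d))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
  expect_gt(acc[1], 0.5)
  expect_lt(acc[1], 1)
})

test_that("a single-class training fold is rejected", {
  b <- matrix(rnorm(16 * 4), 16, 4)
  cond <- rep(c(1, 2), c(8, 8))          # class confounded with subrun
  sub <- rep(1:2, each = 8)
  expect_error(svmDecode(b, cond, sub), "single class")
})
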