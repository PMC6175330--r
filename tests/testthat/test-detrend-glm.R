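test_that("detrend removes exactly the drift it models", {
  n <- 64; t <- seq_len(n)
  expect_lt(max(abs(detrend(cbind(3 * t + 2, -0.5 * t + 7)))), 1e-10)
  expect_lt(max(abs(detrend(cbind(sin(2 * pi * t / n),
                                  cos(2 * pi * t / n))))), 1e-10)
  expect_error(detrend(matrix(1:6, 3, 2)), "timepoints")
})

test_that("detrend agrees with an explicit QR projection oracle and shrinks variance", {
  set.seed(11)
  n <- 50
  y <- matrix(rnorm(n * 4), n, 4)
  t <- seq_len(n)
  B <- cbind(1, t - mean(t), sin(2 * pi * t / n), cos(2 * pi * t / n))
  oracle <- y - B %*% solve(crossprod(B), crossprod(B, y))
  out <- detrend(y)
  expect_equal(out, oracle, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(out))), 1e-12)
  expect_true(all(apply(out, 2, var) < apply(y, 2, var)))
})

test_that("OLS recovers condition means exactly from noiseless data", {
  d <- makeBlockDesign()
  gt <- drawGroundTruth(20, seed = 6)
  X <- subrunDesign(d, 1)
  y <- X %*% t(conditionMeans(gt))
  fit <- fitGlm(y, X, eventCondition = c(1L, 2L))
  expect_lt(max(abs(fit@betas - t(conditionMeans(gt)))), 1e-8)
  expect_lt(max(abs(contrastEstimate(fit) - contrastVector(gt))), 1e-8)
  # full pipeline with drift nuisance regressors is also exact at zero noise
  y4 <- simulateParticipant(d, gt, noiseSpec(0, 0, physScale = 0), seed = 1)
  fits <- fitSubrunGlms(y4, d)
  for (f in fits) {
    expect_lt(max(abs(f@betas[f@eventColumns, ] - t(conditionMeans(gt)))),
              1e-8)
    expect_lt(max(abs(contrastEstimate(f) - contrastVector(gt))), 1e-8)
  }
})

test_that("block-model betas average to the condition-model betas", {
  d <- makeBlockDesign()
  gt <- drawGroundTruth(12, seed = 7)
  # with noise and no drift columns the designs are orthogonal and the
  # identity is exact
  y <- simulateParticipant(d, gt, noiseSpec(physScale = 0.5), seed = 13)
  fc <- fitSubrunGlms(y, d, eventModel = "condition", drift = FALSE)
  fb <- fitSubrunGlms(y, d, eventModel = "block", drift = FALSE)
  for (k in 1:4) {
    bb <- fb[[k]]@betas[fb[[k]]@eventColumns, ]
    cond <- fb[[k]]@eventCondition
    for (cnd in 1:2)
      expect_equal(colMeans(bb[cond == cnd, , drop = FALSE]),
                   fc[[k]]@betas[cnd, ], tolerance = 1e-10)
    expect_equal(nrow(bb), 8)
  }
  # with drift nuisance included the identity holds on noiseless data
  y0 <- simulateParticipant(d, gt, noiseSpec(0, 0, physScale = 0), seed = 13)
  fc0 <- fitSubrunGlms(y0, d, eventModel = "condition")
  fb0 <- fitSubrunGlms(y0, d, eventModel = "block")
  bb <- fb0[[1]]@betas[fb0[[1]]@eventColumns, ]
  cond <- fb0[[1]]@eventCondition
  for (cnd in 1:2)
    expect_equal(colMeans(bb[cond == cnd, , drop = FALSE]),
                 fc0[[1]]@betas[cnd, ], tolerance = 1e-8)
})

test_that("full-design block model has 16 regressors per condition", {
  d <- makeBlockDesign()
  y <- simulateParticipant(d, drawGroundTruth(10, seed = 1),
                           noiseSpec(), seed = 2)
  fb <- fitSubrunGlms(y, d, eventModel = "block")
  cond <- unlist(lapply(fb, function(f) f@eventCondition))
  expect_equal(as.vector(table(cond)), c(16L, 16L))
})

test_that("rank-deficient designs are rejected naming the dependent columns", {
  X <- cbind(rnorm(20), rnorm(20))
  X <- cbind(X, X[, 1])                     # duplicate of column 1
  expect_error(fitGlm(matrix(rnorm(20), 20, 1), X), "3")
})

test_that("residuals are orthogonal to the design and refits are null", {
  d <- makeBlockDesign()
  y <- simulateParticipant(d, drawGroundTruth(15, seed = 3),
                           noiseSpec(physScale = 1), seed = 4)
  fits <- fitSubrunGlms(y, d)
  for (f in fits) {
    xr <- crossprod(f@designUsed, f@residuals)
    expect_lt(max(abs(xr)) / (nrow(f@designUsed) * max(abs(f@residuals))),
              1e-10)
    refit <- fitGlm(f@residuals, f@designUsed)
    expect_lt(max(abs(refit@betas)), 1e-8)
  }
})
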