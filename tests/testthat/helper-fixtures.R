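# Shared fixture builders; everything is generated in code at test time.

# A ground truth with explicit amplitudes (not normalized), e.g. for
# zero-contrast or single-voxel patterns.
fixedTruth <- function(meanA, meanB) {
  A <- cbind(meanA, meanB, deparse.level = 0)
  new("GroundTruth", conditionMeans = A, contrastVector = A[, 1] - A[, 2],
      normalized = FALSE)
}

zeroTruth <- function(nVoxels) fixedTruth(rep(0, nVoxels), rep(0, nVoxels))

# Mean-zero residual matrix with exactly orthogonal columns of equal
# crossproduct scale^2: orthonormal columns orthogonal to the constant
# vector, scaled. With scale = sqrt(n - 1) the sample covariance is exactly
# the identity, so under a diagonal shrinkage target the Ledoit-Wolf
# estimate is exactly I for any shrinkage intensity. When m such blocks of
# n rows each are pooled, use scale = sqrt((m * n - 1) / m) to make the
# pooled covariance exactly I.
identityResiduals <- function(n, p, seed = 1, scale = sqrt(n - 1)) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  Q * scale
}

# Independent dense reimplementation of the Ledoit-Wolf diagonal-target
# shrinkage estimator, written with explicit loops: the oracle against
# which the package's vectorized version is checked.
lwOracle <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) S[i, j] <- sum(Xc[, i] * Xc[, j]) / (n - 1)
  num <- 0; den <- 0
  for (i in 1:p) for (j in 1:p) {
    if (i == j) next
    w <- Xc[, i] * Xc[, j]
    num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
    den <- den + S[i, j]^2
  }
  lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  Sig <- (1 - lambda) * S
  diag(Sig) <- diag(S)
  list(Sigma = Sig, lambda = lambda)
}

# Dense fold-by-fold crossnobis oracle: explicit matrix inverse and dot
# products, using the oracle covariance above.
ldcOracle <- function(contrasts, residuals) {
  nsub <- nrow(contrasts)
  folds <- numeric(nsub)
  for (k in 1:nsub) {
    ctr <- colMeans(contrasts[-k, , drop = FALSE])
    Sig <- lwOracle(do.call(rbind, residuals[-k]))$Sigma
    w <- solve(Sig) %*% ctr
    folds[k] <- as.numeric(t(w) %*% contrasts[k, ])
  }
  list(perFold = folds, mean = mean(folds),
       normalized = mean(folds) / sqrt(ncol(contrasts)))
}
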