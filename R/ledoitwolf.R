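#' Ledoit-Wolf shrinkage covariance of noise residuals
#'
#' Estimates a well-conditioned voxel covariance as the convex combination
#' \eqn{(1-\lambda) S + \lambda T} of the sample covariance \eqn{S} and a
#' structured target \eqn{T}, with the shrinkage intensity \eqn{\lambda}
#' chosen analytically to minimise expected squared error (the Ledoit-Wolf
#' estimator). The default target is the diagonal of \eqn{S}: variances are
#' preserved and off-diagonal covariances are shrunk toward zero, which
#' keeps the estimate invertible even when voxels outnumber timepoints.
#' A scaled-identity target is available as an alternative.
#'
#' @param residuals Numeric matrix, timepoints x voxels, of GLM noise
#'   residuals (columns are demeaned internally).
#' @param target \code{"diagonal"} (default) or \code{"identity"}.
#' @return A [ShrinkageCovariance-class].
#' @examples
#' r <- matrix(rnorm(200 * 5), 200, 5)
#' ledoitWolfCov(r)
#' @export
ledoitWolfCov <- function(residuals, target = c("diagonal", "identity")) {
  target <- match.arg(target)
  X <- as.matrix(residuals)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 timepoints", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  SumW <- crossprod(Xc)                  # sum_k w_kij, w_kij = x_ki x_kj
  S <- SumW / (n - 1)
  if (max(abs(S)) == 0)
    stop("residuals are constant (zero sample covariance)", call. = FALSE)
  SumW2 <- crossprod(Xc^2)               # sum_k w_kij^2
  VarS <- n / (n - 1)^3 * (SumW2 - SumW^2 / n)
  if (target == "diagonal") {
    off <- row(S) != col(S)
    num <- sum(VarS[off])
    den <- sum(S[off]^2)
    lambda <- if (den > 0) max(0, min(1, num / den)) else 1
    Sigma <- (1 - lambda) * S
    diag(Sigma) <- diag(S)
  } else {
    mu <- mean(diag(S))
    Tm <- diag(mu, nrow(S))
    num <- sum(VarS)
    den <- sum((S - Tm)^2)
    lambda <- if (den > 0) max(0, min(1, num / den)) else 1
    Sigma <- (1 - lambda) * S + lambda * Tm
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  new("ShrinkageCovariance", matrix = Sigma, shrinkageIntensity = lambda,
      sourceDf = as.integer(n), target = target)
}
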