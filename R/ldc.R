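#' Cross-validated linear discriminant contrast (crossnobis)
#'
#' For each leave-one-subrun-out fold, the training contrast is the mean of
#' the training subruns' contrast estimates; the discriminant weights are
#' \eqn{\Sigma^{-1} c_{train}} with \eqn{\Sigma} the Ledoit-Wolf shrinkage
#' covariance of the pooled training residuals (the held-out subrun never
#' contributes to the covariance); and the fold statistic is the dot
#' product of the weights with the held-out subrun's contrast estimate.
#' Because training and test estimates carry independent noise, the
#' statistic is unbiased: it is centered on zero when there is no reliable
#' pattern difference, and negative values are legal. The fold average is
#' also reported divided by the square root of the voxel count so values
#' are comparable across ROI sizes.
#'
#' @param contrasts Numeric matrix, subruns x voxels, of per-subrun
#'   condition contrast estimates.
#' @param residuals List of per-subrun timepoints x voxels GLM residual
#'   matrices.
#' @param target Shrinkage target passed to [ledoitWolfCov()].
#' @return An [LdcResult-class].
#' @examples
#' P <- 3
#' contrasts <- matrix(rep(c(1, 0, 0), each = 4), 4, P)  # e1 every subrun
#' res <- lapply(1:4, function(k) matrix(rnorm(60 * P), 60, P))
#' computeLdc(contrasts, res)
#' @export
computeLdc <- function(contrasts, residuals, target = "diagonal") {
  contrasts <- as.matrix(contrasts)
  nsub <- nrow(contrasts)
  if (nsub < 2) stop("need at least 2 subruns for cross-validation",
                     call. = FALSE)
  stopifnot(length(residuals) == nsub)
  V <- ncol(contrasts)
  stopifnot(all(vapply(residuals, ncol, integer(1)) == V))
  perFold <- numeric(nsub)
  for (k in seq_len(nsub)) {
    ctrain <- colMeans(contrasts[-k, , drop = FALSE])
    Sigma <- ledoitWolfCov(do.call(rbind, residuals[-k]), target = target)
    ch <- chol(Sigma@matrix)
    w <- backsolve(ch, forwardsolve(t(ch), ctrain))
    perFold[k] <- sum(w * contrasts[k, ])
  }
  m <- mean(perFold)
  new("LdcResult", perFold = perFold, mean = m,
      normalized = m / sqrt(V), nVoxels = as.integer(V))
}

#' Run the LDC pipeline on one participant
#'
#' Fits the one-event-per-condition GLM (with drift nuisance regressors)
#' per subrun and evaluates [computeLdc()] on the per-subrun contrast
#' estimates and residuals.
#'
#' @param participant List of subrun timepoints x voxels matrices.
#' @param design A [BlockDesign-class].
#' @param target Shrinkage target passed to [ledoitWolfCov()].
#' @return An [LdcResult-class].
#' @export
ldcForParticipant <- function(participant, design, target = "diagonal") {
  fits <- fitSubrunGlms(participant, design, eventModel = "condition")
  computeLdc(do.call(rbind, lapply(fits, contrastEstimate)),
             lapply(fits, glmResiduals), target = target)
}
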