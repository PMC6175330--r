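#' Stimulus-versus-baseline functional contrast-to-noise ratio
#'
#' Fits a single on/off stimulus regressor (plus drift nuisance terms) per
#' voxel and returns amplitude / noise SD, where the amplitude is the
#' maximum of the fitted stimulus timecourse |beta x regressor| taken as an
#' absolute difference from the implicit zero baseline, and the noise SD is
#' the standard deviation of the GLM residuals (degrees-of-freedom
#' corrected). Voxels with zero residual SD are flagged undefined and
#' excluded from the ROI mean.
#'
#' @param data Numeric matrix, timepoints x voxels.
#' @param designOnOff Numeric vector of on/off (0/1-scaled) stimulus values,
#'   one per timepoint.
#' @param drift Include drift nuisance regressors (default \code{TRUE}).
#' @return A [FcnrResult-class].
#' @examples
#' on <- rep(rep(c(0, 1), each = 8), 4)
#' y <- cbind(2 * on + rnorm(64, sd = 1))
#' computeFcnrStimulus(y, on)
#' @export
computeFcnrStimulus <- function(data, designOnOff, drift = TRUE) {
  data <- as.matrix(data)
  designOnOff <- as.numeric(designOnOff)
  stopifnot(length(designOnOff) == nrow(data))
  if (max(designOnOff) <= 0)
    stop("stimulus regressor has no nonzero values", call. = FALSE)
  X <- matrix(designOnOff, ncol = 1)
  if (drift) X <- cbind(X, driftBasis(nrow(data)))
  fit <- fitGlm(data, X)
  beta <- fit@betas[1, ]
  amplitude <- abs(beta) * max(designOnOff)
  sdn <- sqrt(colSums(fit@residuals^2) / fit@df)
  # a residual SD at numerical-noise level relative to the signal counts
  # as zero (undefined fCNR), not as a tiny denominator
  ok <- sdn > 1e-12 * amplitude & sdn > 0
  per <- ifelse(ok, amplitude / sdn, NA_real_)
  new("FcnrResult", perVoxel = per,
      meanOverRoi = mean(per[ok]),
      nUndefined = sum(!ok), noise = "residual")
}

#' Between-condition simulation fCNR
#'
#' The contrast-to-noise ratio of the between-condition contrast: per voxel,
#' the absolute subrun-averaged contrast estimate divided by a noise SD.
#' Two denominators are available. \code{"contrast_se"} (default, the
#' quantity the calibration targets) uses the residual-based standard error
#' of the subrun-averaged contrast estimate - the noise SD of the contrast
#' itself, which accounts for the averaging over stimulus blocks and
#' subruns. \code{"residual"} uses the pooled per-timepoint residual SD,
#' i.e. the raw timecourse noise level.
#'
#' @param participant List of subrun timepoints x voxels matrices.
#' @param design A [BlockDesign-class].
#' @param noise Denominator definition, \code{"contrast_se"} or
#'   \code{"residual"}.
#' @param fits Optional precomputed list of per-subrun condition-model
#'   [GlmFit-class] objects (skips refitting).
#' @return A [FcnrResult-class].
#' @examples
#' ds <- simulateDataset(makeBlockDesign(), noiseSpec(physScale = 1.5),
#'                       1, 100, seed = 5)
#' computeSimFcnr(participantData(ds, 1), ds@design)
#' @export
computeSimFcnr <- function(participant, design,
                           noise = c("contrast_se", "residual"),
                           fits = NULL) {
  noise <- match.arg(noise)
  if (is.null(fits))
    fits <- fitSubrunGlms(participant, design, eventModel = "condition")
  nsub <- length(fits)
  cmat <- do.call(rbind, lapply(fits, contrastEstimate))  # subruns x voxels
  cbar <- colMeans(cmat)
  den <- if (noise == "contrast_se") {
    se2 <- colSums(do.call(rbind, lapply(fits, function(f) f@contrastSe))^2)
    sqrt(se2) / nsub
  } else {
    rss <- Reduce(`+`, lapply(fits, function(f) colSums(f@residuals^2)))
    df <- sum(vapply(fits, function(f) f@df, integer(1)))
    sqrt(rss / df)
  }
  ok <- den > 1e-12 * abs(cbar) & den > 0
  per <- ifelse(ok, abs(cbar) / den, NA_real_)
  if (!any(ok))
    stop("fCNR undefined for every voxel (zero noise denominator)",
         call. = FALSE)
  new("FcnrResult", perVoxel = per, meanOverRoi = mean(per[ok]),
      nUndefined = sum(!ok), noise = noise)
}

# Mean over participants of the ROI-mean simulation fCNR of a dataset.
meanSimFcnr <- function(dataset, noise = "contrast_se") {
  vals <- vapply(seq_len(nParticipants(dataset)), function(p)
    computeSimFcnr(participantData(dataset, p), dataset@design,
                   noise = noise)@meanOverRoi, numeric(1))
  mean(vals)
}
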