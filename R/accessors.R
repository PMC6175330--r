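#' @include AllGenerics.R
NULL

#' @describeIn BlockDesign Number of subruns.
#' @param x,k,... See generic.
#' @export
setMethod("nSubruns", "BlockDesign", function(x, ...) x@nSubruns)

#' @describeIn BlockDesign Sampling interval in seconds.
#' @export
setMethod("samplePeriod", "BlockDesign", function(x, ...) x@samplePeriodS)

#' @describeIn BlockDesign Full-timecourse boxcar regressor matrix.
#' @export
setMethod("regressors", "BlockDesign", function(x, ...) x@regressors)

#' @describeIn BlockDesign One subrun's timepoints x 2 regressors.
#' @export
setMethod("subrunDesign", "BlockDesign", function(x, k) {
  stopifnot(k >= 1, k <= x@nSubruns)
  x@regressors[x@subrun == k, , drop = FALSE]
})

#' @describeIn BlockDesign Per-block bookkeeping table.
#' @export
setMethod("blockTable", "BlockDesign", function(x, ...) x@blocks)

#' @describeIn GroundTruth Per-voxel condition difference.
#' @param x,... See generic.
#' @export
setMethod("contrastVector", "GroundTruth", function(x, ...) x@contrastVector)

#' @describeIn GroundTruth Voxels x 2 condition amplitudes.
#' @export
setMethod("conditionMeans", "GroundTruth", function(x, ...) x@conditionMeans)

#' @describeIn GroundTruth Number of voxels.
#' @export
setMethod("nVoxels", "GroundTruth", function(x, ...)
  nrow(x@conditionMeans))

#' @describeIn SimulatedDataset Number of participants.
#' @param x,p,... See generic.
#' @export
setMethod("nParticipants", "SimulatedDataset", function(x, ...)
  length(x@data))

#' @describeIn SimulatedDataset Number of voxels.
#' @export
setMethod("nVoxels", "SimulatedDataset", function(x, ...)
  ncol(x@data[[1]][[1]]))

#' @describeIn SimulatedDataset One participant's subrun matrices.
#' @export
setMethod("participantData", "SimulatedDataset", function(x, p) {
  stopifnot(p >= 1, p <= length(x@data))
  x@data[[p]]
})

#' @describeIn SimulatedDataset Per-participant ground truth (list, or one
#'   element if \code{p} given via \code{...}).
#' @export
setMethod("groundTruth", "SimulatedDataset", function(x, ...) {
  dots <- list(...)
  if (length(dots)) x@truth[[dots[[1]]]] else x@truth
})

#' @describeIn SimulatedDataset The noise specification used.
#' @export
setMethod("noiseSpecOf", "SimulatedDataset", function(x, ...) x@noise)

#' @describeIn NoiseSpec Physiological scale multiplier.
#' @param x,... See generic.
#' @export
setMethod("physScale", "NoiseSpec", function(x, ...) x@physScale)

#' @describeIn GlmFit Per-voxel condition contrast.
#' @param x,... See generic.
#' @export
setMethod("contrastEstimate", "GlmFit", function(x, ...) x@contrastEstimate)

#' @describeIn GlmFit Residual matrix.
#' @export
setMethod("glmResiduals", "GlmFit", function(x, ...) x@residuals)

#' @describeIn ShrinkageCovariance Estimated shrinkage intensity.
#' @param x,... See generic.
#' @export
setMethod("shrinkageIntensity", "ShrinkageCovariance", function(x, ...)
  x@shrinkageIntensity)

#' @describeIn LdcResult Per-fold LDC values.
#' @param x,... See generic.
#' @export
setMethod("perFold", "LdcResult", function(x, ...) x@perFold)

#' @describeIn LdcResult Fold-averaged LDC divided by sqrt(voxels).
#' @export
setMethod("normalizedLdc", "LdcResult", function(x, ...) x@normalized)

#' @describeIn LdcResult Number of voxels.
#' @export
setMethod("nVoxels", "LdcResult", function(x, ...) x@nVoxels)

#' @describeIn SvmResult Per-fold accuracies.
#' @param x,... See generic.
#' @export
setMethod("perFold", "SvmResult", function(x, ...) x@perFoldAccuracy)

#' @describeIn SvmResult Mean cross-validated accuracy.
#' @export
setMethod("meanAccuracy", "SvmResult", function(x, ...) x@meanAccuracy)

#' @describeIn PermutationResult Two-sided Monte-Carlo p-value.
#' @param x,... See generic.
#' @export
setMethod("pValue", "PermutationResult", function(x, ...) x@pValue)

#' @describeIn RejectionGrid Levels x levels x methods array of rejection
#'   probabilities.
#' @param x,... See generic.
#' @export
setMethod("rejectionCells", "RejectionGrid", function(x, ...) {
  dimnames(x@cells) <- list(
    format(x@fcnrLevels), format(x@fcnrLevels), x@methods)
  x@cells
})

setMethod("show", "BlockDesign", function(object) {
  cat(sprintf(
    "BlockDesign: %d subruns x %d blocks of %gs (gap %gs), TR %gs, %d samples\n",
    object@nSubruns, object@blocksPerSubrun, object@blockDurationS,
    object@interBlockGapS, object@samplePeriodS, nrow(object@regressors)))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf(
    "NoiseSpec: attention SD %g | thermal SD %g | %d phys components (SD %g) x scale %g\n",
    object@attentionSd, object@thermalSd, object@physNComponents,
    object@physComponentSd, object@physScale))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d voxels, mean |contrast| = %.6g%s\n",
              nrow(object@conditionMeans),
              mean(abs(object@contrastVector)),
              if (object@normalized) " (normalized)" else ""))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf(
    "SimulatedDataset: %d participants x %d subruns x %d timepoints x %d voxels (seed %d)\n",
    length(object@data), length(object@data[[1]]),
    nrow(object@data[[1]][[1]]), ncol(object@data[[1]][[1]]), object@seed))
})

setMethod("show", "GlmFit", function(object) {
  cat(sprintf("GlmFit: %d regressors x %d voxels, %d residual df%s\n",
              nrow(object@betas), ncol(object@betas), object@df,
              if (length(object@contrastEstimate))
                sprintf(", mean |contrast| = %.4g",
                        mean(abs(object@contrastEstimate))) else ""))
})

setMethod("show", "FcnrResult", function(object) {
  cat(sprintf("FcnrResult (%s): mean over ROI = %.4g (%d voxels, %d undefined)\n",
              object@noise, object@meanOverRoi, length(object@perVoxel),
              object@nUndefined))
})

setMethod("show", "ShrinkageCovariance", function(object) {
  cat(sprintf(
    "ShrinkageCovariance: %d x %d, lambda = %.4f (target: %s, %d obs)\n",
    nrow(object@matrix), ncol(object@matrix), object@shrinkageIntensity,
    object@target, object@sourceDf))
})

setMethod("show", "LdcResult", function(object) {
  cat(sprintf("LdcResult: mean = %.4g, normalized = %.4g over %d voxels\n",
              object@mean, object@normalized, object@nVoxels))
  cat("  per fold:", paste(sprintf("%.4g", object@perFold), collapse = " "),
      "\n")
})

setMethod("show", "SvmResult", function(object) {
  cat(sprintf("SvmResult: mean accuracy = %.3f (%s)\n",
              object@meanAccuracy,
              paste(sprintf("%.3f", object@perFoldAccuracy), collapse = " ")))
})

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace: %d volumes at %gs\n", nrow(object@samples),
              object@sampleIntervalS))
})

setMethod("show", "TsnrMap", function(object) {
  cat(sprintf("TsnrMap: median = %.4g over %d voxels (%d undefined)\n",
              object@median, length(object@perVoxel), object@nUndefined))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed mean diff = %.4g, p = %.4g (%d iterations)\n",
    object@observedMeanDiff, object@pValue, object@nIterations))
})

setMethod("show", "ExperimentConfig", function(object) {
  cat(sprintf(
    "ExperimentConfig: %d datasets x %d participants x %d voxels; alpha %g; levels %s; methods %s\n",
    object@nDatasets, object@nParticipants, object@nVoxels, object@alpha,
    paste(object@fcnrLevels, collapse = ", "),
    paste(object@methods, collapse = "+")))
})

setMethod("show", "RejectionGrid", function(object) {
  cat(sprintf(
    "RejectionGrid: %d fCNR levels x %s, %d datasets/cell, alpha %g\n",
    length(object@fcnrLevels), paste(object@methods, collapse = "+"),
    object@nDatasets, object@alpha))
  print(rejectionCells(object))
})
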