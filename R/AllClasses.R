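#' @import methods
NULL

#' Temporal layout of a two-condition alternating block design
#'
#' A \code{BlockDesign} holds the sampled timeline of an experiment in which
#' two stimulus conditions alternate in fixed-duration blocks within each
#' subrun, with the leading condition alternating across subruns so that both
#' conditions occupy early and late positions equally often. The boxcar
#' regressor matrix covers the full timecourse (all subruns concatenated);
#' \code{subrunDesign()} extracts one subrun's regressors.
#'
#' @slot blockDurationS Duration of one stimulus block in seconds.
#' @slot blocksPerSubrun Number of blocks per subrun, both conditions
#'   combined (must be even; each condition gets half).
#' @slot nSubruns Number of independent subruns (cross-validation folds).
#' @slot samplePeriodS Sampling interval (simulation TR) in seconds.
#' @slot interBlockGapS Fixation gap between consecutive blocks in seconds
#'   (0 for a contiguous alternating design).
#' @slot nConditions Number of conditions (always 2).
#' @slot regressors Numeric matrix, total timepoints x 2, of 0/1 boxcar
#'   values; column j is condition j.
#' @slot subrun Integer vector mapping each timepoint to its subrun.
#' @slot blocks \code{data.frame} with one row per block: \code{subrun},
#'   \code{block} (index within subrun), \code{condition}, \code{start},
#'   \code{end} (sample indices within the subrun).
#'
#' @seealso [makeBlockDesign()]
#' @export
setClass("BlockDesign",
  representation(
    blockDurationS  = "numeric",
    blocksPerSubrun = "integer",
    nSubruns        = "integer",
    samplePeriodS   = "numeric",
    interBlockGapS  = "numeric",
    nConditions     = "integer",
    regressors      = "matrix",
    subrun          = "integer",
    blocks          = "data.frame"
  )
)

setValidity("BlockDesign", function(object) {
  msg <- character()
  R <- object@regressors
  if (any(R < 0) || any(R > 1))
    msg <- c(msg, "regressor values must lie in [0, 1]")
  if (ncol(R) != 2L)
    msg <- c(msg, "exactly two condition regressors are required")
  if (any(R[, 1] > 0 & R[, 2] > 0))
    msg <- c(msg, "condition regressors must never be simultaneously nonzero")
  if (length(object@subrun) != nrow(R))
    msg <- c(msg, "subrun index length must match regressor rows")
  # per condition per subrun, total "on" duration = (blocks/2) * block duration
  expect_on <- (object@blocksPerSubrun / 2) * object@blockDurationS
  for (k in seq_len(object@nSubruns)) {
    on_s <- colSums(R[object@subrun == k, , drop = FALSE]) *
      object@samplePeriodS
    if (any(abs(on_s - expect_on) > 1e-9)) {
      msg <- c(msg, sprintf(
        "subrun %d: on-duration per condition (%s s) != %g s",
        k, paste(on_s, collapse = ", "), expect_on))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Noise model for simulated block-design data
#'
#' Three independent noise sources are combined: per-block amplitude jitter
#' ("attention" noise, modulated by the stimulus boxcar), per-timepoint white
#' thermal noise, and physiological noise constructed as a randomly weighted
#' projection of a small set of shared Gaussian timecourse components onto
#' all voxels (spatially correlated, with the projection weights fixed within
#' a participant and the component timecourses redrawn every subrun).
#'
#' @slot attentionSd SD of the per-block, per-voxel amplitude jitter
#'   (amplitude units).
#' @slot thermalSd SD of the per-timepoint, per-voxel thermal noise.
#' @slot physNComponents Number of shared physiological timecourse
#'   components.
#' @slot physComponentSd SD of each physiological component timecourse.
#' @slot physScale Dimensionless multiplier on the projected physiological
#'   signal; the knob the calibration procedure turns.
#'
#' @seealso [noiseSpec()], [calibrateNoiseToFcnr()]
#' @export
setClass("NoiseSpec",
  representation(
    attentionSd     = "numeric",
    thermalSd       = "numeric",
    physNComponents = "integer",
    physComponentSd = "numeric",
    physScale       = "numeric"
  )
)

setValidity("NoiseSpec", function(object) {
  msg <- character()
  sds <- c(object@attentionSd, object@thermalSd, object@physComponentSd,
           object@physScale)
  if (any(!is.finite(sds)) || any(sds < 0))
    msg <- c(msg, "all noise SDs and physScale must be finite and >= 0")
  if (object@physNComponents < 1L)
    msg <- c(msg, "physNComponents must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ground-truth activation pattern for one simulated participant
#'
#' Per-voxel response amplitudes for the two conditions and their difference
#' (the contrast vector). When \code{normalized} is \code{TRUE} the whole
#' pattern has been rescaled so the mean absolute contrast over voxels is
#' exactly 1.
#'
#' @slot conditionMeans Numeric matrix, voxels x 2, of activation amplitudes.
#' @slot contrastVector Numeric vector, condition 1 minus condition 2.
#' @slot normalized Logical; whether mean |contrast| has been scaled to 1
#'   (\code{FALSE} for e.g. null patterns with zero contrast).
#'
#' @seealso [drawGroundTruth()], [nullGroundTruth()]
#' @export
setClass("GroundTruth",
  representation(
    conditionMeans = "matrix",
    contrastVector = "numeric",
    normalized     = "logical"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (nrow(object@conditionMeans) != length(object@contrastVector))
    msg <- c(msg, "contrastVector length must equal nrow(conditionMeans)")
  if (ncol(object@conditionMeans) != 2L)
    msg <- c(msg, "conditionMeans must have 2 columns")
  d <- object@conditionMeans[, 1] - object@conditionMeans[, 2]
  if (max(abs(d - object@contrastVector)) > 1e-9)
    msg <- c(msg, "contrastVector must equal conditionMeans[,1] - conditionMeans[,2]")
  if (isTRUE(object@normalized) &&
      abs(mean(abs(object@contrastVector)) - 1) > 1e-12)
    msg <- c(msg, "normalized ground truth must have mean |contrast| == 1")
  if (length(msg)) msg else TRUE
})

#' Simulated multi-participant block-design dataset
#'
#' @slot data List of participants; each element is a list of subrun
#'   timepoints x voxels signal matrices.
#' @slot design The [BlockDesign-class] the data were generated from.
#' @slot truth List of per-participant [GroundTruth-class] objects.
#' @slot noise The [NoiseSpec-class] used.
#' @slot seed Integer root seed; regenerating with the same seed reproduces
#'   the dataset bit-for-bit.
#'
#' @seealso [simulateDataset()]
#' @export
setClass("SimulatedDataset",
  representation(
    data   = "list",
    design = "BlockDesign",
    truth  = "list",
    noise  = "NoiseSpec",
    seed   = "integer"
  )
)

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  if (length(object@data) != length(object@truth))
    msg <- c(msg, "one GroundTruth per participant is required")
  if (length(object@data)) {
    v <- vapply(object@data, function(p) ncol(p[[1]]), integer(1))
    if (length(unique(v)) != 1L)
      msg <- c(msg, "all participants must have the same voxel count")
  }
  if (length(msg)) msg else TRUE
})

#' Ordinary-least-squares fit of a subrun's timecourse
#'
#' Coefficients, residuals and (for two-condition event models) the
#' per-voxel condition contrast with its residual-based standard error.
#' Drift nuisance regressors are part of \code{designUsed}; event columns
#' are identified by \code{eventColumns}/\code{eventCondition}.
#'
#' @slot betas Coefficient matrix, regressors x voxels.
#' @slot contrastEstimate Per-voxel condition-1-minus-condition-2 contrast
#'   (length 0 when the design has no condition labels).
#' @slot contrastSe Residual-based standard error of
#'   \code{contrastEstimate} (same length).
#' @slot residuals Residual matrix, timepoints x voxels.
#' @slot designUsed The full design matrix the fit used.
#' @slot eventColumns Integer indices of event (non-nuisance) columns.
#' @slot eventCondition Integer condition label per event column.
#' @slot df Residual degrees of freedom (timepoints minus design rank).
#'
#' @seealso [fitGlm()], [fitSubrunGlms()]
#' @export
setClass("GlmFit",
  representation(
    betas            = "matrix",
    contrastEstimate = "numeric",
    contrastSe       = "numeric",
    residuals        = "matrix",
    designUsed       = "matrix",
    eventColumns     = "integer",
    eventCondition   = "integer",
    df               = "integer"
  )
)

setValidity("GlmFit", function(object) {
  # residual orthogonality to every design column, relative tolerance
  X <- object@designUsed
  r <- object@residuals
  if (nrow(X) != nrow(r))
    return("designUsed and residuals must have the same number of rows")
  xr <- crossprod(X, r)
  scale <- max(1, max(abs(X)) * max(1, max(abs(r))) * nrow(X))
  if (max(abs(xr)) / scale > 1e-8)
    return("residuals are not orthogonal to the design")
  TRUE
})

#' Functional contrast-to-noise ratio over an ROI
#'
#' @slot perVoxel Per-voxel fCNR values; \code{NA} where undefined
#'   (zero noise denominator).
#' @slot meanOverRoi Mean over the defined voxels.
#' @slot nUndefined Number of voxels flagged undefined and excluded.
#' @slot noise Which noise denominator was used (see [computeSimFcnr()]).
#' @export
setClass("FcnrResult",
  representation(
    perVoxel    = "numeric",
    meanOverRoi = "numeric",
    nUndefined  = "integer",
    noise       = "character"
  )
)

setValidity("FcnrResult", function(object) {
  v <- object@perVoxel
  if (any(v[!is.na(v)] < 0)) "fCNR values must be >= 0" else TRUE
})

#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Convex combination \eqn{(1-\lambda) S + \lambda T} of the sample
#' covariance \eqn{S} and a structured target \eqn{T}, with the shrinkage
#' intensity \eqn{\lambda} estimated from the data. The default target is
#' the diagonal of \eqn{S} (variances preserved, off-diagonals shrunk),
#' giving an invertible estimate even when voxels outnumber timepoints.
#'
#' @slot matrix The shrunk covariance, voxels x voxels.
#' @slot shrinkageIntensity Estimated \eqn{\lambda} in [0, 1].
#' @slot sourceDf Number of observations the estimate is based on.
#' @slot target Either \code{"diagonal"} or \code{"identity"}.
#' @seealso [ledoitWolfCov()]
#' @export
setClass("ShrinkageCovariance",
  representation(
    matrix             = "matrix",
    shrinkageIntensity = "numeric",
    sourceDf           = "integer",
    target             = "character"
  )
)

setValidity("ShrinkageCovariance", function(object) {
  msg <- character()
  M <- object@matrix
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-10 * max(1, max(abs(M))))
    msg <- c(msg, "covariance must be square and symmetric")
  l <- object@shrinkageIntensity
  if (l < 0 || l > 1) msg <- c(msg, "shrinkage intensity must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cross-validated linear discriminant contrast result
#'
#' @slot perFold One LDC value per cross-validation fold (held-out subrun).
#' @slot mean Average over folds.
#' @slot normalized \code{mean / sqrt(nVoxels)}, comparable across ROI sizes.
#' @slot nVoxels Number of voxels the statistic was computed on.
#' @seealso [computeLdc()]
#' @export
setClass("LdcResult",
  representation(
    perFold    = "numeric",
    mean       = "numeric",
    normalized = "numeric",
    nVoxels    = "integer"
  )
)

setValidity("LdcResult", function(object) {
  msg <- character()
  if (abs(object@normalized - object@mean / sqrt(object@nVoxels)) >
      1e-12 * max(1, abs(object@mean)))
    msg <- c(msg, "normalized must equal mean / sqrt(nVoxels)")
  if (length(msg)) msg else TRUE
})

#' Leave-one-subrun-out SVM decoding result
#'
#' @slot perFoldAccuracy Fraction correct per fold, each a multiple of
#'   1 / (test presentations per fold).
#' @slot meanAccuracy Average over folds.
#' @slot nTestPerFold Number of held-out presentations per fold.
#' @slot nBoundaryTies Count of test points that fell exactly on the
#'   decision boundary (assigned to the first class by convention).
#' @seealso [svmDecode()]
#' @export
setClass("SvmResult",
  representation(
    perFoldAccuracy = "numeric",
    meanAccuracy    = "numeric",
    nTestPerFold    = "integer",
    nBoundaryTies   = "integer"
  )
)

setValidity("SvmResult", function(object) {
  a <- object@perFoldAccuracy
  if (any(a < 0 | a > 1)) return("fold accuracies must lie in [0, 1]")
  g <- a * object@nTestPerFold
  if (max(abs(g - round(g))) > 1e-9)
    return("fold accuracies must be multiples of 1/nTestPerFold")
  TRUE
})

#' Rigid-body head-motion trace
#'
#' @slot samples Numeric matrix, volumes x 6: three translations (mm)
#'   followed by three rotations (radians).
#' @slot sampleIntervalS Time between consecutive volumes, in seconds.
#' @seealso [readMotionParams()], [integratedMotionMetric()]
#' @export
setClass("MotionTrace",
  representation(
    samples         = "matrix",
    sampleIntervalS = "numeric"
  )
)

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (nrow(object@samples) < 2L)
    msg <- c(msg, "a motion trace needs at least 2 volumes")
  if (ncol(object@samples) != 6L)
    msg <- c(msg, "a motion trace needs exactly 6 parameter columns")
  if (object@sampleIntervalS <= 0)
    msg <- c(msg, "sampleIntervalS must be positive")
  if (length(msg)) msg else TRUE
})

#' Temporal signal-to-noise ratio map
#'
#' @slot perVoxel Per-voxel mean/SD; \code{NA} where the SD is zero.
#' @slot median Median over the defined voxels.
#' @slot nUndefined Number of voxels flagged undefined.
#' @seealso [computeTsnr()]
#' @export
setClass("TsnrMap",
  representation(
    perVoxel   = "numeric",
    median     = "numeric",
    nUndefined = "integer"
  )
)

#' Fixed-effects permutation test result
#'
#' @slot observedMeanDiff Observed mean paired difference.
#' @slot nullDistribution Mean differences under within-participant label
#'   permutation.
#' @slot pValue Two-sided add-one Monte-Carlo p-value.
#' @slot nIterations Number of permutation iterations.
#' @seealso [ffxPermutationTest()]
#' @export
setClass("PermutationResult",
  representation(
    observedMeanDiff = "numeric",
    nullDistribution = "numeric",
    pValue           = "numeric",
    nIterations      = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) "pValue must lie in [0, 1]"
  else TRUE
})

#' Configuration for the decoding-sensitivity simulation experiment
#'
#' Bundles the design geometry, noise template, target fCNR levels and
#' cohort sizes for [runCohort()], [rejectionProbability()] and
#' [buildGrid()].
#'
#' @slot design A [BlockDesign-class].
#' @slot noiseTemplate A [NoiseSpec-class]; \code{physScale} is overridden
#'   per fCNR level by the calibration.
#' @slot fcnrLevels Strictly positive, sorted target mean-fCNR levels.
#' @slot nDatasets Simulated datasets per grid cell.
#' @slot nParticipants Participants per simulated cohort.
#' @slot nVoxels Voxels per participant.
#' @slot alpha Significance level for the per-dataset group test.
#' @slot seed Integer root seed.
#' @slot methods Methods to run: subset of \code{c("ldc", "svm")}.
#' @seealso [experimentConfig()]
#' @export
setClass("ExperimentConfig",
  representation(
    design        = "BlockDesign",
    noiseTemplate = "NoiseSpec",
    fcnrLevels    = "numeric",
    nDatasets     = "integer",
    nParticipants = "integer",
    nVoxels       = "integer",
    alpha         = "numeric",
    seed          = "integer",
    methods       = "character"
  )
)

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (any(object@fcnrLevels <= 0) || is.unsorted(object@fcnrLevels))
    msg <- c(msg, "fcnrLevels must be strictly positive and sorted")
  if (!all(object@methods %in% c("ldc", "svm")))
    msg <- c(msg, "methods must be a subset of c('ldc', 'svm')")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Rejection-probability grid over fCNR pairings
#'
#' For every ordered pair of calibrated fCNR levels and every method, the
#' proportion of simulated datasets in which the group-level paired test
#' between the two levels reached significance. Diagonal cells pair a level
#' with itself and so estimate the false-positive rate.
#'
#' @slot fcnrLevels The target mean-fCNR levels (grid axes).
#' @slot physScales Calibrated physiological noise scale per level.
#' @slot cells Numeric array levels x levels x methods of rejection
#'   probabilities (NA where not computed).
#' @slot methods Method names along the third dimension.
#' @slot nDatasets,nParticipants,alpha,seed Experiment conditions.
#' @seealso [buildGrid()]
#' @export
setClass("RejectionGrid",
  representation(
    fcnrLevels    = "numeric",
    physScales    = "numeric",
    cells         = "array",
    methods       = "character",
    nDatasets     = "integer",
    nParticipants = "integer",
    alpha         = "numeric",
    seed          = "integer"
  )
)

setValidity("RejectionGrid", function(object) {
  p <- object@cells
  if (any(p[!is.na(p)] < 0 | p[!is.na(p)] > 1))
    return("rejection probabilities must lie in [0, 1]")
  d <- dim(p)
  if (d[1] != length(object@fcnrLevels) || d[2] != length(object@fcnrLevels) ||
      d[3] != length(object@methods))
    return("cells array dimensions must match fcnrLevels and methods")
  TRUE
})
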