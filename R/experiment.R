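#' Build a sensitivity-experiment configuration
#'
#' Defaults reproduce the package's reference simulation conditions:
#' alternating 16 s blocks, 8 blocks per subrun, 4 subruns, 500 voxels,
#' 15 participants per cohort, 100 simulated datasets per grid cell, and
#' attention/thermal/physiological noise per [noiseSpec()].
#'
#' @param design A [BlockDesign-class].
#' @param noiseTemplate A [NoiseSpec-class]; its \code{physScale} is
#'   replaced by the per-level calibration.
#' @param fcnrLevels Target mean-fCNR levels (sorted, > 0).
#' @param nDatasets Simulated datasets per cell.
#' @param nParticipants Participants per cohort.
#' @param nVoxels Voxels per participant.
#' @param alpha Per-dataset significance level.
#' @param seed Root seed.
#' @param methods Subset of \code{c("ldc", "svm")}.
#' @return An [ExperimentConfig-class].
#' @export
experimentConfig <- function(design = makeBlockDesign(),
                             noiseTemplate = noiseSpec(),
                             fcnrLevels = seq(1.0, 2.4, by = 0.2),
                             nDatasets = 100, nParticipants = 15,
                             nVoxels = 500, alpha = 0.05, seed = 1,
                             methods = c("ldc", "svm")) {
  new("ExperimentConfig", design = design, noiseTemplate = noiseTemplate,
      fcnrLevels = sort(fcnrLevels), nDatasets = as.integer(nDatasets),
      nParticipants = as.integer(nParticipants),
      nVoxels = as.integer(nVoxels), alpha = alpha,
      seed = as.integer(seed), methods = methods)
}

#' Calibrate the physiological scale for every fCNR level
#'
#' @param config An [ExperimentConfig-class].
#' @param ... Passed to [calibrateNoiseToFcnr()].
#' @return Named numeric vector of calibrated \code{physScale} values, one
#'   per level, with the achieved fCNRs in attribute \code{"achievedFcnr"}.
#' @export
calibrateLevels <- function(config, ...) {
  out <- numeric(length(config@fcnrLevels))
  ach <- numeric(length(config@fcnrLevels))
  for (i in seq_along(config@fcnrLevels)) {
    ns <- calibrateNoiseToFcnr(config@design, config@noiseTemplate,
                               config@fcnrLevels[i],
                               nVoxels = config@nVoxels,
                               seed = childSeed(config@seed, 9000L, i), ...)
    out[i] <- physScale(ns)
    ach[i] <- attr(ns, "achievedFcnr")
  }
  names(out) <- format(config@fcnrLevels)
  attr(out, "achievedFcnr") <- ach
  out
}

#' Simulate and analyse one cohort
#'
#' Simulates \code{nParticipants} independent participants at a given
#' physiological noise scale and passes each through the requested decoding
#' analyses (condition-model GLM + LDC; block-model GLM + SVM).
#'
#' @param config An [ExperimentConfig-class].
#' @param physScale Physiological noise scale for this cohort (typically a
#'   calibrated value from [calibrateLevels()]).
#' @param seed Cohort seed.
#' @param truth Optional list of per-participant [GroundTruth-class]
#'   objects to reuse (matched cohorts across noise levels).
#' @param nullEffect Simulate with no true condition difference.
#' @param noiseSeedOffset Integer mixed into the noise streams only.
#' @param methods Overrides \code{config@methods}.
#' @return \code{data.frame} with one row per participant: \code{participant},
#'   \code{ldcNormalized} (if run), \code{svmAccuracy} (if run); the
#'   per-participant ground truths in attribute \code{"truth"}.
#' @export
runCohort <- function(config, physScale, seed, truth = NULL,
                      nullEffect = FALSE, noiseSeedOffset = 0L,
                      methods = NULL) {
  methods <- methods %||% config@methods
  ns <- config@noiseTemplate
  ns@physScale <- physScale
  ds <- simulateDataset(config@design, ns,
                        nParticipants = config@nParticipants,
                        nVoxels = config@nVoxels, seed = seed,
                        truth = truth, nullEffect = nullEffect,
                        noiseSeedOffset = noiseSeedOffset)
  out <- data.frame(participant = seq_len(config@nParticipants))
  if ("ldc" %in% methods)
    out$ldcNormalized <- vapply(seq_len(config@nParticipants), function(p)
      normalizedLdc(ldcForParticipant(participantData(ds, p), config@design)),
      numeric(1))
  if ("svm" %in% methods)
    out$svmAccuracy <- vapply(seq_len(config@nParticipants), function(p)
      meanAccuracy(svmForParticipant(participantData(ds, p), config@design)),
      numeric(1))
  attr(out, "truth") <- groundTruth(ds)
  out
}

# statistic column and chance level per method
.methodColumn <- function(method) {
  switch(method,
         ldc = list(col = "ldcNormalized", chance = 0),
         svm = list(col = "svmAccuracy", chance = 0.5),
         stop("unknown method: ", method, call. = FALSE))
}

#' Rejection probability for one fCNR pairing
#'
#' For each of \code{nDatasets} simulated datasets, two matched cohorts are
#' generated at the paired noise levels - the same participants (identical
#' ground-truth patterns) observed under different physiological noise -
#' and the per-participant statistic of the chosen method is compared by a
#' two-sided paired t-test. The rejection probability is the proportion of
#' datasets with p below \code{alpha}. Pairing a level with itself
#' estimates the false-positive rate. With \code{physScaleB = NULL} the
#' test is instead a one-sample t-test of the statistic against its chance
#' level (0 for LDC, 0.5 for SVM accuracy), measuring detection of any
#' pattern information at all.
#'
#' @param config An [ExperimentConfig-class].
#' @param physScaleA,physScaleB Calibrated physiological scales for the two
#'   levels; \code{physScaleB = NULL} requests the versus-chance test.
#' @param method \code{"ldc"} or \code{"svm"}.
#' @param nDatasets Overrides \code{config@nDatasets}.
#' @param seed Overrides \code{config@seed}.
#' @return Proportion of datasets reaching significance; number of datasets
#'   in attribute \code{"nDatasets"}, the p-values in attribute
#'   \code{"pValues"}.
#' @export
rejectionProbability <- function(config, physScaleA, physScaleB = NULL,
                                 method = "ldc", nDatasets = NULL,
                                 seed = NULL) {
  mc <- .methodColumn(method)
  nDatasets <- nDatasets %||% config@nDatasets
  seed <- seed %||% config@seed
  pvals <- vapply(seq_len(nDatasets), function(d) {
    sd1 <- childSeed(seed, 5000L, d)
    a <- runCohort(config, physScaleA, seed = sd1, methods = method,
                   noiseSeedOffset = 1L)
    if (is.null(physScaleB)) {
      oneSampleTTest(a[[mc$col]], alpha = config@alpha, mu = mc$chance)$p
    } else {
      b <- runCohort(config, physScaleB, seed = sd1,
                     truth = attr(a, "truth"), methods = method,
                     noiseSeedOffset = 2L)
      pairedTTest(a[[mc$col]], b[[mc$col]], alpha = config@alpha)$p
    }
  }, numeric(1))
  out <- mean(pvals < config@alpha)
  attr(out, "nDatasets") <- nDatasets
  attr(out, "pValues") <- pvals
  out
}

#' Fill the rejection-probability grid over all fCNR pairings
#'
#' Computes [rejectionProbability()] for every unordered pair of fCNR
#' levels (cells are symmetric and mirrored) and every requested method.
#' Cell seeds are derived from the root seed and the cell coordinates, so
#' any cell can be recomputed in isolation. When \code{progressDir} is
#' given, each finished cell is persisted as a small JSON file and
#' already-present cells are reused, making interrupted grids resumable.
#'
#' @param config An [ExperimentConfig-class].
#' @param physScales Calibrated scales from [calibrateLevels()]; computed
#'   on the fly if missing.
#' @param progressDir Optional directory for per-cell checkpoint files.
#' @return A [RejectionGrid-class].
#' @export
buildGrid <- function(config, physScales = NULL, progressDir = NULL) {
  if (is.null(physScales)) physScales <- calibrateLevels(config)
  L <- length(config@fcnrLevels)
  stopifnot(length(physScales) == L)
  if (!is.null(progressDir) && !dir.exists(progressDir))
    dir.create(progressDir, recursive = TRUE)
  cells <- array(NA_real_, dim = c(L, L, length(config@methods)))
  for (m in seq_along(config@methods)) {
    for (i in seq_len(L)) for (j in i:L) {
      cellfile <- if (!is.null(progressDir))
        file.path(progressDir, sprintf("cell_%s_%d_%d.json",
                                       config@methods[m], i, j)) else NULL
      if (!is.null(cellfile) && file.exists(cellfile)) {
        val <- jsonlite::fromJSON(cellfile)$value
      } else {
        val <- as.numeric(rejectionProbability(
          config, physScales[i], physScales[j], method = config@methods[m],
          seed = childSeed(config@seed, 7000L, m, i, j)))
        if (!is.null(cellfile))
          jsonlite::write_json(
            list(method = config@methods[m], i = i, j = j, value = val),
            cellfile, auto_unbox = TRUE, digits = NA)
      }
      cells[i, j, m] <- val
      cells[j, i, m] <- val
    }
  }
  new("RejectionGrid", fcnrLevels = config@fcnrLevels,
      physScales = as.numeric(physScales), cells = cells,
      methods = config@methods, nDatasets = config@nDatasets,
      nParticipants = config@nParticipants, alpha = config@alpha,
      seed = config@seed)
}
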