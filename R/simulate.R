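#' Create a noise specification
#'
#' Defaults match the package's reference simulation: per-block attention
#' jitter of SD 1, thermal noise of SD 1.8 per timepoint, and 10 unit-SD
#' physiological timecourse components projected onto voxels through random
#' weights, scaled by \code{physScale}.
#'
#' @param attentionSd SD of per-block amplitude jitter.
#' @param thermalSd SD of per-timepoint white noise.
#' @param physNComponents Number of shared physiological components.
#' @param physComponentSd SD of each component timecourse.
#' @param physScale Multiplier on the projected physiological signal.
#' @return A [NoiseSpec-class].
#' @examples
#' noiseSpec(physScale = 1.5)
#' @export
noiseSpec <- function(attentionSd = 1, thermalSd = 1.8,
                      physNComponents = 10, physComponentSd = 1,
                      physScale = 1) {
  new("NoiseSpec",
      attentionSd = attentionSd, thermalSd = thermalSd,
      physNComponents = as.integer(physNComponents),
      physComponentSd = physComponentSd, physScale = physScale)
}

#' Draw a ground-truth activation pattern
#'
#' Per voxel, the response amplitude to each condition is drawn i.i.d. from
#' a standard normal, so the unnormalized between-condition difference has
#' expected mean absolute value \eqn{2/\sqrt{\pi}}. The whole pattern (both
#' condition amplitudes, hence also the contrast) is then rescaled so the
#' mean absolute contrast over voxels is exactly 1. A zero-contrast draw
#' (probability zero in exact arithmetic) is rejected and redrawn with a
#' warning.
#'
#' @param nVoxels Number of voxels (>= 1).
#' @param seed Integer seed; if \code{NULL}, the current RNG state is used.
#' @param normalize If \code{FALSE}, return the raw draw (mainly for
#'   verifying the \eqn{2/\sqrt{\pi}} constant).
#' @return A [GroundTruth-class].
#' @examples
#' gt <- drawGroundTruth(500, seed = 1)
#' mean(abs(contrastVector(gt)))  # exactly 1
#' @export
drawGroundTruth <- function(nVoxels, seed = NULL, normalize = TRUE) {
  if (nVoxels < 1) stop("nVoxels must be >= 1", call. = FALSE)
  draw <- function() matrix(stats::rnorm(nVoxels * 2), nVoxels, 2)
  A <- if (is.null(seed)) draw() else withSeed(seed, draw())
  d <- A[, 1] - A[, 2]
  if (normalize) {
    tries <- 0L
    while (mean(abs(d)) == 0) {    # degenerate zero-contrast draw
      tries <- tries + 1L
      if (tries > 100L)
        stop("could not draw a nonzero contrast pattern", call. = FALSE)
      warning("zero-contrast draw rejected; redrawing", call. = FALSE)
      A <- if (is.null(seed)) draw() else
        withSeed(childSeed(seed, 997L, tries), draw())
      d <- A[, 1] - A[, 2]
    }
    s <- 1 / mean(abs(d))
    A <- A * s
    d <- d * s
  }
  new("GroundTruth", conditionMeans = A, contrastVector = d,
      normalized = normalize)
}

#' Null ground truth (no condition difference)
#'
#' Both conditions share the same i.i.d. standard-normal amplitude per
#' voxel, so the true contrast is identically zero. Used for null
#' simulations of the decoding statistics.
#'
#' @inheritParams drawGroundTruth
#' @return A [GroundTruth-class] with zero contrast.
#' @export
nullGroundTruth <- function(nVoxels, seed = NULL) {
  if (nVoxels < 1) stop("nVoxels must be >= 1", call. = FALSE)
  draw <- function() stats::rnorm(nVoxels)
  a <- if (is.null(seed)) draw() else withSeed(seed, draw())
  new("GroundTruth", conditionMeans = cbind(a, a, deparse.level = 0),
      contrastVector = rep(0, nVoxels), normalized = FALSE)
}

#' Simulate one participant's block-design timecourses
#'
#' The noiseless signal of a voxel is its condition amplitude times the
#' condition boxcar. Three noise sources are added: (i) attention noise - an
#' independent Gaussian amplitude offset per block per voxel, modulated by
#' that block's boxcar; (ii) thermal noise - i.i.d. Gaussian per timepoint
#' and voxel; (iii) physiological noise - \code{physNComponents} Gaussian
#' component timecourses, redrawn every subrun, projected onto voxels
#' through standard-normal weights that are drawn once per participant and
#' reused across subruns (giving the noise a stable spatial covariance), the
#' projection multiplied by \code{physScale}.
#'
#' @param design A [BlockDesign-class].
#' @param truth A [GroundTruth-class] with matching voxel count.
#' @param noise A [NoiseSpec-class].
#' @param seed Integer seed for this participant. Child streams for the
#'   projection weights and for each subrun's attention/thermal/
#'   physiological draws are derived deterministically, so individual noise
#'   components are reproducible in isolation.
#' @return List of subrun timepoints x voxels signal matrices.
#' @examples
#' d <- makeBlockDesign()
#' gt <- drawGroundTruth(50, seed = 1)
#' y <- simulateParticipant(d, gt, noiseSpec(physScale = 0.5), seed = 2)
#' dim(y[[1]])
#' @export
simulateParticipant <- function(design, truth, noise, seed) {
  V <- nVoxels(truth)
  A <- conditionMeans(truth)
  blocks <- blockTable(design)
  nsub <- nSubruns(design)
  # participant-level physiological projection weights, fixed across subruns
  W <- withSeed(childSeed(seed, 1L),
                matrix(stats::rnorm(noise@physNComponents * V),
                       noise@physNComponents, V))
  out <- vector("list", nsub)
  for (k in seq_len(nsub)) {
    X <- subrunDesign(design, k)
    Tn <- nrow(X)
    Y <- X %*% t(A)                     # noiseless design x condition means
    bl <- blocks[blocks$subrun == k, , drop = FALSE]
    if (noise@attentionSd > 0) {
      eps <- withSeed(childSeed(seed, 2L, k),
                      matrix(stats::rnorm(nrow(bl) * V, sd = noise@attentionSd),
                             nrow(bl), V))
      for (b in seq_len(nrow(bl)))
        Y[bl$start[b]:bl$end[b], ] <-
          Y[bl$start[b]:bl$end[b], ] +
          rep(eps[b, ], each = bl$end[b] - bl$start[b] + 1L)
    }
    if (noise@thermalSd > 0)
      Y <- Y + withSeed(childSeed(seed, 3L, k),
                        matrix(stats::rnorm(Tn * V, sd = noise@thermalSd),
                               Tn, V))
    if (noise@physScale > 0) {
      C <- withSeed(childSeed(seed, 4L, k),
                    matrix(stats::rnorm(Tn * noise@physNComponents,
                                        sd = noise@physComponentSd),
                           Tn, noise@physNComponents))
      Y <- Y + noise@physScale * (C %*% W)
    }
    out[[k]] <- Y
  }
  out
}

#' Simulate a multi-participant dataset
#'
#' Draws an independent ground-truth pattern per participant (or reuses
#' supplied ones) and simulates each participant's timecourses under a
#' common design and noise model. All randomness derives from \code{seed}
#' through per-participant child streams, so the dataset regenerates
#' bit-identically; supplying \code{noiseSeedOffset} changes only the noise
#' draws while keeping the ground truths, which is how matched cohorts at
#' two noise levels are built.
#'
#' @param design A [BlockDesign-class].
#' @param noise A [NoiseSpec-class].
#' @param nParticipants Number of participants.
#' @param nVoxels Number of voxels.
#' @param seed Integer root seed.
#' @param truth Optional list of [GroundTruth-class] objects (length
#'   \code{nParticipants}) to reuse.
#' @param nullEffect If \code{TRUE}, use [nullGroundTruth()] patterns (no
#'   condition difference).
#' @param noiseSeedOffset Integer mixed into the noise child streams only.
#' @return A [SimulatedDataset-class].
#' @examples
#' ds <- simulateDataset(makeBlockDesign(), noiseSpec(), nParticipants = 2,
#'                       nVoxels = 30, seed = 7)
#' ds
#' @export
simulateDataset <- function(design, noise, nParticipants = 15,
                            nVoxels = 500, seed, truth = NULL,
                            nullEffect = FALSE, noiseSeedOffset = 0L) {
  stopifnot(nParticipants >= 1)
  if (is.null(truth)) {
    truth <- lapply(seq_len(nParticipants), function(p) {
      if (nullEffect) nullGroundTruth(nVoxels, seed = childSeed(seed, 100L, p))
      else drawGroundTruth(nVoxels, seed = childSeed(seed, 100L, p))
    })
  } else {
    stopifnot(length(truth) == nParticipants)
  }
  data <- lapply(seq_len(nParticipants), function(p)
    simulateParticipant(design, truth[[p]], noise,
                        seed = childSeed(seed, 200L, p, noiseSeedOffset)))
  new("SimulatedDataset", data = data, design = design, truth = truth,
      noise = noise, seed = as.integer(seed))
}
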