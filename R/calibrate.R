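#' Calibrate physiological noise to a target mean fCNR
#'
#' Finds, by bisection on the physiological noise scale (attention and
#' thermal SDs held fixed), the [NoiseSpec-class] whose simulated data have
#' a mean simulation fCNR over voxels (see [computeSimFcnr()]) within
#' \code{tol} of \code{targetFcnr}. Measurement uses a fixed calibration
#' seed and a small pool of measurement participants, so the result is
#' deterministic for a given seed. Mean fCNR decreases monotonically in the
#' physiological scale; if the target exceeds the value achievable at zero
#' physiological noise, the call fails and reports the achievable bound.
#'
#' @param design A [BlockDesign-class].
#' @param noiseTemplate A [NoiseSpec-class] whose \code{physScale} is
#'   ignored; all-zero noise is rejected (fCNR would be infinite).
#' @param targetFcnr Target mean fCNR (> 0).
#' @param nVoxels Voxels per measurement participant.
#' @param nMeasure Number of measurement participants averaged per
#'   evaluation.
#' @param seed Calibration seed.
#' @param tol Relative tolerance (default 2\%).
#' @param maxIter Bisection iteration cap.
#' @param noise fCNR denominator definition passed to [computeSimFcnr()].
#' @return The calibrated [NoiseSpec-class], with the measured mean fCNR in
#'   attribute \code{"achievedFcnr"}.
#' @examples
#' \donttest{
#' ns <- calibrateNoiseToFcnr(makeBlockDesign(), noiseSpec(), 1.8,
#'                            nVoxels = 200, seed = 11)
#' physScale(ns); attr(ns, "achievedFcnr")
#' }
#' @export
calibrateNoiseToFcnr <- function(design, noiseTemplate, targetFcnr,
                                 nVoxels = 500, nMeasure = 6, seed = 1,
                                 tol = 0.02, maxIter = 60,
                                 noise = "contrast_se") {
  stopifnot(targetFcnr > 0)
  if (noiseTemplate@attentionSd == 0 && noiseTemplate@thermalSd == 0)
    stop(paste("noise template has zero attention and thermal noise;",
               "fCNR is unbounded at zero physiological scale"),
         call. = FALSE)
  measure <- function(ps) {
    ns <- noiseTemplate; ns@physScale <- ps
    ds <- simulateDataset(design, ns, nParticipants = nMeasure,
                          nVoxels = nVoxels, seed = seed)
    meanSimFcnr(ds, noise = noise)
  }
  f0 <- measure(0)
  if (targetFcnr > f0)
    stop(sprintf(
      "target fCNR %.4g unreachable: maximum achievable (physScale = 0) is %.4g",
      targetFcnr, f0), call. = FALSE)
  lo <- 0; flo <- f0
  hi <- 1
  fhi <- measure(hi)
  tries <- 0L
  while (fhi > targetFcnr) {        # expand bracket upward
    lo <- hi; flo <- fhi
    hi <- hi * 2
    fhi <- measure(hi)
    tries <- tries + 1L
    if (tries > 40L)
      stop("could not bracket the target fCNR", call. = FALSE)
  }
  achieved <- NA_real_; mid <- hi
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    fm <- measure(mid)
    if (abs(fm - targetFcnr) / targetFcnr <= tol) { achieved <- fm; break }
    if (fm > targetFcnr) lo <- mid else hi <- mid
  }
  if (is.na(achieved)) {
    achieved <- measure(mid)
    if (abs(achieved - targetFcnr) / targetFcnr > tol)
      warning(sprintf(
        "calibration stopped at fCNR %.4g (target %.4g, tol %.2g%%)",
        achieved, targetFcnr, 100 * tol), call. = FALSE)
  }
  out <- noiseTemplate
  out@physScale <- mid
  attr(out, "achievedFcnr") <- achieved
  out
}
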