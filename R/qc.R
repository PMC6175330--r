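#' Read SPM-style realignment parameters
#'
#' Reads a whitespace-delimited 6-column rigid-body parameter file
#' (three translations in mm, three rotations) as written by SPM's
#' realignment (\code{rp_*.txt}). SPM stores rotations in radians; set
#' \code{rotationUnits = "degrees"} to convert on read.
#'
#' @param file Path to the parameter file.
#' @param sampleIntervalS Inter-volume interval in seconds.
#' @param rotationUnits \code{"radians"} (default) or \code{"degrees"}.
#' @return A [MotionTrace-class].
#' @export
readMotionParams <- function(file, sampleIntervalS,
                             rotationUnits = c("radians", "degrees")) {
  rotationUnits <- match.arg(rotationUnits)
  m <- as.matrix(utils::read.table(file))
  if (ncol(m) != 6)
    stop(sprintf("expected 6 columns, found %d", ncol(m)), call. = FALSE)
  dimnames(m) <- NULL
  if (rotationUnits == "degrees")
    m[, 4:6] <- m[, 4:6] * pi / 180
  motionTrace(m, sampleIntervalS)
}

#' Construct a motion trace
#'
#' @param samples Numeric matrix, volumes x 6: translations (mm) then
#'   rotations (radians).
#' @param sampleIntervalS Inter-volume interval in seconds.
#' @return A [MotionTrace-class].
#' @export
motionTrace <- function(samples, sampleIntervalS) {
  new("MotionTrace", samples = as.matrix(samples),
      sampleIntervalS = sampleIntervalS)
}

#' Integrated head-motion metric (mm per second)
#'
#' Summarises a six-parameter rigid-body motion trace as a single motion
#' rate. Rotation angles are converted to arc-length displacements using a
#' rotational radius (default 57 mm, a typical adult head), framewise
#' differences of the six displacement parameters are combined by
#' root-sum-of-squares, divided by the inter-volume interval, and averaged
#' over all volume pairs. Depends only on parameter differences, so any
#' constant offset per column is ignored.
#'
#' @param trace A [MotionTrace-class].
#' @param radiusMm Rotational radius in millimetres.
#' @return Scalar motion rate in mm/s.
#' @examples
#' tr <- motionTrace(rbind(rep(0, 6), c(1, 0, 0, 0, 0, 0)), 1)
#' integratedMotionMetric(tr)   # 1 mm/s
#' @export
integratedMotionMetric <- function(trace, radiusMm = 57) {
  m <- trace@samples
  disp <- m
  disp[, 4:6] <- disp[, 4:6] * radiusMm    # arc length = radius x angle
  d <- diff(disp)
  mean(sqrt(rowSums(d^2))) / trace@sampleIntervalS
}

#' Temporal signal-to-noise ratio
#'
#' Per voxel, the timecourse mean divided by the timecourse SD. Voxels
#' with zero SD are flagged undefined (\code{NA}) and excluded from the
#' reported median, with their count retained.
#'
#' @param timeseries Numeric matrix, timepoints x voxels.
#' @return A [TsnrMap-class].
#' @examples
#' y <- matrix(100 + rnorm(1000, sd = 10), 100, 10)
#' computeTsnr(y)
#' @export
computeTsnr <- function(timeseries) {
  y <- as.matrix(timeseries)
  if (nrow(y) < 2) stop("need at least 2 timepoints", call. = FALSE)
  mu <- colMeans(y)
  sd <- apply(y, 2, stats::sd)
  ok <- sd > 0
  per <- ifelse(ok, mu / sd, NA_real_)
  new("TsnrMap", perVoxel = per,
      median = if (any(ok)) stats::median(per[ok]) else NA_real_,
      nUndefined = sum(!ok))
}
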