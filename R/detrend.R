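# Drift basis for one subrun segment: constant, centered linear ramp, and
# one sine/cosine pair whose period equals the segment length.
driftBasis <- function(n) {
  t <- seq_len(n)
  cbind(intercept = rep(1, n),
        linear = t - mean(t),
        sin1 = sin(2 * pi * t / n),
        cos1 = cos(2 * pi * t / n))
}

#' Remove linear and first-order sinusoidal drift from a timecourse segment
#'
#' Projects out a constant, a linear ramp, and one sine/cosine pair whose
#' period equals the segment length. Intended to be applied independently
#' per subrun segment so that no trend information leaks across
#' cross-validation folds. The output has zero mean per voxel.
#'
#' @param x Numeric matrix, timepoints x voxels (a vector is treated as one
#'   voxel).
#' @param samplePeriodS Sampling interval in seconds (kept for interface
#'   symmetry; the basis depends only on the segment length).
#' @return Detrended matrix of the same shape.
#' @examples
#' y <- outer(1:32, c(1, 2))        # pure ramps
#' max(abs(detrend(y)))             # ~ 0
#' @export
detrend <- function(x, samplePeriodS = NULL) {
  x <- as.matrix(x)
  B <- driftBasis(nrow(x))
  if (nrow(x) < ncol(B))
    stop(sprintf("detrend needs at least %d timepoints, got %d",
                 ncol(B), nrow(x)), call. = FALSE)
  qr.resid(qr(B), x)
}
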