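#' Ordinary least squares fit of a timecourse matrix
#'
#' Plain OLS of every voxel's timecourse on a common design matrix. The
#' design must be full column rank; a rank-deficient design is rejected
#' with the indices of the dependent columns. When \code{eventCondition}
#' labels (condition 1/2 per event column) are supplied, the per-voxel
#' condition contrast (mean of condition-1 event betas minus mean of
#' condition-2 event betas) and its residual-based standard error are
#' computed.
#'
#' @param data Numeric matrix, timepoints x voxels.
#' @param design Numeric matrix, timepoints x regressors.
#' @param eventColumns Integer indices of the event (non-nuisance) columns;
#'   defaults to all columns when \code{eventCondition} is given and has
#'   length \code{ncol(design)}.
#' @param eventCondition Integer vector (values 1/2), condition of each
#'   event column, or \code{NULL} for a contrast-free fit.
#' @return A [GlmFit-class].
#' @examples
#' d <- makeBlockDesign()
#' X <- subrunDesign(d, 1)
#' gt <- drawGroundTruth(20, seed = 1)
#' y <- X %*% t(conditionMeans(gt))          # noiseless
#' fit <- fitGlm(y, X, eventCondition = c(1L, 2L))
#' max(abs(contrastEstimate(fit) - contrastVector(gt)))
#' @export
fitGlm <- function(data, design, eventColumns = NULL, eventCondition = NULL) {
  data <- as.matrix(data); design <- as.matrix(design)
  stopifnot(nrow(data) == nrow(design))
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    dep <- sort(qx$pivot[seq.int(qx$rank + 1L, ncol(design))])
    stop(sprintf("design is rank deficient; dependent column(s): %s",
                 paste(dep, collapse = ", ")), call. = FALSE)
  }
  betas <- qr.coef(qx, data)
  resid <- qr.resid(qx, data)
  df <- nrow(data) - qx$rank
  ce <- numeric(0); se <- numeric(0)
  if (!is.null(eventCondition)) {
    if (is.null(eventColumns)) {
      stopifnot(length(eventCondition) <= ncol(design))
      eventColumns <- seq_along(eventCondition)
    }
    stopifnot(length(eventColumns) == length(eventCondition),
              all(eventCondition %in% c(1L, 2L)),
              any(eventCondition == 1L), any(eventCondition == 2L))
    w <- numeric(ncol(design))
    w[eventColumns[eventCondition == 1L]] <- 1 / sum(eventCondition == 1L)
    w[eventColumns[eventCondition == 2L]] <- -1 / sum(eventCondition == 2L)
    ce <- as.numeric(crossprod(w, betas))
    # Var(w'beta) = sigma^2 * w'(X'X)^-1 w, sigma^2 from residuals
    R <- qr.R(qx)
    wp <- w[qx$pivot]
    u <- backsolve(R, wp, transpose = TRUE)
    quad <- sum(u^2)
    sigma2 <- colSums(resid^2) / df
    se <- sqrt(quad * sigma2)
  }
  new("GlmFit", betas = betas, contrastEstimate = ce, contrastSe = se,
      residuals = resid, designUsed = design,
      eventColumns = as.integer(eventColumns %||% integer(0)),
      eventCondition = as.integer(eventCondition %||% integer(0)),
      df = as.integer(df))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build one subrun's design matrix for a given event model, with drift
# nuisance regressors appended. The constant column is included only when
# the event regressors do not already span it (with a contiguous block
# design the condition boxcars tile the timecourse and sum to 1, so adding
# an intercept would make the design rank deficient).
buildEventDesign <- function(design, k, eventModel = c("condition", "block"),
                             drift = TRUE) {
  eventModel <- match.arg(eventModel)
  X <- subrunDesign(design, k)
  Tn <- nrow(X)
  if (eventModel == "condition") {
    E <- X
    cond <- c(1L, 2L)
  } else {
    bl <- blockTable(design)
    bl <- bl[bl$subrun == k, , drop = FALSE]
    E <- matrix(0, Tn, nrow(bl))
    for (b in seq_len(nrow(bl))) E[bl$start[b]:bl$end[b], b] <- 1
    cond <- as.integer(bl$condition)
  }
  if (!drift)
    return(list(X = E, eventColumns = seq_len(ncol(E)),
                eventCondition = cond))
  B <- driftBasis(Tn)
  # is the constant in the span of the event regressors?
  spans1 <- max(abs(qr.resid(qr(E), rep(1, Tn)))) < 1e-8
  nuis <- if (spans1) B[, -1, drop = FALSE] else B
  list(X = cbind(E, nuis), eventColumns = seq_len(ncol(E)),
       eventCondition = cond)
}

#' Fit per-subrun GLMs for a participant
#'
#' Builds, for each subrun, an event design under the requested model
#' ("condition": one regressor per condition; "block": one regressor per
#' block) with drift nuisance regressors (linear trend and one sine/cosine
#' pair, plus a constant whenever the event regressors do not already span
#' it), and fits each subrun by OLS. Fitting the drift terms inside the GLM
#' is equivalent to detrending data and design for the contrast estimate,
#' but keeps the condition amplitudes identifiable when the blocks tile the
#' timecourse.
#'
#' @param participant List of subrun timepoints x voxels matrices (one
#'   element of [SimulatedDataset-class]'s data, or any matching layout).
#' @param design The [BlockDesign-class] describing the timeline.
#' @param eventModel \code{"condition"} or \code{"block"}.
#' @param drift Include drift nuisance regressors (default \code{TRUE}).
#' @return List of [GlmFit-class], one per subrun.
#' @examples
#' ds <- simulateDataset(makeBlockDesign(), noiseSpec(), 1, 40, seed = 3)
#' fits <- fitSubrunGlms(participantData(ds, 1), ds@design)
#' fits[[1]]
#' @export
fitSubrunGlms <- function(participant, design,
                          eventModel = c("condition", "block"),
                          drift = TRUE) {
  eventModel <- match.arg(eventModel)
  stopifnot(length(participant) == nSubruns(design))
  lapply(seq_len(nSubruns(design)), function(k) {
    ed <- buildEventDesign(design, k, eventModel, drift)
    fitGlm(participant[[k]], ed$X, eventColumns = ed$eventColumns,
           eventCondition = ed$eventCondition)
  })
}
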