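#' Leave-one-subrun-out linear SVM decoding of block-wise patterns
#'
#' Trains a linear-kernel support vector machine (unit box constraint) on
#' the block-wise response patterns of all but one subrun and tests on the
#' held-out subrun's blocks, cycling through every subrun. Features are
#' standardized per voxel using training-fold statistics only. A test point
#' falling exactly on the decision boundary is assigned to the first class
#' and counted.
#'
#' @param blockBetas Numeric matrix, blocks x voxels, of per-block GLM
#'   coefficient patterns.
#' @param condition Integer/factor vector, condition label per block.
#' @param subrun Integer vector, subrun of each block.
#' @param cost SVM box constraint (default 1).
#' @return An [SvmResult-class].
#' @examples
#' set.seed(1)
#' b <- matrix(rnorm(32 * 10, sd = 0.1), 32, 10)
#' cond <- rep(rep(1:2, each = 4), 4); sub <- rep(1:4, each = 8)
#' b[, 1] <- b[, 1] + ifelse(cond == 1, 5, -5)
#' svmDecode(b, cond, sub)
#' @export
svmDecode <- function(blockBetas, condition, subrun, cost = 1) {
  blockBetas <- as.matrix(blockBetas)
  condition <- as.integer(as.factor(condition))
  subrun <- as.integer(subrun)
  stopifnot(nrow(blockBetas) == length(condition),
            length(condition) == length(subrun))
  folds <- sort(unique(subrun))
  if (length(folds) < 2)
    stop("need at least 2 subruns for cross-validation", call. = FALSE)
  acc <- numeric(length(folds))
  ntest <- integer(length(folds))
  ties <- 0L
  for (i in seq_along(folds)) {
    te <- subrun == folds[i]
    tr <- !te
    ytr <- condition[tr]
    if (length(unique(ytr)) < 2)
      stop(sprintf("training fold %d contains a single class", folds[i]),
           call. = FALSE)
    mu <- colMeans(blockBetas[tr, , drop = FALSE])
    sd <- apply(blockBetas[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    Xtr <- sweep(sweep(blockBetas[tr, , drop = FALSE], 2, mu), 2, sd, "/")
    Xte <- sweep(sweep(blockBetas[te, , drop = FALSE], 2, mu), 2, sd, "/")
    fit <- e1071::svm(Xtr, factor(ytr, levels = sort(unique(condition))),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    onb <- abs(dv) < 1e-12
    if (any(onb)) {
      ties <- ties + sum(onb)
      pred[onb] <- levels(pred)[1]      # boundary convention: first class
    }
    acc[i] <- mean(as.integer(as.character(pred)) == condition[te])
    ntest[i] <- sum(te)
  }
  if (length(unique(ntest)) != 1L)
    warning("unequal test-fold sizes", call. = FALSE)
  new("SvmResult", perFoldAccuracy = acc, meanAccuracy = mean(acc),
      nTestPerFold = ntest[1], nBoundaryTies = as.integer(ties))
}

#' Run the SVM decoding pipeline on one participant
#'
#' Fits the one-event-per-block GLM per subrun, collects the block-wise
#' coefficient patterns with their condition and subrun labels, and
#' evaluates [svmDecode()].
#'
#' @inheritParams ldcForParticipant
#' @param cost SVM box constraint.
#' @return An [SvmResult-class].
#' @export
svmForParticipant <- function(participant, design, cost = 1) {
  fits <- fitSubrunGlms(participant, design, eventModel = "block")
  betas <- do.call(rbind, lapply(fits, function(f)
    f@betas[f@eventColumns, , drop = FALSE]))
  condition <- unlist(lapply(fits, function(f) f@eventCondition))
  subrun <- rep(seq_along(fits),
                vapply(fits, function(f) length(f@eventColumns), integer(1)))
  svmDecode(betas, condition, subrun, cost = cost)
}
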