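#' Fixed-effects permutation test for paired condition measures
#'
#' Tests the mean within-participant difference between two conditions by
#' randomly exchanging each participant's pair of labels (independently,
#' with probability one half) and recording the resulting mean difference;
#' the observed mean difference is referred to this null distribution. The
#' two-sided p-value uses the add-one convention
#' \eqn{p = (\#\{|null| \ge |obs|\} + 1) / (n_{iter} + 1)}, so it is never
#' exactly zero. Participants are treated as fixed effects.
#'
#' @param valuesA,valuesB Per-participant paired measurements (equal
#'   length, at least 2).
#' @param nIterations Number of permutation iterations (default 10000).
#' @param seed Integer seed for the permutation draws.
#' @return A [PermutationResult-class].
#' @examples
#' a <- rnorm(15, mean = 0.5); b <- rnorm(15)
#' ffxPermutationTest(a, b, seed = 1)
#' @export
ffxPermutationTest <- function(valuesA, valuesB, nIterations = 10000,
                               seed = NULL) {
  stopifnot(length(valuesA) == length(valuesB), length(valuesA) >= 2)
  d <- valuesA - valuesB
  obs <- mean(d)
  if (all(d == 0)) {
    warning("all pairs identical; test is degenerate", call. = FALSE)
    return(new("PermutationResult", observedMeanDiff = 0,
               nullDistribution = rep(0, nIterations), pValue = 1,
               nIterations = as.integer(nIterations)))
  }
  n <- length(d)
  draw <- function() matrix(
    sample(c(-1, 1), n * nIterations, replace = TRUE), n, nIterations)
  S <- if (is.null(seed)) draw() else withSeed(seed, draw())
  null <- colMeans(d * S)
  p <- (sum(abs(null) >= abs(obs) - 1e-12) + 1) / (nIterations + 1)
  new("PermutationResult", observedMeanDiff = obs, nullDistribution = null,
      pValue = min(p, 1), nIterations = as.integer(nIterations))
}

# Degenerate-variance convention shared by the t-test wrappers: when the
# (differenced) sample is constant, t is 0 and p is 1 if the constant is 0,
# otherwise t is +/-Inf and p is 0.
.degenerateT <- function(m, alpha) {
  if (m == 0) list(statistic = 0, p = 1, reject = FALSE)
  else list(statistic = sign(m) * Inf, p = 0, reject = TRUE)
}

#' Two-sided paired t-test with a reject flag
#'
#' Thin wrapper over [stats::t.test()] adding the package's degenerate-case
#' convention: if the paired differences are constant, p = 1 when they are
#' identically zero and p = 0 otherwise.
#'
#' @param valuesA,valuesB Paired samples of equal length (>= 2).
#' @param alpha Significance level for the \code{reject} flag.
#' @return List with \code{statistic}, \code{p}, \code{reject}.
#' @export
pairedTTest <- function(valuesA, valuesB, alpha = 0.05) {
  stopifnot(length(valuesA) == length(valuesB), length(valuesA) >= 2)
  d <- valuesA - valuesB
  if (stats::sd(d) == 0) return(.degenerateT(mean(d), alpha))
  tt <- stats::t.test(valuesA, valuesB, paired = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       reject = tt$p.value < alpha)
}

#' Two-sided one-sample t-test of the mean against zero
#'
#' Same degenerate-case convention as [pairedTTest()].
#'
#' @param values Sample (length >= 2).
#' @param alpha Significance level for the \code{reject} flag.
#' @param mu Null mean (default 0).
#' @return List with \code{statistic}, \code{p}, \code{reject}.
#' @export
oneSampleTTest <- function(values, alpha = 0.05, mu = 0) {
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0) return(.degenerateT(mean(values) - mu, alpha))
  tt <- stats::t.test(values, mu = mu)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       reject = tt$p.value < alpha)
}
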