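#' Construct an alternating two-condition block design
#'
#' Builds the sampled timeline of a block-design experiment in which two
#' conditions alternate within each subrun (optionally separated by fixation
#' gaps) and the leading condition alternates across subruns, so that
#' condition order is counterbalanced over the session. Regressors are unit
#' boxcars sampled at \code{samplePeriodS}; no haemodynamic convolution is
#' applied.
#'
#' @param blockDurationS Block duration in seconds; must be an integer
#'   multiple of \code{samplePeriodS}.
#' @param blocksPerSubrun Blocks per subrun, both conditions combined; must
#'   be even.
#' @param nSubruns Number of subruns.
#' @param samplePeriodS Sampling interval (simulation TR) in seconds.
#' @param interBlockGapS Fixation gap between consecutive blocks, in
#'   seconds; must be an integer multiple of \code{samplePeriodS}. Gaps are
#'   placed between blocks only (none before the first or after the last
#'   block of a subrun).
#'
#' @return A [BlockDesign-class].
#'
#' @examples
#' d <- makeBlockDesign()
#' d
#' colSums(subrunDesign(d, 1))  # 32 "on" samples per condition
#' @export
makeBlockDesign <- function(blockDurationS = 16, blocksPerSubrun = 8,
                            nSubruns = 4, samplePeriodS = 2,
                            interBlockGapS = 0) {
  stopifnot(blockDurationS > 0, samplePeriodS > 0, nSubruns >= 1,
            blocksPerSubrun >= 2, interBlockGapS >= 0)
  chkdiv <- function(value, name) {
    r <- value / samplePeriodS
    if (abs(r - round(r)) > 1e-9)
      stop(sprintf(
        "%s (%g s) is not an integer multiple of samplePeriodS (%g s)",
        name, value, samplePeriodS), call. = FALSE)
    as.integer(round(r))
  }
  spb <- chkdiv(blockDurationS, "blockDurationS")
  spg <- chkdiv(interBlockGapS, "interBlockGapS")
  if (blocksPerSubrun %% 2 != 0)
    stop("blocksPerSubrun must be even so both conditions get equal blocks",
         call. = FALSE)

  nb <- as.integer(blocksPerSubrun)
  tps <- nb * spb + (nb - 1L) * spg   # samples per subrun
  reg <- matrix(0, tps * nSubruns, 2)
  subrun <- rep(seq_len(nSubruns), each = tps)
  blocks <- vector("list", nSubruns * nb)
  for (k in seq_len(nSubruns)) {
    lead <- if (k %% 2 == 1) 1L else 2L   # alternate leading condition
    off <- (k - 1L) * tps
    pos <- 0L
    for (b in seq_len(nb)) {
      cond <- if (b %% 2 == 1) lead else 3L - lead
      idx <- (pos + 1L):(pos + spb)
      reg[off + idx, cond] <- 1
      blocks[[(k - 1L) * nb + b]] <- data.frame(
        subrun = k, block = b, condition = cond,
        start = pos + 1L, end = pos + spb)
      pos <- pos + spb + if (b < nb) spg else 0L
    }
  }
  new("BlockDesign",
      blockDurationS = blockDurationS,
      blocksPerSubrun = nb,
      nSubruns = as.integer(nSubruns),
      samplePeriodS = samplePeriodS,
      interBlockGapS = interBlockGapS,
      nConditions = 2L,
      regressors = reg,
      subrun = subrun,
      blocks = do.call(rbind, blocks))
}
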