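#' Write a simulated dataset to a plain-text on-disk layout
#'
#' One tab-separated matrix file per participant per subrun
#' (\code{sub<p>_run<k>.tsv}, timepoints x voxels) plus a
#' \code{manifest.json} recording the design geometry, noise specification,
#' seed and every participant's ground-truth pattern.
#'
#' @param dataset A [SimulatedDataset-class].
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @seealso [readSimulatedDataset()]
#' @export
writeSimulatedDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dataset@design
  for (p in seq_len(nParticipants(dataset))) {
    pd <- participantData(dataset, p)
    for (k in seq_along(pd))
      utils::write.table(pd[[k]],
                         file.path(dir, sprintf("sub%02d_run%d.tsv", p, k)),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(
    design = list(blockDurationS = d@blockDurationS,
                  blocksPerSubrun = d@blocksPerSubrun,
                  nSubruns = d@nSubruns, samplePeriodS = d@samplePeriodS,
                  interBlockGapS = d@interBlockGapS),
    noise = list(attentionSd = dataset@noise@attentionSd,
                 thermalSd = dataset@noise@thermalSd,
                 physNComponents = dataset@noise@physNComponents,
                 physComponentSd = dataset@noise@physComponentSd,
                 physScale = dataset@noise@physScale),
    seed = dataset@seed,
    nParticipants = nParticipants(dataset),
    nVoxels = nVoxels(dataset),
    truth = lapply(dataset@truth, function(t)
      list(conditionMeans = conditionMeans(t), normalized = t@normalized)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated dataset written by [writeSimulatedDataset()]
#'
#' @param dir Directory containing the matrix files and manifest.
#' @return A [SimulatedDataset-class].
#' @export
readSimulatedDataset <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = TRUE)
  d <- manifest$design
  design <- makeBlockDesign(d$blockDurationS, d$blocksPerSubrun,
                            d$nSubruns, d$samplePeriodS, d$interBlockGapS)
  n <- manifest$noise
  noise <- noiseSpec(n$attentionSd, n$thermalSd, n$physNComponents,
                     n$physComponentSd, n$physScale)
  truth <- lapply(seq_len(manifest$nParticipants), function(p) {
    cm <- manifest$truth[[p]]$conditionMeans
    A <- if (is.matrix(cm)) cm else
      matrix(as.numeric(unlist(cm)), ncol = 2, byrow = TRUE)
    new("GroundTruth", conditionMeans = A,
        contrastVector = A[, 1] - A[, 2],
        normalized = isTRUE(manifest$truth[[p]]$normalized))
  })
  data <- lapply(seq_len(manifest$nParticipants), function(p)
    lapply(seq_len(d$nSubruns), function(k)
      as.matrix(utils::read.table(
        file.path(dir, sprintf("sub%02d_run%d.tsv", p, k)), sep = "\t"))))
  data <- lapply(data, function(pd) lapply(pd, function(m) {
    dimnames(m) <- NULL; m
  }))
  new("SimulatedDataset", data = data, design = design, truth = truth,
      noise = noise, seed = as.integer(manifest$seed))
}

#' Read an experiment configuration from JSON or YAML
#'
#' Recognised top-level keys (all optional, with [experimentConfig()]
#' defaults): \code{design} (\code{blockDurationS}, \code{blocksPerSubrun},
#' \code{nSubruns}, \code{samplePeriodS}, \code{interBlockGapS});
#' \code{noise} ([noiseSpec()] fields); \code{fcnrLevels};
#' \code{nDatasets}; \code{nParticipants}; \code{nVoxels}; \code{alpha};
#' \code{seed}; \code{methods}.
#'
#' @param file Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return An [ExperimentConfig-class].
#' @export
readExperimentConfig <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    yaml::read_yaml(file)
  } else jsonlite::fromJSON(file)
  design <- do.call(makeBlockDesign, cfg$design %||% list())
  noise <- do.call(noiseSpec, cfg$noise %||% list())
  args <- cfg[setdiff(names(cfg), c("design", "noise"))]
  do.call(experimentConfig,
          c(list(design = design, noiseTemplate = noise), args))
}

#' Export a timepoints x voxels matrix as 4D NIfTI
#'
#' Voxels are laid out on a dummy 3D grid (as close to cubic as possible,
#' padding with zeros) and timepoints become the 4th dimension; useful for
#' feeding simulated data through NIfTI-based pipelines. Requires the
#' \pkg{RNifti} package.
#'
#' @param timeseries Numeric matrix, timepoints x voxels.
#' @param file Output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{file}, invisibly.
#' @export
exportNifti <- function(timeseries, file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the 'RNifti' package is required for NIfTI export", call. = FALSE)
  y <- as.matrix(timeseries)
  V <- ncol(y); Tn <- nrow(y)
  nx <- ceiling(V^(1 / 3)); ny <- nx
  nz <- ceiling(V / (nx * ny))
  arr <- array(0, dim = c(nx, ny, nz, Tn))
  for (t in seq_len(Tn)) {
    v <- numeric(nx * ny * nz)
    v[seq_len(V)] <- y[t, ]
    arr[, , , t] <- v
  }
  RNifti::writeNifti(RNifti::asNifti(arr), file)
  invisible(file)
}
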