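#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the package's S4 classes; use these instead of
#' reaching into slots.
#'
#' @param x An object of one of the package's S4 classes.
#' @param ... Further arguments passed to methods.
#' @return The corresponding slot value (see the method for each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x, ...) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("nSubruns", function(x, ...) standardGeneric("nSubruns"))

#' @rdname accessors
#' @export
setGeneric("nParticipants", function(x, ...) standardGeneric("nParticipants"))

#' @rdname accessors
#' @export
setGeneric("samplePeriod", function(x, ...) standardGeneric("samplePeriod"))

#' @rdname accessors
#' @export
setGeneric("regressors", function(x, ...) standardGeneric("regressors"))

#' Extract one subrun's condition regressors
#'
#' @param x A [BlockDesign-class].
#' @param k Subrun index.
#' @return Timepoints x 2 boxcar matrix for subrun \code{k}.
#' @export
setGeneric("subrunDesign", function(x, k) standardGeneric("subrunDesign"))

#' @rdname accessors
#' @export
setGeneric("blockTable", function(x, ...) standardGeneric("blockTable"))

#' @rdname accessors
#' @export
setGeneric("contrastVector", function(x, ...) standardGeneric("contrastVector"))

#' @rdname accessors
#' @export
setGeneric("conditionMeans", function(x, ...) standardGeneric("conditionMeans"))

#' Extract one participant's simulated signal
#'
#' @param x A [SimulatedDataset-class].
#' @param p Participant index.
#' @return List of subrun timepoints x voxels matrices.
#' @export
setGeneric("participantData", function(x, p) standardGeneric("participantData"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("noiseSpecOf", function(x, ...) standardGeneric("noiseSpecOf"))

#' @rdname accessors
#' @export
setGeneric("physScale", function(x, ...) standardGeneric("physScale"))

#' @rdname accessors
#' @export
setGeneric("contrastEstimate", function(x, ...)
  standardGeneric("contrastEstimate"))

#' @rdname accessors
#' @export
setGeneric("glmResiduals", function(x, ...) standardGeneric("glmResiduals"))

#' @rdname accessors
#' @export
setGeneric("shrinkageIntensity", function(x, ...)
  standardGeneric("shrinkageIntensity"))

#' @rdname accessors
#' @export
setGeneric("perFold", function(x, ...) standardGeneric("perFold"))

#' @rdname accessors
#' @export
setGeneric("normalizedLdc", function(x, ...) standardGeneric("normalizedLdc"))

#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x, ...) standardGeneric("meanAccuracy"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("rejectionCells", function(x, ...) standardGeneric("rejectionCells"))
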