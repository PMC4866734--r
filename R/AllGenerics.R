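#' @include AllClasses.R
NULL

#' Accessors for paired datasets and models
#'
#' `primaryData` and `auxiliaryData` return the two feature matrices,
#' `markerLabels` the per-protein label vector (named by accession),
#' `classSet` the ordered class names and `proteinIds` the shared ordered
#' accession vector.
#'
#' @param object a [PairedDataset] or model object.
#' @return the corresponding slot content.
#' @aliases primaryData auxiliaryData markerLabels classSet proteinIds
#' @rdname accessors
#' @export
setGeneric("primaryData", function(object) standardGeneric("primaryData"))

#' @rdname accessors
#' @export
setGeneric("auxiliaryData", function(object) standardGeneric("auxiliaryData"))

#' @rdname accessors
#' @export
setGeneric("markerLabels", function(object) standardGeneric("markerLabels"))

#' @rdname accessors
#' @export
setGeneric("classSet", function(object) standardGeneric("classSet"))

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(object) standardGeneric("proteinIds"))

#' @rdname accessors
#' @param plan a [SplitPlan].
#' @export
setGeneric("trainIds", function(plan) standardGeneric("trainIds"))

#' @rdname accessors
#' @export
setGeneric("testIds", function(plan) standardGeneric("testIds"))
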