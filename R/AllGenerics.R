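#' @rdname DecisionModel-accessors
#' @export
setGeneric("criterionIds", function(x) standardGeneric("criterionIds"))

#' @rdname DecisionModel-accessors
#' @export
setGeneric("dimensionIds", function(x) standardGeneric("dimensionIds"))

#' @rdname DecisionModel-accessors
#' @export
setGeneric("nCriteria", function(x) standardGeneric("nCriteria"))

#' @rdname DecisionModel-accessors
#' @export
setGeneric("nDimensions", function(x) standardGeneric("nDimensions"))

#' @rdname DecisionModel-accessors
#' @export
setGeneric("criterionPartition",
           function(x) standardGeneric("criterionPartition"))

#' @rdname DecisionModel-accessors
#' @export
setGeneric("dimensionOf", function(x) standardGeneric("dimensionOf"))

#' @rdname WeightVector-accessors
#' @export
setGeneric("criterionWeights",
           function(x) standardGeneric("criterionWeights"))

#' @rdname WeightVector-accessors
#' @export
setGeneric("dimensionRollup", function(x) standardGeneric("dimensionRollup"))
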