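#' Accessors for DecisionModel
#'
#' \code{criterionIds}/\code{dimensionIds} return ids in canonical order;
#' \code{criterionPartition} returns, per dimension, the integer indices of
#' its criteria in that order; \code{dimensionOf} maps criterion id to
#' dimension id.
#'
#' @param x a \linkS4class{DecisionModel}.
#' @return character vectors, counts, or a named list of integer vectors.
#' @name DecisionModel-accessors
NULL

#' @rdname DecisionModel-accessors
setMethod("criterionIds", "DecisionModel", function(x) x@criteria$id)

#' @rdname DecisionModel-accessors
setMethod("dimensionIds", "DecisionModel", function(x) x@dimensions$id)

#' @rdname DecisionModel-accessors
setMethod("nCriteria", "DecisionModel", function(x) nrow(x@criteria))

#' @rdname DecisionModel-accessors
setMethod("nDimensions", "DecisionModel", function(x) nrow(x@dimensions))

#' @rdname DecisionModel-accessors
setMethod("criterionPartition", "DecisionModel", function(x) {
  idx <- seq_len(nCriteria(x))
  split(idx, factor(x@criteria$dimension, levels = dimensionIds(x)))
})

#' @rdname DecisionModel-accessors
setMethod("dimensionOf", "DecisionModel", function(x) {
  stats::setNames(x@criteria$dimension, x@criteria$id)
})

#' Accessors for WeightVector
#'
#' @param x a \linkS4class{WeightVector}.
#' @return \code{criterionWeights}: named per-criterion weights (sum 1);
#'   \code{dimensionRollup}: named per-dimension sums of member weights.
#' @name WeightVector-accessors
NULL

#' @rdname WeightVector-accessors
setMethod("criterionWeights", "WeightVector", function(x) x@weights)

#' @rdname WeightVector-accessors
setMethod("dimensionRollup", "WeightVector", function(x) x@rollup)

#' Matrix views of pipeline objects
#'
#' Every matrix-bearing class coerces to its plain numeric matrix with
#' criterion (or dimension) ids as dimnames.
#'
#' @param x the object.
#' @param ... ignored.
#' @return a numeric matrix.
#' @name as.matrix-methods
NULL

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "RawResponse", function(x, ...) x@matrix)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "AggregateMatrix", function(x, ...) x@matrix)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "NormalizedMatrix", function(x, ...) x@matrix)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "TotalInfluence", function(x, ...) x@matrix)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "DimensionMatrix", function(x, ...) x@matrix)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "NormalizedDimensionMatrix", function(x, ...) x@matrix)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "Supermatrix", function(x, ...) x@matrix)

setMethod("show", "DecisionModel", function(object) {
  part <- criterionPartition(object)
  cat(sprintf("DecisionModel: %d dimensions, %d criteria\n",
              nDimensions(object), nCriteria(object)))
  for (d in dimensionIds(object)) {
    lab <- object@dimensions$label[object@dimensions$id == d]
    cat(sprintf("  %s (%s): %s\n", d, lab,
                paste(criterionIds(object)[part[[d]]], collapse = ", ")))
  }
})

setMethod("show", "ExpertPanel", function(object) {
  groups <- vapply(object@responses, function(r) r@group, character(1))
  cat(sprintf("ExpertPanel: %d experts on %d criteria\n",
              length(object@responses), nCriteria(object@model)))
  if (!all(is.na(groups))) {
    tab <- table(groups, useNA = "no")
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  }
})

setMethod("show", "AggregateMatrix", function(object) {
  cat(sprintf("AggregateMatrix (%s of %s experts): %d x %d, entries [%g, %g]\n",
              object@method,
              ifelse(is.na(object@nExperts), "?", object@nExperts),
              nrow(object@matrix), ncol(object@matrix),
              min(object@matrix), max(object@matrix)))
})

setMethod("show", "TotalInfluence", function(object) {
  cat(sprintf("TotalInfluence: %d x %d, total influence %.4f\n",
              nrow(object@matrix), ncol(object@matrix), sum(object@r)))
})

setMethod("show", "Supermatrix", function(object) {
  cat(sprintf("Supermatrix: %d x %d, %s\n",
              nrow(object@matrix), ncol(object@matrix),
              if (isTRUE(object@stochastic)) "column-stochastic"
              else "unweighted"))
  if (length(object@zeroRows))
    cat("  zero block-rows:", paste(object@zeroRows, collapse = ", "), "\n")
})

setMethod("show", "WeightVector", function(object) {
  w <- sort(object@weights, decreasing = TRUE)
  cat("WeightVector (DANP influential weights, %):\n")
  print(round(100 * w, 2))
  cat("dimension rollups (%):\n")
  print(round(100 * object@rollup, 2))
})

setMethod("show", "RiskScore", function(object) {
  cat(sprintf("RiskScore: patient %s, risk level %.2f\n",
              object@patientId, object@score))
})
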