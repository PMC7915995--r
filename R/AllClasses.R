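#' @import methods
NULL

.TOL <- 1e-9

#' DecisionModel: dimensions, criteria and their partition
#'
#' A decision model is an ordered list of dimensions and an ordered list of
#' criteria, each criterion belonging to exactly one dimension. The criterion
#' order fixes the canonical row/column order of every matrix in the
#' pipeline, and the dimension membership fixes the block partition of the
#' total-influence matrix and the supermatrix.
#'
#' @slot dimensions data.frame with columns \code{id}, \code{label}, in
#'   canonical order.
#' @slot criteria data.frame with columns \code{id}, \code{label},
#'   \code{dimension}, in canonical order.
#' @export
setClass("DecisionModel",
  representation(dimensions = "data.frame", criteria = "data.frame"))

setValidity("DecisionModel", function(object) {
  d <- object@dimensions
  cr <- object@criteria
  if (!all(c("id", "label") %in% names(d)))
    return("dimensions must have columns 'id' and 'label'")
  if (!all(c("id", "label", "dimension") %in% names(cr)))
    return("criteria must have columns 'id', 'label' and 'dimension'")
  if (nrow(d) < 1L) return("at least one dimension is required")
  if (anyDuplicated(d$id)) return("duplicate dimension ids")
  if (anyDuplicated(cr$id)) return("duplicate criterion ids")
  bad <- setdiff(cr$dimension, d$id)
  if (length(bad))
    return(sprintf("criterion references undeclared dimension: %s",
                   paste(bad, collapse = ", ")))
  empty <- setdiff(d$id, cr$dimension)
  if (length(empty))
    return(sprintf("dimension with no criteria: %s",
                   paste(empty, collapse = ", ")))
  if (nrow(d) > nrow(cr)) return("more dimensions than criteria")
  TRUE
})

#' RawResponse: one expert's questionnaire matrix
#'
#' An n x n integer matrix on the 0--4 influence scale, zero diagonal.
#' Entry (i, j) is the influence of criterion i ON criterion j.
#'
#' @slot matrix numeric matrix, dimnames = criterion ids in canonical order.
#' @slot expertId character scalar.
#' @slot group character scalar, experience-group code (may be \code{NA}).
#' @export
setClass("RawResponse",
  representation(matrix = "matrix", expertId = "character",
                 group = "character"))

setValidity("RawResponse", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (any(diag(m) != 0)) return("nonzero diagonal")
  if (any(m < 0 | m > 4)) return("entries must lie in [0, 4]")
  if (any(m != round(m)))
    return("raw responses must be integers in {0, 1, 2, 3, 4}")
  if (length(object@expertId) != 1L) return("expertId must be a scalar")
  TRUE
})

#' ExpertPanel: a set of raw responses under one model
#'
#' @slot model the \linkS4class{DecisionModel} shared by all responses.
#' @slot responses list of \linkS4class{RawResponse}, in entry order (the
#'   default expert order for the consensus check).
#' @export
setClass("ExpertPanel",
  representation(model = "DecisionModel", responses = "list"))

setValidity("ExpertPanel", function(object) {
  if (length(object@responses) < 1L) return("panel must be nonempty")
  n <- nrow(object@model@criteria)
  ok <- vapply(object@responses, function(r)
    is(r, "RawResponse") && nrow(r@matrix) == n, logical(1))
  if (!all(ok)) return("all responses must be RawResponse of the model's size")
  ids <- vapply(object@responses, function(r) r@expertId, character(1))
  if (anyDuplicated(ids)) return("duplicate expert ids")
  TRUE
})

#' AggregateMatrix: the panel's initial average matrix
#'
#' The elementwise aggregate (median by default) of the panel's raw
#' responses. Unlike raw responses, aggregates may contain half-steps such
#' as 2.50 (the median of an even panel averages the two middle values).
#'
#' @slot matrix numeric n x n, zero diagonal, entries in [0, 4].
#' @slot method aggregation tag, e.g. "median".
#' @slot nExperts number of questionnaires aggregated (NA if loaded from
#'   a published table).
#' @export
setClass("AggregateMatrix",
  representation(matrix = "matrix", method = "character",
                 nExperts = "numeric"))

setValidity("AggregateMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (any(diag(m) != 0)) return("nonzero diagonal")
  if (any(m < 0 | m > 4)) return("entries must lie in [0, 4]")
  TRUE
})

#' NormalizedMatrix: the direct-influence matrix N
#'
#' N = AI / s where s = max(largest row sum, largest column sum) of the
#' aggregate AI, so that the Neumann series N + N^2 + ... converges.
#'
#' @slot matrix numeric n x n.
#' @slot scaleDivisor the positive divisor s.
#' @export
setClass("NormalizedMatrix",
  representation(matrix = "matrix", scaleDivisor = "numeric"))

setValidity("NormalizedMatrix", function(object) {
  m <- object@matrix
  rs <- max(rowSums(m)); cs <- max(colSums(m))
  if (rs > 1 + 1e-8 || cs > 1 + 1e-8)
    return("row and column sums must not exceed 1")
  if (object@scaleDivisor <= 0) return("scaleDivisor must be positive")
  TRUE
})

#' TotalInfluence: T = N (I - N)^-1 with its row/column sums
#'
#' @slot matrix the total-influence matrix T (nonnegative).
#' @slot r row sums (influence given by each criterion).
#' @slot d column sums (influence received by each criterion).
#' @export
setClass("TotalInfluence",
  representation(matrix = "matrix", r = "numeric", d = "numeric"))

setValidity("TotalInfluence", function(object) {
  if (any(object@matrix < -.TOL)) return("T must be nonnegative")
  if (abs(sum(object@r) - sum(object@d)) > 1e-6 * max(1, sum(object@r)))
    return("sum of r must equal sum of d")
  TRUE
})

#' DimensionMatrix: block means of the total-influence matrix
#'
#' Entry (i, j) is the arithmetic mean of all elements of T's block (i, j)
#' under the model's dimension partition (diagonal blocks include their
#' near-zero diagonal entries).
#'
#' @slot matrix numeric m x m, dimnames = dimension ids.
#' @export
setClass("DimensionMatrix", representation(matrix = "matrix"))

setValidity("DimensionMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (any(m < -.TOL)) return("entries must be nonnegative")
  TRUE
})

#' NormalizedDimensionMatrix: row-stochastic dimension matrix
#'
#' Each row of the dimension matrix divided by its row sum.
#'
#' @slot matrix numeric m x m with unit row sums.
#' @export
setClass("NormalizedDimensionMatrix", representation(matrix = "matrix"))

setValidity("NormalizedDimensionMatrix", function(object) {
  m <- object@matrix
  if (any(m < -.TOL) || any(m > 1 + .TOL))
    return("entries must lie in [0, 1]")
  if (any(abs(rowSums(m) - 1) > .TOL))
    return("every row must sum to 1")
  TRUE
})

#' Supermatrix: criterion-level influence transition matrix
#'
#' The unweighted supermatrix is the transpose of the blockwise
#' row-normalized total-influence matrix; after weighting by the normalized
#' dimension matrix it becomes column-stochastic and its limit powers carry
#' the influential weights.
#'
#' @slot matrix numeric n x n, nonnegative, dimnames = criterion ids.
#' @slot model the \linkS4class{DecisionModel} fixing the block partition.
#' @slot stochastic TRUE when every column sums to 1 (within 1e-9).
#' @slot zeroRows criterion ids whose within-block row sum was zero
#'   (left as zero rows and reported).
#' @export
setClass("Supermatrix",
  representation(matrix = "matrix", model = "DecisionModel",
                 stochastic = "logical", zeroRows = "character"))

setValidity("Supermatrix", function(object) {
  m <- object@matrix
  if (any(m < -.TOL)) return("entries must be nonnegative")
  if (isTRUE(object@stochastic) && any(abs(colSums(m) - 1) > .TOL))
    return("stochastic supermatrix must have unit column sums")
  TRUE
})

#' WeightVector: DANP influential weights with dimension rollups
#'
#' @slot weights named per-criterion weights, nonnegative, summing to 1.
#' @slot rollup named per-dimension sums of member weights.
#' @slot membership named character, criterion id -> dimension id.
#' @export
setClass("WeightVector",
  representation(weights = "numeric", rollup = "numeric",
                 membership = "character"))

setValidity("WeightVector", function(object) {
  w <- object@weights
  if (is.null(names(w))) return("weights must be named by criterion id")
  if (any(w < -.TOL)) return("weights must be nonnegative")
  if (abs(sum(w) - 1) > .TOL) return("weights must sum to 1")
  if (!setequal(names(object@membership), names(w)))
    return("membership must cover exactly the weighted criteria")
  roll <- tapply(w, object@membership[names(w)], sum)
  if (any(abs(object@rollup[names(roll)] - roll) > 1e-8))
    return("each dimension rollup must equal the sum of its members")
  TRUE
})

#' RiskScore: a patient's SAW risk level
#'
#' @slot patientId patient identifier.
#' @slot score the additive risk level (weighted sum of grades).
#' @slot contributions named per-criterion weight x grade terms.
#' @export
setClass("RiskScore",
  representation(patientId = "character", score = "numeric",
                 contributions = "numeric"))

setValidity("RiskScore", function(object) {
  if (abs(sum(object@contributions) - object@score) > 1e-8)
    return("score must equal the sum of its contributions")
  TRUE
})

#' GroupPolicy: experience-group weighting of an expert panel
#'
#' @slot groupWeights named nonnegative weights, one per experience group
#'   (normalized to sum 1 at aggregation time).
#' @slot membership named character, expert id -> group id.
#' @export
setClass("GroupPolicy",
  representation(groupWeights = "numeric", membership = "character"))

setValidity("GroupPolicy", function(object) {
  gw <- object@groupWeights
  if (is.null(names(gw))) return("group weights must be named")
  if (any(gw < 0)) return("group weights must be nonnegative")
  if (sum(gw) <= 0) return("at least one group must have positive weight")
  bad <- setdiff(unique(object@membership), names(gw))
  if (length(bad))
    return(sprintf("expert assigned to unknown group: %s",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' RiskRecordStore: append-only store of labelled risk scores
#'
#' Accumulates (patient, score, clinician label) records so that empirical
#' score ranges per label can be reported; no threshold is hard-coded.
#'
#' @slot records data.frame with columns patient_id, score, label, timestamp.
#' @slot path optional JSON-lines file mirroring the store (length 0 for
#'   in-memory only).
#' @export
setClass("RiskRecordStore",
  representation(records = "data.frame", path = "character"))

setValidity("RiskRecordStore", function(object) {
  need <- c("patient_id", "score", "label", "timestamp")
  if (!all(need %in% names(object@records)))
    return("records must have patient_id, score, label, timestamp")
  TRUE
})
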