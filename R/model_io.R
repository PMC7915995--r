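#' Construct a decision model
#'
#' @param dimensions data.frame with columns \code{id}, \code{label} (or a
#'   named character vector id -> label).
#' @param criteria data.frame with columns \code{id}, \code{label},
#'   \code{dimension}.
#' @return a validated \linkS4class{DecisionModel}; the given ordering is
#'   preserved as the canonical matrix order.
#' @examples
#' m <- decisionModel(
#'   dimensions = data.frame(id = "D1", label = "Only"),
#'   criteria = data.frame(id = c("C1", "C2"), label = c("a", "b"),
#'                         dimension = "D1"))
#' criterionIds(m)
#' @export
decisionModel <- function(dimensions, criteria) {
  if (is.character(dimensions))
    dimensions <- data.frame(id = names(dimensions), label = unname(dimensions),
                             stringsAsFactors = FALSE)
  dimensions <- as.data.frame(dimensions, stringsAsFactors = FALSE)
  criteria <- as.data.frame(criteria, stringsAsFactors = FALSE)
  if (is.null(criteria$label)) criteria$label <- criteria$id
  new("DecisionModel",
      dimensions = dimensions[, c("id", "label")],
      criteria = criteria[, c("id", "label", "dimension")])
}

#' Read / write a decision-model specification
#'
#' The on-disk form is JSON:
#' \preformatted{{"dimensions": [{"id": "D1", "label": "..."}, ...],
#'  "criteria":   [{"id": "C11", "label": "...", "dimension": "D1"}, ...]}}
#' File order is preserved as the canonical order.
#'
#' @param path JSON file path.
#' @param model a \linkS4class{DecisionModel} (for \code{writeModel}).
#' @return \code{loadModel}: a validated \linkS4class{DecisionModel}.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(spec$dimensions) || is.null(spec$criteria))
    stopf("model file must declare 'dimensions' and 'criteria': %s", path)
  decisionModel(spec$dimensions, spec$criteria)
}

#' @rdname loadModel
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "DecisionModel"))
  jsonlite::write_json(
    list(dimensions = model@dimensions, criteria = model@criteria),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Read an id-keyed square CSV matrix and re-map it to the model's canonical
# criterion order. The first column holds row ids; the header holds column
# ids. Errors name the offending criterion or cell.
readMatrixCSV <- function(path, model) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  ids <- criterionIds(model)
  missR <- setdiff(ids, rn)
  if (length(missR))
    stopf("%s: missing row(s) for criterion %s", path,
          paste(missR, collapse = ", "))
  missC <- setdiff(ids, colnames(df))
  if (length(missC))
    stopf("%s: missing column(s) for criterion %s", path,
          paste(missC, collapse = ", "))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))) &
                   !is.na(as.matrix(df)), arr.ind = TRUE)
    if (nrow(bad))
      stopf("%s: non-numeric cell at row '%s', column '%s'", path,
            rn[bad[1, 1]], colnames(df)[bad[1, 2]])
    m <- apply(df, 2, as.numeric)
  }
  rownames(m) <- rn
  m <- m[ids, ids, drop = FALSE]   # canonical re-mapping, file order ignored
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stopf("%s: missing or non-numeric cell (%s, %s)", path,
          ids[bad[1, 1]], ids[bad[1, 2]])
  }
  m
}

writeMatrixCSV <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an influence matrix against a model
#'
#' Checks shape, the 0--4 scale bounds and the zero diagonal, and re-maps
#' rows/columns to the model's canonical order when the matrix carries
#' dimnames. With \code{raw = TRUE} entries must be integers (a single
#' questionnaire); with \code{raw = FALSE} half-steps such as 2.50 are
#' legal (a panel aggregate).
#'
#' @param matrix square numeric matrix, optionally id-keyed via dimnames.
#' @param model a \linkS4class{DecisionModel}.
#' @param raw logical; TRUE for a single expert's questionnaire.
#' @return the validated matrix in canonical order, dimnames set.
#' @export
validateResponse <- function(matrix, model, raw = TRUE) {
  ids <- criterionIds(model)
  n <- length(ids)
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stopf("influence matrix must be square")
  if (nrow(matrix) != n)
    stopf("matrix size %d does not match the model's %d criteria",
          nrow(matrix), n)
  if (!is.null(rownames(matrix)) && !identical(rownames(matrix), ids)) {
    miss <- setdiff(ids, rownames(matrix))
    if (length(miss))
      stopf("missing row(s) for criterion %s", paste(miss, collapse = ", "))
    matrix <- matrix[ids, ids, drop = FALSE]
  }
  bad <- which(matrix < 0 | matrix > 4, arr.ind = TRUE)
  if (nrow(bad))
    stopf("entry out of [0, 4] at (%s, %s): %g", ids[bad[1, 1]],
          ids[bad[1, 2]], matrix[bad[1, 1], bad[1, 2]])
  nzd <- which(diag(matrix) != 0)
  if (length(nzd))
    stopf("nonzero diagonal at %s", ids[nzd[1]])
  if (raw && any(matrix != round(matrix))) {
    bad <- which(matrix != round(matrix), arr.ind = TRUE)
    stopf("raw responses must be integers in {0..4}; found %g at (%s, %s)",
          matrix[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], ids[bad[1, 2]])
  }
  dimnames(matrix) <- list(ids, ids)
  matrix
}

#' Read / write an expert panel
#'
#' Each questionnaire is a CSV matrix keyed by criterion ids (arbitrary
#' row/column order; re-mapped to the model's canonical order on load).
#'
#' @param paths character vector of CSV files, one per expert.
#' @param model a \linkS4class{DecisionModel}.
#' @param expertIds expert identifiers (default: file base names).
#' @param groups optional experience-group code per expert.
#' @param panel an \linkS4class{ExpertPanel} (for \code{writePanel}).
#' @param dir output directory (created if needed).
#' @return \code{loadPanel}: a validated \linkS4class{ExpertPanel};
#'   \code{writePanel}: the written file paths, invisibly.
#' @export
loadPanel <- function(paths, model, expertIds = NULL, groups = NULL) {
  if (is.null(expertIds))
    expertIds <- sub("\\.[^.]*$", "", basename(paths))
  if (is.null(groups)) groups <- rep(NA_character_, length(paths))
  responses <- mapply(function(p, e, g) {
    m <- validateResponse(readMatrixCSV(p, model), model, raw = TRUE)
    new("RawResponse", matrix = m, expertId = e, group = g)
  }, paths, expertIds, groups, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  new("ExpertPanel", model = model, responses = responses)
}

#' @rdname loadPanel
#' @export
writePanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(panel@responses, function(r) {
    p <- file.path(dir, paste0(r@expertId, ".csv"))
    writeMatrixCSV(r@matrix, p)
    p
  }, character(1))
  invisible(paths)
}

#' Construct an expert panel from in-memory matrices
#'
#' @param matrices list of square matrices on the raw 0--4 integer scale.
#' @param model a \linkS4class{DecisionModel}.
#' @param expertIds,groups per-expert metadata (defaults: E01, E02, ...;
#'   no group).
#' @return a validated \linkS4class{ExpertPanel}.
#' @export
expertPanel <- function(matrices, model, expertIds = NULL, groups = NULL) {
  k <- length(matrices)
  if (is.null(expertIds)) expertIds <- sprintf("E%02d", seq_len(k))
  if (is.null(groups)) groups <- rep(NA_character_, k)
  responses <- mapply(function(m, e, g) {
    m <- validateResponse(m, model, raw = TRUE)
    new("RawResponse", matrix = m, expertId = e, group = g)
  }, matrices, expertIds, groups, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  new("ExpertPanel", model = model, responses = responses)
}

#' Read / write an aggregate (initial average) matrix
#'
#' Aggregates may carry half-steps (e.g. 2.50 where an even panel's median
#' averages the two middle responses), so they are validated with
#' \code{raw = FALSE}.
#'
#' @param path CSV file keyed by criterion ids.
#' @param model a \linkS4class{DecisionModel}.
#' @param ai an \linkS4class{AggregateMatrix} (for \code{writeAggregate}).
#' @return \code{loadAggregate}: an \linkS4class{AggregateMatrix}.
#' @export
loadAggregate <- function(path, model) {
  m <- validateResponse(readMatrixCSV(path, model), model, raw = FALSE)
  new("AggregateMatrix", matrix = m, method = "file", nExperts = NA_real_)
}

#' @rdname loadAggregate
#' @export
writeAggregate <- function(ai, path) {
  writeMatrixCSV(as.matrix(ai), path)
}

#' Read / write patient grade tables
#'
#' One row per patient: a \code{patient_id} column plus one column per
#' criterion, grades in [1, 10] (1 = low risk, 10 = high risk).
#'
#' @param path CSV file.
#' @param model a \linkS4class{DecisionModel}.
#' @param patients a patient grade data.frame (for \code{writePatients}).
#' @return \code{loadPatients}: a validated data.frame with
#'   \code{patient_id} first and criterion columns in canonical order.
#' @export
loadPatients <- function(path, model) {
  if (!file.exists(path)) stopf("patient file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validatePatients(df, model)
}

#' @rdname loadPatients
#' @export
writePatients <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname loadPatients
#' @param df in-memory patient grades to validate.
#' @export
validatePatients <- function(df, model) {
  ids <- criterionIds(model)
  if (!"patient_id" %in% names(df))
    stopf("patient table must have a 'patient_id' column")
  miss <- setdiff(ids, names(df))
  if (length(miss))
    stopf("patient table missing criterion column(s): %s",
          paste(miss, collapse = ", "))
  if (nrow(df)) {
    g <- as.matrix(df[, ids, drop = FALSE])
    if (!is.numeric(g)) stopf("patient grades must be numeric")
    bad <- which(g < 1 | g > 10 | is.na(g), arr.ind = TRUE)
    if (nrow(bad))
      stopf("grade out of [1, 10] for patient '%s', criterion %s",
            df$patient_id[bad[1, 1]], ids[bad[1, 2]])
  }
  df[, c("patient_id", ids), drop = FALSE]
}

#' Construct or read a group-weighting policy
#'
#' A policy assigns each expert to an experience group and each group a
#' nonnegative weight (e.g. senior 50%, mid 30%, junior 20%); weights are
#' renormalized to sum 1 when applied. JSON form:
#' \preformatted{{"groups": {"G1": 0.5, "G2": 0.3, "G3": 0.2},
#'  "membership": {"E01": "G1", ...}}}
#'
#' @param groupWeights named nonnegative weights per group.
#' @param membership named character vector, expert id -> group id.
#' @param path JSON file (for \code{loadPolicy}/\code{writePolicy}).
#' @param policy a \linkS4class{GroupPolicy}.
#' @return a validated \linkS4class{GroupPolicy}.
#' @export
groupPolicy <- function(groupWeights, membership = character()) {
  new("GroupPolicy", groupWeights = groupWeights,
      membership = membership)
}

#' @rdname groupPolicy
#' @export
loadPolicy <- function(path) {
  if (!file.exists(path)) stopf("policy file not found: %s", path)
  spec <- jsonlite::fromJSON(path)
  groupPolicy(unlist(spec$groups), unlist(spec$membership))
}

#' @rdname groupPolicy
#' @export
writePolicy <- function(policy, path) {
  jsonlite::write_json(
    list(groups = as.list(policy@groupWeights),
         membership = as.list(policy@membership)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
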