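#' Aggregate an expert panel into the initial average matrix
#'
#' The default aggregation is the elementwise median, which resists outlier
#' opinions; with an even panel the two middle responses are averaged, which
#' is how half-steps such as 2.50 arise on an integer questionnaire scale.
#' The arithmetic mean (optionally expert-weighted) is also available.
#'
#' @param panel an \linkS4class{ExpertPanel}.
#' @param method "median" (default) or "mean".
#' @param expertWeights optional nonnegative weights, one per expert, used
#'   only with \code{method = "mean"}.
#' @return an \linkS4class{AggregateMatrix}.
#' @export
aggregatePanel <- function(panel, method = c("median", "mean"),
                           expertWeights = NULL) {
  method <- match.arg(method)
  mats <- lapply(panel@responses, as.matrix)
  k <- length(mats)
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), k))
  if (!is.null(expertWeights)) {
    if (method != "mean")
      stopf("expert weights apply only to method = \"mean\"")
    if (length(expertWeights) != k)
      stopf("expected %d expert weights, got %d", k, length(expertWeights))
    if (any(expertWeights < 0) || sum(expertWeights) == 0)
      stopf("expert weights must be nonnegative and not all zero")
    w <- expertWeights / sum(expertWeights)
    m <- apply(arr, c(1, 2), function(v) sum(v * w))
  } else if (method == "median") {
    m <- apply(arr, c(1, 2), stats::median)
  } else {
    m <- apply(arr, c(1, 2), mean)
  }
  dimnames(m) <- dimnames(mats[[1]])
  new("AggregateMatrix", matrix = m, method = method, nExperts = k)
}

#' Consensus confidence of a panel's running mean
#'
#' Measures how much the panel's elementwise mean moved when the last
#' questionnaire arrived: with A(k) the mean of the first k responses, the
#' gap is the average over off-diagonal cells of
#' |A(k)_ij - A(k-1)_ij| / A(k)_ij, in percent; cells where A(k)_ij = 0 are
#' skipped and the divisor reduced accordingly. The returned confidence is
#' 100 minus that gap; above 95 the panel is conventionally deemed stable
#' enough that one more questionnaire would barely change the aggregate.
#'
#' @param panel an \linkS4class{ExpertPanel} with at least two experts.
#' @param order optional permutation of expert positions; the gap is
#'   evaluated at k = panel size under this ordering (default entry order).
#' @return confidence in percent (at most 100).
#' @export
consensusConfidence <- function(panel, order = NULL) {
  k <- length(panel@responses)
  if (k < 2L) stopf("consensus requires at least two experts")
  if (is.null(order)) order <- seq_len(k)
  if (!setequal(order, seq_len(k)))
    stopf("'order' must be a permutation of 1..%d", k)
  mats <- lapply(panel@responses[order], as.matrix)
  acc <- Reduce(`+`, mats)
  ak <- acc / k
  ak1 <- (acc - mats[[k]]) / (k - 1)
  off <- row(ak) != col(ak)
  use <- off & ak != 0
  gap <- mean(abs(ak[use] - ak1[use]) / ak[use]) * 100
  100 - gap
}

#' Normalize the initial average matrix
#'
#' Divides AI by s = max(largest row sum, largest column sum), the standard
#' DEMATEL scaling that bounds both row and column sums of N by 1 so the
#' influence series N + N^2 + ... converges. A zero-diagonal matrix can
#' still be degenerate (e.g. a 2 x 2 with both off-diagonal cells positive
#' reaches spectral radius 1); such inputs are rejected.
#'
#' @param ai an \linkS4class{AggregateMatrix} (or plain matrix on the 0--4
#'   scale with zero diagonal).
#' @return a \linkS4class{NormalizedMatrix} with the divisor recorded.
#' @export
normalizeInfluence <- function(ai) {
  m <- if (is(ai, "AggregateMatrix")) as.matrix(ai) else ai
  if (all(m == 0)) stopf("cannot normalize an all-zero matrix")
  s <- max(max(rowSums(m)), max(colSums(m)))
  n <- m / s
  if (spectralRadius(n) >= 1 - 1e-10)
    stopf(paste("normalized matrix has spectral radius >= 1;",
                "the influence series does not converge"))
  new("NormalizedMatrix", matrix = n, scaleDivisor = s)
}

#' Total-influence matrix T = N (I - N)^-1
#'
#' Sums the full chain of direct and indirect influence
#' N + N^2 + N^3 + ... in closed form. Row sums r give the influence each
#' criterion exerts; column sums d the influence it receives.
#'
#' @param norm a \linkS4class{NormalizedMatrix}.
#' @return a \linkS4class{TotalInfluence}.
#' @export
totalInfluence <- function(norm) {
  n <- as.matrix(norm)
  if (spectralRadius(n) >= 1 - 1e-10)
    stopf(paste("normalized matrix has spectral radius >= 1;",
                "the influence series does not converge"))
  eye <- diag(nrow(n))
  tm <- tryCatch(n %*% solve(eye - n),
                 error = function(e) stopf("(I - N) is singular: %s",
                                           conditionMessage(e)))
  # tiny negative round-off can appear at machine precision
  tm[tm < 0 & tm > -1e-12] <- 0
  new("TotalInfluence", matrix = tm, r = rowSums(tm), d = colSums(tm))
}

.prominence <- function(r, d, ids) {
  data.frame(id = ids, r = r, d = d,
             r_plus_d = r + d, r_minus_d = r - d,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Prominence and net relation per criterion
#'
#' For each criterion: r (influence given), d (influence received), the
#' prominence r + d (total involvement) and the net relation r - d
#' (positive = net cause, negative = net effect). Values are full
#' precision; set \code{digits} to get the 2-decimal presentation used in
#' published tables (round half away from zero).
#'
#' @param t a \linkS4class{TotalInfluence}.
#' @param digits optional presentation rounding.
#' @return data.frame with columns id, r, d, r_plus_d, r_minus_d.
#' @export
prominenceRelation <- function(t, digits = NULL) {
  ids <- rownames(as.matrix(t))
  if (is.null(ids)) ids <- sprintf("C%d", seq_along(t@r))
  out <- .prominence(t@r, t@d, ids)
  if (!is.null(digits)) out[-1] <- lapply(out[-1], roundHalfUp, digits)
  out
}

#' Dimension matrix: block means of T
#'
#' Partitions T by the model's dimensions and averages every block,
#' including the near-zero diagonal entries of diagonal blocks, yielding
#' the m x m dimension-level influence matrix.
#'
#' @param t a \linkS4class{TotalInfluence}.
#' @param model the \linkS4class{DecisionModel} fixing the partition.
#' @return a \linkS4class{DimensionMatrix}.
#' @export
dimensionMatrix <- function(t, model) {
  tm <- as.matrix(t)
  if (nrow(tm) != nCriteria(model))
    stopf("matrix size %d does not match the model's %d criteria",
          nrow(tm), nCriteria(model))
  part <- criterionPartition(model)
  m <- length(part)
  td <- matrix(0, m, m, dimnames = list(names(part), names(part)))
  for (i in seq_len(m))
    for (j in seq_len(m))
      td[i, j] <- mean(tm[part[[i]], part[[j]]])
  new("DimensionMatrix", matrix = td)
}

#' Prominence and net relation per dimension
#'
#' @param td a \linkS4class{DimensionMatrix}.
#' @param digits optional presentation rounding.
#' @return data.frame with columns id, r, d, r_plus_d, r_minus_d.
#' @export
dimensionProminence <- function(td, digits = NULL) {
  m <- as.matrix(td)
  out <- .prominence(rowSums(m), colSums(m), rownames(m))
  if (!is.null(digits)) out[-1] <- lapply(out[-1], roundHalfUp, digits)
  out
}

#' Influence-network (INRM) edge extraction
#'
#' Keeps the directed edges i -> j (i != j) whose total influence reaches a
#' threshold, for drawing the influence network relation map. No canonical
#' threshold exists; the default is the mean off-diagonal entry of the
#' analyzed matrix, recorded on the result as attribute \code{"threshold"}.
#'
#' @param x a \linkS4class{TotalInfluence} (criterion level) or
#'   \linkS4class{DimensionMatrix} (dimension level).
#' @param threshold nonnegative cutoff; default mean off-diagonal entry.
#' @return data.frame (source, target, strength, level), sorted by
#'   descending strength, with attribute \code{threshold}.
#' @export
inrmEdges <- function(x, threshold = NULL) {
  level <- if (is(x, "DimensionMatrix")) "dimension" else "criterion"
  m <- as.matrix(x)
  if (is.null(rownames(m)))
    dimnames(m) <- rep(list(sprintf("V%d", seq_len(nrow(m)))), 2)
  off <- row(m) != col(m)
  if (is.null(threshold))
    threshold <- if (any(off)) mean(m[off]) else 0
  if (threshold < 0) stopf("threshold must be nonnegative")
  keep <- which(off & m >= threshold, arr.ind = TRUE)
  edges <- data.frame(source = rownames(m)[keep[, 1]],
                      target = colnames(m)[keep[, 2]],
                      strength = m[keep],
                      level = rep(level, nrow(keep)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$strength, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "threshold") <- threshold
  edges
}

#' Export INRM edges for graph tools
#'
#' \code{writeInrmDot} writes Graphviz DOT; \code{writeInrmGraphML} writes
#' GraphML (via igraph) with a \code{strength} edge attribute.
#'
#' @param edges data.frame from \code{\link{inrmEdges}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeInrmDot <- function(edges, path) {
  lines <- c("digraph INRM {",
             sprintf("  \"%s\" -> \"%s\" [strength=%.6f];",
                     edges$source, edges$target, edges$strength),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeInrmDot
#' @export
writeInrmGraphML <- function(edges, path) {
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "strength")], directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
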