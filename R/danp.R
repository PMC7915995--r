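#' Unweighted supermatrix from the total-influence matrix
#'
#' Each block of T (criteria of one dimension against criteria of another)
#' is row-normalized — every row divided by its within-block sum, so a
#' criterion's influence is expressed as proportions within each target
#' dimension — and the blockwise-normalized matrix is transposed. Columns
#' of the result sum to the number of dimensions contributing nonzero
#' blocks; the weighted step restores column-stochasticity. Rows whose
#' within-block sum is zero are left as zero rows and recorded in
#' \code{zeroRows}.
#'
#' @param t a \linkS4class{TotalInfluence}.
#' @param model the \linkS4class{DecisionModel} fixing the block partition.
#' @return an (unweighted) \linkS4class{Supermatrix}.
#' @export
unweightedSupermatrix <- function(t, model) {
  tm <- as.matrix(t)
  ids <- criterionIds(model)
  if (nrow(tm) != length(ids))
    stopf("matrix size %d does not match the model's %d criteria",
          nrow(tm), length(ids))
  dimnames(tm) <- list(ids, ids)
  part <- criterionPartition(model)
  norm <- tm
  zero <- character()
  for (i in seq_along(part)) {
    for (j in seq_along(part)) {
      blk <- tm[part[[i]], part[[j]], drop = FALSE]
      rs <- rowSums(blk)
      z <- rs == 0
      if (any(z)) {
        zero <- union(zero, rownames(blk)[z])
        rs[z] <- 1  # keep the zero row as-is
      }
      norm[part[[i]], part[[j]]] <- blk / rs
    }
  }
  w <- t(norm)
  stoch <- all(abs(colSums(w) - 1) <= 1e-9)
  if (length(zero))
    warning(sprintf("zero within-block row sum for: %s",
                    paste(zero, collapse = ", ")), call. = FALSE)
  new("Supermatrix", matrix = w, model = model, stochastic = stoch,
      zeroRows = zero)
}

#' Row-normalize the dimension matrix
#'
#' Divides each row of the dimension matrix by its row sum, giving the
#' row-stochastic matrix that weights the supermatrix blocks.
#'
#' @param td a \linkS4class{DimensionMatrix} with positive row sums.
#' @return a \linkS4class{NormalizedDimensionMatrix}.
#' @export
normalizeDimensionMatrix <- function(td) {
  m <- as.matrix(td)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    bad <- rownames(m)[which(rs <= 0)[1]]
    stopf("dimension matrix row '%s' has nonpositive sum", bad)
  }
  new("NormalizedDimensionMatrix", matrix = m / rs)
}

#' Weight the supermatrix by the normalized dimension matrix
#'
#' Scales block (i, j) of the unweighted supermatrix W by the (j, i) entry
#' of the normalized dimension matrix (W is a transpose, so the scalar for
#' its block (i, j) comes from the transposed position), making every
#' column sum to 1. Columns short of 1 because of zero rows upstream are
#' renormalized, with a warning naming them.
#'
#' @param tdn a \linkS4class{NormalizedDimensionMatrix}.
#' @param w the unweighted \linkS4class{Supermatrix}.
#' @param model optional \linkS4class{DecisionModel}; default \code{w}'s.
#' @return a column-stochastic \linkS4class{Supermatrix}.
#' @export
weightedSupermatrix <- function(tdn, w, model = NULL) {
  if (is.null(model)) model <- w@model
  part <- criterionPartition(model)
  tn <- as.matrix(tdn)
  if (nrow(tn) != length(part))
    stopf("dimension matrix is %d x %d but the model has %d dimensions",
          nrow(tn), ncol(tn), length(part))
  wm <- as.matrix(w)
  for (i in seq_along(part))
    for (j in seq_along(part))
      wm[part[[i]], part[[j]]] <-
        tn[j, i] * wm[part[[i]], part[[j]], drop = FALSE]
  cs <- colSums(wm)
  if (any(cs <= 0)) {
    bad <- colnames(wm)[which(cs <= 0)[1]]
    stopf("column '%s' of the weighted supermatrix is all zero", bad)
  }
  offUnit <- abs(cs - 1) > 1e-9
  if (any(offUnit)) {
    warning(sprintf("renormalizing %d column(s) not summing to 1: %s",
                    sum(offUnit),
                    paste(colnames(wm)[offUnit], collapse = ", ")),
            call. = FALSE)
    wm <- sweep(wm, 2, cs, "/")
  }
  new("Supermatrix", matrix = wm, model = model, stochastic = TRUE,
      zeroRows = w@zeroRows)
}

#' Limit of the weighted supermatrix: DANP influential weights
#'
#' Raises the column-stochastic supermatrix to increasing powers (by
#' repeated squaring, renormalizing columns against floating-point drift)
#' until successive powers agree elementwise within \code{tol}. At the
#' limit all columns coincide and carry the steady-state influential
#' weights. If the chain is 2-periodic the even-power limit alternates
#' with its one-step image; the two are then averaged (Cesaro limit).
#'
#' @param wadj a column-stochastic \linkS4class{Supermatrix}.
#' @param tol elementwise convergence tolerance (default 1e-9).
#' @param maxIter maximum number of squarings (default 10000).
#' @return a \linkS4class{WeightVector} with per-dimension rollups.
#' @export
limitSupermatrix <- function(wadj, tol = 1e-9, maxIter = 10000) {
  if (!isTRUE(wadj@stochastic))
    stopf("limit requires a column-stochastic supermatrix")
  w0 <- as.matrix(wadj)
  m <- w0
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    m2 <- m %*% m
    m2 <- sweep(m2, 2, colSums(m2), "/")
    if (max(abs(m2 - m)) < tol) { m <- m2; converged <- TRUE; break }
    m <- m2
  }
  if (!converged)
    stopf("supermatrix powers did not converge after %d squarings", maxIter)
  step <- w0 %*% m
  if (max(abs(step - m)) > sqrt(tol)) m <- (m + step) / 2  # period-2 cycle
  weights <- rowMeans(m)
  weights <- weights / sum(weights)
  names(weights) <- rownames(w0)
  member <- dimensionOf(wadj@model)
  rollup <- vapply(split(weights, factor(member[names(weights)],
                                         levels = dimensionIds(wadj@model))),
                   sum, numeric(1))
  new("WeightVector", weights = weights, rollup = rollup,
      membership = member)
}

#' End-to-end DANP influential weights from an aggregate matrix
#'
#' Convenience composition: normalize the initial average matrix, compute
#' the total-influence matrix, block-average it into the dimension matrix,
#' row-normalize that, build and weight the supermatrix, and take its
#' limit.
#'
#' @param ai an \linkS4class{AggregateMatrix} (or plain matrix).
#' @param model the \linkS4class{DecisionModel}.
#' @return a \linkS4class{WeightVector}.
#' @examples
#' wv <- danpWeights(akiAggregate(), akiModel())
#' round(100 * sort(criterionWeights(wv), decreasing = TRUE)[1:2], 2)
#' @export
danpWeights <- function(ai, model) {
  norm <- normalizeInfluence(ai)
  t <- totalInfluence(norm)
  td <- dimensionMatrix(t, model)
  tdn <- normalizeDimensionMatrix(td)
  w <- unweightedSupermatrix(t, model)
  wadj <- weightedSupermatrix(tdn, w, model)
  limitSupermatrix(wadj)
}
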