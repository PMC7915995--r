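# Small models and independent oracles used across test files.

oneDimModel <- function(n = 4) {
  ids <- sprintf("C%d", seq_len(n))
  decisionModel(
    dimensions = data.frame(id = "D1", label = "Only"),
    criteria = data.frame(id = ids, label = ids, dimension = "D1"))
}

twoDimModel <- function() {
  decisionModel(
    dimensions = data.frame(id = c("D1", "D2"), label = c("a", "b")),
    criteria = data.frame(id = c("C1", "C2", "C3", "C4"),
                          label = c("C1", "C2", "C3", "C4"),
                          dimension = c("D1", "D1", "D2", "D2")))
}

# constant-off-diagonal raw matrix on a model
constMatrix <- function(model, value = 2) {
  n <- nCriteria(model)
  m <- matrix(value, n, n, dimnames = list(criterionIds(model),
                                           criterionIds(model)))
  diag(m) <- 0
  m
}

# truncated Neumann series: independent oracle for T = N (I - N)^-1
seriesTotalInfluence <- function(N, w = 200) {
  acc <- matrix(0, nrow(N), ncol(N))
  p <- diag(nrow(N))
  for (i in seq_len(w)) {
    p <- p %*% N
    acc <- acc + p
  }
  acc
}

# stationary distribution of a column-stochastic matrix: eigen oracle
eigenStationary <- function(P) {
  e <- eigen(P)
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sum(v)
}

# random column-stochastic matrix with strictly positive entries
randomStochastic <- function(n) {
  m <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  sweep(m, 2, colSums(m), "/")
}

# constant off-diagonal matrices normalize to spectral radius exactly 1
# (every row and column sum equals the divisor), so the influence series
# diverges; perturbing one cell restores convergence for pipeline tests
pertMatrix <- function(model, value = 2) {
  m <- constMatrix(model, value)
  m[1, 2] <- value - 1
  m
}
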