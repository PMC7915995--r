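#' Round half away from zero
#'
#' Presentation rounding used in all reports: ties go away from zero
#' (2.675 -> 2.68, -0.045 -> -0.05), unlike base \code{round}'s banker's
#' rounding. Internal computation is never rounded; this is applied only
#' when printing or writing report tables.
#'
#' @param x numeric.
#' @param digits number of decimal places (default 2).
#' @return rounded numeric of the same shape.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-9 relative nudge guards values stored a hair below .5 in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Spectral radius (largest eigenvalue modulus).
spectralRadius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
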