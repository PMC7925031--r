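#' @keywords internal
"_PACKAGE"

## Small numeric helpers shared across layers. All activations are exact
## (no table lookups); softmax uses max-subtraction for stability.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Numerically stable softmax over the rows of a matrix
#'
#' Subtracts the row maximum before exponentiating; mathematically identical
#' to the plain definition.
#'
#' @param x numeric matrix (rows are independent score vectors) or a vector.
#' @return matrix (or vector) of the same shape with non-negative rows
#'   summing to 1.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) {
    z <- exp(x - max(x))
    return(z / sum(z))
  }
  z <- exp(x - apply(x, 1L, max))
  z / rowSums(z)
}

## Glorot/Xavier uniform initialization for a fan_out x fan_in matrix.
glorot <- function(nrow, ncol) {
  r <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}

stop_dclstm <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_dclstm("non-finite values in %s", what)
  invisible(x)
}

## Derive a per-use 31-bit sub-seed from a base seed, stays < 2^31.
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}
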