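#' @keywords internal
"_PACKAGE"

# log floor used wherever a probability enters a logarithm
.LOG_EPS <- 1e-30

#' Row-wise softmax with max subtraction
#'
#' Numerically stable softmax applied to each row of a matrix (or to a single
#' vector). Subtracting the row maximum before exponentiating keeps the
#' computation finite for large scores.
#'
#' @param x numeric matrix (rows are transformed independently) or vector.
#' @return matrix (or vector) of the same shape; rows are probability
#'   simplices summing to 1.
#' @examples
#' softmax_rows(c(0, 0, 0))          # uniform 1/3
#' softmax_rows(rbind(c(1, 2), c(0, 0)))
#' @export
softmax_rows <- function(x) {
  if (is.null(dim(x))) {
    z <- exp(x - max(x))
    return(z / sum(z))
  }
  m <- apply(x, 1L, max)
  z <- exp(x - m)
  z / rowSums(z)
}

# column standardization to mean 0 / sd 1; zero-variance columns -> all zeros
.standardize_cols <- function(x) {
  mu <- colMeans(x)
  sd <- sqrt(colMeans(x^2) - mu^2)
  keep <- sd > 0
  out <- sweep(x, 2L, mu, "-")
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2L, sd[keep], "/")
  out[, !keep] <- 0
  attr(out, "n_zero_variance") <- sum(!keep)
  out
}

# derive a per-purpose sub-seed from a master seed, kept below 2^31
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
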