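# Internal numeric helpers shared across the network code.
#
# Convention: "batched" 3-D arrays have the batch index LAST, i.e. dim (m, k, B),
# so that dim<- reshapes between matrix and batch views without copying order.

# Batched matrix multiply: A (m, k, B) x B (k, n, B) -> (m, n, B).
# Thin wrapper over the compiled slice-wise product.
#' @useDynLib stgate, .registration = TRUE
#' @importFrom Rcpp evalCpp
bmm <- function(A, B) {
  da <- dim(A); db <- dim(B)
  stopifnot(length(da) == 3L, length(db) == 3L, da[2] == db[1], da[3] == db[3])
  bmm_cpp(A, B)
}

# Batched transpose: (m, n, B) -> (n, m, B)
btrans <- function(A) aperm(A, c(2L, 1L, 3L))

# Row-wise softmax of a matrix, numerically stabilized.
softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  E <- exp(X - m)
  E / rowSums(E)
}

# Stable log-sum-exp over rows.
logsumexp_rows <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dy) dy * (x > 0)

elu_fwd <- function(x, alpha = 1) ifelse(x > 0, x, alpha * (exp(x) - 1))
elu_bwd <- function(x, dy, alpha = 1) dy * ifelse(x > 0, 1, alpha * exp(x))

leaky_relu_fwd <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leaky_relu_bwd <- function(x, dy, slope = 0.2) dy * ifelse(x > 0, 1, slope)

tanh_bwd <- function(y, dy) dy * (1 - y^2)

# Glorot-uniform init for a matrix of given fan-in/fan-out.
glorot <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_config("non-finite values in %s", what)
  invisible(TRUE)
}
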