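#' k-nearest-neighbour electrode graph
#'
#' Builds the initial binary adjacency from 2-D electrode positions: each node
#' is linked to its k nearest neighbours by Euclidean distance (ties broken by
#' lower index), then the directed graph is symmetrized by edge union, since
#' the multichannel signal is modelled as an undirected graph. No self-loops
#' are stored; the attention layer adds them.
#'
#' @param coords N x 2 matrix of electrode positions.
#' @param k Number of neighbours, `1 <= k <= N - 1`.
#' @return N x N binary symmetric adjacency matrix.
#' @export
knn_graph <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1L || k >= n) stop_config("k must satisfy 1 <= k <= N - 1 (k=%d, N=%d)", k, n)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]  # order() is stable: ties keep lower index
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))  # edge union
  dimnames(A) <- list(rownames(coords), rownames(coords))
  A
}

#' Mini-batch standardization of attention scores
#'
#' Standardizes a batch of score matrices to zero mean and unit population
#' variance over all entries, `(S - mean) / sqrt(var + eps)` — the batch
#' normalization step applied to the dynamic adjacency before Top-K
#' sparsification. This is the pure functional form; inside the network a
#' learnable affine rescale and running statistics are layered on top.
#'
#' @param S Array `B x N x N` (or any numeric array/matrix).
#' @param eps Variance guard (default 1e-5).
#' @param return_stats Also return the mean/variance used.
#' @return Standardized array of the same shape (list with `out`, `mean`,
#'   `var` when `return_stats = TRUE`).
#' @export
batch_standardize <- function(S, eps = 1e-5, return_stats = FALSE) {
  check_finite(S, "scores")
  mu <- mean(S)
  v <- mean((S - mu)^2)  # population variance
  out <- (S - mu) / sqrt(v + eps)
  if (return_stats) list(out = out, mean = mu, var = v) else out
}

#' Row-wise Top-K sparsification
#'
#' Keeps, in every row, the k largest entries at their original values and
#' zeroes the rest; rows with at most k entries are unchanged. Ties are broken
#' stably in favour of the lower column index. Applied per destination node,
#' so the result may be asymmetric.
#'
#' @param A N x N matrix or B x N x N array.
#' @param k Number of entries to keep per row (default 10).
#' @return Same shape as `A`, row-sparse.
#' @export
topk_sparsify <- function(A, k = 10L) {
  if (k < 1L) stop_config("k must be >= 1")
  if (is.matrix(A)) return(topk_rows(A, k))
  stopifnot(length(dim(A)) == 3L)
  out <- A
  for (b in seq_len(dim(A)[1])) out[b, , ] <- topk_rows(A[b, , ], k)
  out
}

topk_rows <- function(M, k) {
  n <- ncol(M)
  if (k >= n) return(M)
  out <- matrix(0, nrow(M), n)
  for (i in seq_len(nrow(M))) {
    keep <- order(M[i, ], decreasing = TRUE)[seq_len(k)]  # stable: ties keep lower index
    out[i, keep] <- M[i, keep]
  }
  dimnames(out) <- dimnames(M)
  out
}
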