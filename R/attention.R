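# Spatial attention, temporal attention, graph attention and the full
# network forward/backward. Array layout inside the network:
#   X_h : B x N x C x T_r ("bnct")

# Batch-normalization with learnable scalar affine and running statistics,
# wrapping the pure batch_standardize() rule.
bn_fwd <- function(S, gamma, beta, run_mean, run_var, train, eps = 1e-5, momentum = 0.1) {
  if (train) {
    mu <- mean(S); v <- mean((S - mu)^2)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (S - mu) * inv
  list(out = gamma * xhat + beta, xhat = xhat, inv = inv, train = train,
       run_mean = new_mean, run_var = new_var)
}

bn_bwd <- function(cache, gamma, dY) {
  dgamma <- sum(dY * cache$xhat)
  dbeta <- sum(dY)
  dxhat <- dY * gamma
  if (cache$train) {
    dx <- cache$inv * (dxhat - mean(dxhat) - cache$xhat * mean(dxhat * cache$xhat))
  } else {
    dx <- dxhat * cache$inv
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- spatial attention: S = V tanh(W1 X W2 + b_s), standardize, Top-K ------
# W1 contracts the encoded tensor over time (B,N,C), W2 projects channels to
# nodes (B,N,N); after bias, tanh and left-multiplication by V the scores
# are standardized over the mini-batch and row-wise Top-K sparsified.

spatial_attention_fwd <- function(Xh, p, k_top, state, train) {
  d <- dim(Xh); B <- d[1]; N <- d[2]; C <- d[3]; Tr <- d[4]
  if (length(p$sa_W1) != Tr) stop_config("spatial attention W1 length %d != T_r %d", length(p$sa_W1), Tr)
  if (!all(dim(p$sa_W2) == c(C, N))) stop_config("spatial attention W2 must be C x N")
  Xm <- Xh; dim(Xm) <- c(B * N * C, Tr)
  M1 <- as.vector(Xm %*% p$sa_W1)              # (B*N*C)
  M1m <- M1; dim(M1m) <- c(B * N, C)
  M2 <- M1m %*% p$sa_W2                        # (B*N, N)
  pre <- array(M2, c(B, N, N)) + rep(p$sa_bs, each = B)
  Z <- tanh(pre)
  Zm <- aperm(Z, c(2L, 1L, 3L)); dim(Zm) <- c(N, B * N)
  Sm <- p$sa_V %*% Zm                          # (N_i, B*N_j)
  Sarr <- array(Sm, c(N, B, N)); Sarr <- aperm(Sarr, c(2L, 1L, 3L))  # (B, N, N)
  bn <- bn_fwd(Sarr, p$sa_bn_g, p$sa_bn_b, state$sa_mean, state$sa_var, train)
  A <- topk_sparsify(bn$out, k_top)
  keep <- A != 0
  list(A = A, A_pre_topk = bn$out, keep = keep,
       cache = list(Xm = Xm, M1m = M1m, Z = Z, Zm = Zm, bn = bn, dims = d),
       state = list(sa_mean = bn$run_mean, sa_var = bn$run_var))
}

spatial_attention_bwd <- function(fw, p, dA) {
  d <- fw$cache$dims; B <- d[1]; N <- d[2]; C <- d[3]; Tr <- d[4]
  dbn_out <- dA * fw$keep                      # Top-K: gradient only on kept entries
  g_bn <- bn_bwd(fw$cache$bn, p$sa_bn_g, dbn_out)
  dS <- g_bn$dx                                # (B, N, N)
  dSm <- aperm(dS, c(2L, 1L, 3L)); dim(dSm) <- c(N, B * N)
  dV <- dSm %*% t(fw$cache$Zm)
  dZm <- t(p$sa_V) %*% dSm                     # (N_m, B*N_j)
  dZ <- array(dZm, c(N, B, N)); dZ <- aperm(dZ, c(2L, 1L, 3L))
  dpre <- dZ * (1 - fw$cache$Z^2)
  dbs <- colSums(matrix(dpre, B, N * N)); dim(dbs) <- c(N, N)
  dM2 <- dpre; dim(dM2) <- c(B * N, N)
  dW2 <- crossprod(fw$cache$M1m, dM2)
  dM1 <- dM2 %*% t(p$sa_W2)                    # (B*N, C)
  dM1v <- as.vector(dM1)
  dW1 <- as.vector(crossprod(fw$cache$Xm, dM1v))
  dXm <- dM1v %o% p$sa_W1                      # (B*N*C, Tr)
  dXh <- array(dXm, d)
  list(dXh = dXh,
       grads = list(sa_W1 = dW1, sa_W2 = dW2, sa_bs = dbs, sa_V = dV,
                    sa_bn_g = g_bn$dgamma, sa_bn_b = g_bn$dbeta))
}

#' Spatial attention: dynamic adjacency from encoded features
#'
#' Builds the per-sample score matrix `S = V tanh(W1 X W2 + b_s)`: the
#' encoded tensor is contracted over time with `W1`, projected from
#' channels to nodes with `W2`, biased, passed through tanh and
#' left-multiplied by `V`. Scores are standardized over the mini-batch and
#' sparsified to the Top-K entries of every row.
#'
#' @param Xh Array `B x N x C x T_r`.
#' @param params Parameter list with `sa_W1` (length T_r), `sa_W2` (C x N),
#'   `sa_bs`, `sa_V` (N x N) and the affine `sa_bn_g`, `sa_bn_b`.
#' @param k_top Entries kept per row (default 10).
#' @param train Use mini-batch statistics (`TRUE`) or running statistics.
#' @param state Running-statistics list (`sa_mean`, `sa_var`).
#' @return List with `A` (`B x N x N` sparsified adjacency), `A_pre_topk`
#'   (standardized scores before Top-K) and updated `state`.
#' @export
spatial_attention <- function(Xh, params, k_top = 10L, train = TRUE,
                              state = list(sa_mean = 0, sa_var = 1)) {
  fw <- spatial_attention_fwd(Xh, params, k_top, state, train)
  list(A = fw$A, A_pre_topk = fw$A_pre_topk, state = fw$state)
}

# ---- temporal attention ----------------------------------------------------

# Temporal attention mirrors the spatial construction on the transposed
# tensor (B,T,C,N): U3 contracts nodes, U4 projects channels to time,
# yielding a T_r x T_r map, then bias, tanh, V and standardization.
temporal_attention_fwd <- function(Xh, p, state, train) {
  d <- dim(Xh); B <- d[1]; N <- d[2]; C <- d[3]; Tr <- d[4]
  if (length(p$ta_U3) != N) stop_config("temporal attention U3 length %d != N %d", length(p$ta_U3), N)
  if (!all(dim(p$ta_U4) == c(C, Tr))) stop_config("temporal attention U4 must be C x T_r")
  Y <- aperm(Xh, c(1L, 4L, 3L, 2L))            # (B, T, C, N)
  Ym <- Y; dim(Ym) <- c(B * Tr * C, N)
  M1 <- as.vector(Ym %*% p$ta_U3)
  M1m <- M1; dim(M1m) <- c(B * Tr, C)
  M2 <- M1m %*% p$ta_U4                        # (B*T, T)
  pre <- array(M2, c(B, Tr, Tr)) + rep(p$ta_bt, each = B)
  Z <- tanh(pre)
  Zm <- aperm(Z, c(2L, 1L, 3L)); dim(Zm) <- c(Tr, B * Tr)
  Tm <- p$ta_V %*% Zm
  Tarr <- array(Tm, c(Tr, B, Tr)); Tarr <- aperm(Tarr, c(2L, 1L, 3L))  # (B, T, T)
  bn <- bn_fwd(Tarr, p$ta_bn_g, p$ta_bn_b, state$ta_mean, state$ta_var, train)
  list(That = bn$out,
       cache = list(Ym = Ym, M1m = M1m, Z = Z, Zm = Zm, bn = bn, dims = d),
       state = list(ta_mean = bn$run_mean, ta_var = bn$run_var))
}

temporal_attention_bwd <- function(fw, p, dThat) {
  d <- fw$cache$dims; B <- d[1]; N <- d[2]; C <- d[3]; Tr <- d[4]
  g_bn <- bn_bwd(fw$cache$bn, p$ta_bn_g, dThat)
  dT <- g_bn$dx
  dTm <- aperm(dT, c(2L, 1L, 3L)); dim(dTm) <- c(Tr, B * Tr)
  dV <- dTm %*% t(fw$cache$Zm)
  dZm <- t(p$ta_V) %*% dTm
  dZ <- array(dZm, c(Tr, B, Tr)); dZ <- aperm(dZ, c(2L, 1L, 3L))
  dpre <- dZ * (1 - fw$cache$Z^2)
  dbt <- colSums(matrix(dpre, B, Tr * Tr)); dim(dbt) <- c(Tr, Tr)
  dM2 <- dpre; dim(dM2) <- c(B * Tr, Tr)
  dU4 <- crossprod(fw$cache$M1m, dM2)
  dM1 <- dM2 %*% t(p$ta_U4)
  dM1v <- as.vector(dM1)
  dU3 <- as.vector(crossprod(fw$cache$Ym, dM1v))
  dYm <- dM1v %o% p$ta_U3                      # (B*T*C, N)
  dY <- array(dYm, c(B, Tr, C, N))
  dXh <- aperm(dY, c(1L, 4L, 3L, 2L))
  list(dXh = dXh,
       grads = list(ta_U3 = dU3, ta_U4 = dU4, ta_bt = dbt, ta_V = dV,
                    ta_bn_g = g_bn$dgamma, ta_bn_b = g_bn$dbeta))
}

#' Temporal attention weights
#'
#' Mirrors the spatial construction on the time-transposed tensor: contract
#' nodes with `U3`, project channels to time with `U4`, bias, tanh,
#' left-multiply by `V`, then mini-batch standardization, yielding a
#' `T_r x T_r` temporal weight map.
#'
#' @inheritParams spatial_attention
#' @param params Parameter list with `ta_U3` (length N), `ta_U4` (C x T_r),
#'   `ta_bt`, `ta_V` (T_r x T_r) and the affine `ta_bn_g`, `ta_bn_b`.
#' @return List with `That` (`B x T_r x T_r` standardized weights) and
#'   updated `state`.
#' @export
temporal_attention <- function(Xh, params, train = TRUE,
                               state = list(ta_mean = 0, ta_var = 1)) {
  fw <- temporal_attention_fwd(Xh, params, state, train)
  list(That = fw$That, state = fw$state)
}

#' Re-weight the encoded tensor by temporal attention
#'
#' `Xhat[b, n, c, ] = That[b, , ] %*% Xh[b, n, c, ]`.
#'
#' @param That Array `B x T_r x T_r`.
#' @param Xh Array `B x N x C x T_r`.
#' @return Array of the same shape as `Xh`.
#' @export
apply_temporal <- function(That, Xh) apply_temporal_fwd(That, Xh)$out

apply_temporal_fwd <- function(That, Xh) {
  d <- dim(Xh); B <- d[1]; N <- d[2]; C <- d[3]; Tr <- d[4]
  stopifnot(all(dim(That) == c(B, Tr, Tr)))
  Xb <- aperm(Xh, c(2L, 3L, 4L, 1L)); dim(Xb) <- c(N * C, Tr, B)   # (NC, T', B)
  Tt <- aperm(That, c(3L, 2L, 1L))                                 # (T', T, B)
  Ob <- bmm(Xb, Tt)                                                # (NC, T, B)
  out <- array(Ob, c(N, C, Tr, B)); out <- aperm(out, c(4L, 1L, 2L, 3L))
  list(out = out, cache = list(Xb = Xb, Tt = Tt, dims = d))
}

apply_temporal_bwd <- function(cache, dOut) {
  d <- cache$dims; B <- d[1]; N <- d[2]; C <- d[3]; Tr <- d[4]
  dOb <- aperm(dOut, c(2L, 3L, 4L, 1L)); dim(dOb) <- c(N * C, Tr, B)
  dXb <- bmm(dOb, btrans(cache$Tt))
  dTt <- bmm(btrans(cache$Xb), dOb)            # (T', T, B)
  dThat <- aperm(dTt, c(3L, 2L, 1L))
  dXh <- array(dXb, c(N, C, Tr, B)); dXh <- aperm(dXh, c(4L, 1L, 2L, 3L))
  list(dXh = dXh, dThat = dThat)
}

# ---- graph attention layer -------------------------------------------------

# H: (B, N, F); A: (B, N, N) dynamic weights or (N, N) static binary.
# Neighborhood of i = nonzeros of row i plus a self-loop. Per head:
#   e_ij = LeakyReLU(a1.Wh_i + a2.Wh_j)
#   alpha = softmax_j(e_ij) over the neighborhood, attention dropout,
#   out_i = mean over heads of sum_j alpha_ij * w_ij * Wh_j, then ELU,
# where w_ij multiplies the retained dynamic edge weight A_ij into the
# message (w_ii = 1 on self-loops unless Top-K kept the diagonal entry;
# w = 1 on the edges of a binary static graph, i.e. a plain GAT). The
# multiplicative path is what makes the dynamic adjacency trainable.
gat_layer_fwd <- function(H, A, p, n_heads, dropout = 0, train = FALSE,
                          dynamic = NULL, slope = 0.2) {
  d <- dim(H); B <- d[1]; N <- d[2]; Fin <- d[3]
  if (is.matrix(A)) {
    if (is.null(dynamic)) dynamic <- FALSE
    Aarr <- array(rep(as.vector(A), each = B), c(B, N, N))
  } else {
    if (is.null(dynamic)) dynamic <- TRUE
    Aarr <- A
  }
  if (!all(is.finite(Aarr))) stop_config("adjacency contains non-finite values")
  mask <- Aarr != 0
  for (i in seq_len(N)) mask[, i, i] <- TRUE   # mandatory self-loop
  WA <- Aarr
  diag_zero <- !Aarr & mask                    # self-loops Top-K left at zero
  WA[diag_zero] <- 1
  if (!dynamic) WA[mask] <- 1                  # static binary graph: plain GAT
  Hm <- H; dim(Hm) <- c(B * N, Fin)
  heads <- vector("list", n_heads)
  Gout <- ncol(p$W[[1]])
  out_sum <- array(0, c(N, Gout, B))
  neg_inf <- -1e30
  for (k in seq_len(n_heads)) {
    Wh <- Hm %*% p$W[[k]]                      # (B*N, G)
    f1 <- as.vector(Wh %*% p$a1[[k]]); dim(f1) <- c(B, N)
    f2 <- as.vector(Wh %*% p$a2[[k]]); dim(f2) <- c(B, N)
    epre <- array(f1, c(B, N, N)) + aperm(array(f2, c(B, N, N)), c(1L, 3L, 2L))
    etot <- leaky_relu_fwd(epre, slope)
    etot[!mask] <- neg_inf
    em <- etot; dim(em) <- c(B * N, N)
    alpha <- softmax_rows(em)                  # rows = (b, i), cols = j
    drop <- dropout_fwd(alpha, dropout, train)
    al <- array(drop$out, c(B, N, N)) * WA     # edge-weighted attention
    alB <- aperm(al, c(2L, 3L, 1L))            # (N_i, N_j, B)
    WhB <- array(Wh, c(B, N, Gout)); WhB <- aperm(WhB, c(2L, 3L, 1L))  # (N_j, G, B)
    agg <- bmm(alB, WhB)                       # (N_i, G, B)
    out_sum <- out_sum + agg
    heads[[k]] <- list(Wh = Wh, f1 = f1, f2 = f2, epre = epre, alpha = alpha,
                       alpha_drop = drop$out, dropmask = drop$mask,
                       alB = alB, WhB = WhB)
  }
  pre_act <- aperm(out_sum / n_heads, c(3L, 1L, 2L))  # (B, N, G)
  out <- elu_fwd(pre_act)
  list(out = out,
       cache = list(heads = heads, Hm = Hm, mask = mask, dynamic = dynamic,
                    WA = WA, diag_zero = diag_zero, pre_act = pre_act, dims = d,
                    Gout = Gout, n_heads = n_heads, slope = slope,
                    static = is.matrix(A)))
}

gat_layer_bwd <- function(fw, p, dOut) {
  cc <- fw$cache
  B <- cc$dims[1]; N <- cc$dims[2]; Fin <- cc$dims[3]
  Gout <- cc$Gout; K <- cc$n_heads
  dpre <- elu_bwd(cc$pre_act, dOut)
  dagg <- aperm(dpre / K, c(2L, 3L, 1L))       # (N_i, G, B)
  dHm <- matrix(0, B * N, Fin)
  dA <- array(0, c(B, N, N))
  gW <- vector("list", K); ga1 <- vector("list", K); ga2 <- vector("list", K)
  for (k in seq_len(K)) {
    hd <- cc$heads[[k]]
    dalB <- bmm(dagg, btrans(hd$WhB))          # (N_i, N_j, B), wrt weighted alpha
    dWhB <- bmm(btrans(hd$alB), dagg)          # (N_j, G, B)
    dalw <- aperm(dalB, c(3L, 1L, 2L))         # (B, N_i, N_j)
    if (cc$dynamic) {
      dWA <- dalw * array(hd$alpha_drop, c(B, N, N))
      dWA[cc$diag_zero] <- 0                   # forced unit self-loops carry no edge grad
      dA <- dA + dWA
    }
    dal <- dalw * cc$WA
    dalpha <- dropout_bwd(hd$dropmask, matrix(dal, B * N, N))
    de <- hd$alpha * (dalpha - rowSums(dalpha * hd$alpha))
    de_arr <- array(de, c(B, N, N))
    de_arr[!cc$mask] <- 0
    depre <- leaky_relu_bwd(hd$epre, de_arr, cc$slope)
    df1 <- rowSums(matrix(depre, B * N, N)); dim(df1) <- c(B, N)      # sum over j
    df2 <- colSums(matrix(aperm(depre, c(2L, 1L, 3L)), N, B * N))
    dim(df2) <- c(B, N)                                               # sum over i
    dWh <- as.vector(df1) %o% p$a1[[k]] + as.vector(df2) %o% p$a2[[k]]
    dWh_agg <- aperm(dWhB, c(3L, 1L, 2L)); dim(dWh_agg) <- c(B * N, Gout)
    dWh <- dWh + dWh_agg
    ga1[[k]] <- as.vector(crossprod(hd$Wh, as.vector(df1)))
    ga2[[k]] <- as.vector(crossprod(hd$Wh, as.vector(df2)))
    gW[[k]] <- crossprod(cc$Hm, dWh)
    dHm <- dHm + dWh %*% t(p$W[[k]])
  }
  dH <- array(dHm, cc$dims)
  list(dH = dH, dA = if (cc$dynamic) dA else NULL, gW = gW, ga1 = ga1, ga2 = ga2)
}

#' Multi-head graph attention layer
#'
#' Computes attention coefficients over each node's neighborhood (the nonzero
#' entries of its adjacency row plus a mandatory self-loop), normalizes them
#' with a softmax, aggregates neighbour features and averages the heads. When
#' the adjacency is dynamic (a per-sample batch), its retained edge weights
#' are added to the attention logits so gradients reach the spatial-attention
#' parameters through the Top-K mask.
#'
#' @param H Node features, `B x N x F`.
#' @param A Adjacency: `N x N` static (binary) or `B x N x N` dynamic batch.
#' @param W,a1,a2 Lists (one per head) of weight matrices `F x F'` and
#'   attention-vector halves (length `F'`): `e_ij` uses
#'   `a1 . Wh_i + a2 . Wh_j`, i.e. the concatenation form split in two.
#' @param dropout Attention dropout rate (active only when `train = TRUE`).
#' @param train Training mode flag.
#' @return List with `out` (`B x N x F'`) and `alpha` (list of per-head
#'   `B*N x N` attention matrices).
#' @export
gat_layer <- function(H, A, W, a1, a2, dropout = 0, train = FALSE) {
  stopifnot(is.list(W), length(W) == length(a1), length(a1) == length(a2))
  fw <- gat_layer_fwd(H, A, list(W = W, a1 = a1, a2 = a2), length(W),
                      dropout = dropout, train = train)
  list(out = fw$out, alpha = lapply(fw$cache$heads, function(h) h$alpha))
}
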