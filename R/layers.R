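# Low-level differentiable layers. Each *_fwd returns list(out, cache);
# each *_bwd consumes (cache, grad-of-output) and returns grads.
#
# Image layout for convolutions: (C_in, H, W, M) with M the flattened
# batch-electrode index (batch fastest). Token layout for the transformer:
# (T, S, C) arrays reshaped to (T*S, C) matrices (token index t fastest).

.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(cin, H, W, kh, kw, M) {
  key <- paste(cin, H, W, kh, kw, M, sep = "|")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  Ho <- H - kh + 1L; Wo <- W - kw + 1L
  cs <- seq_len(cin) - 1L; dis <- seq_len(kh) - 1L; djs <- seq_len(kw) - 1L
  roff <- as.vector(outer(outer(cs, cin * dis, "+"), cin * H * djs, "+"))
  is <- seq_len(Ho) - 1L; js <- seq_len(Wo) - 1L; ms <- seq_len(M) - 1L
  coff <- as.vector(outer(outer(cin * is, cin * H * js, "+"), cin * H * W * ms, "+"))
  idx <- outer(roff, coff, "+") + 1L
  .im2col_cache[[key]] <- idx
  idx
}

# x: (C_in, H, W, M); w: (C_in, kh, kw, C_out); b: length C_out.
# Valid (unpadded) convolution, stride 1; compiled im2col + GEMM.
conv2d_fwd <- function(x, w, b) {
  dx <- dim(x); dw <- dim(w)
  stopifnot(dw[1] == dx[1], dx[2] >= dw[2], dx[3] >= dw[3])
  f <- conv2d_fwd_cpp(x, as.integer(dx), w, as.integer(dw), b)
  list(out = f$out, cache = list(cols = f$cols, w = w, dims = dx, kdims = dw))
}

conv2d_bwd <- function(cache, dout) {
  g <- conv2d_bwd_cpp(dout, cache$cols, cache$w, as.integer(cache$kdims),
                      as.integer(cache$dims))
  list(dx = g$dx, dw = g$dw, db = as.vector(g$db))
}

linear_fwd <- function(X, W, b) {
  out <- X %*% W + rep(b, each = nrow(X))
  list(out = out, cache = list(X = X, W = W))
}

linear_bwd <- function(cache, dY) {
  list(dx = dY %*% t(cache$W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X))
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(cache, dY) {
  n <- ncol(dY)
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * rep(cache$g, each = nrow(dY))
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# Column-wise softmax of a (k, m) matrix (each column a distribution).
softmax_cols <- function(M) {
  k <- nrow(M)
  mx <- M[1L, ]
  if (k > 1L) for (r in 2:k) mx <- pmax(mx, M[r, ])
  E <- exp(M - rep(mx, each = k))
  E / rep(colSums(E), each = k)
}

softmax_cols_bwd <- function(P, dP) {
  k <- nrow(P)
  s <- colSums(dP * P)
  P * (dP - rep(s, each = k))
}

# Multi-head self-attention over token matrix X (T*S, C) with T tokens per
# sequence, S sequences, h heads of width d = C/h.
mhsa_fwd <- function(X, Tlen, S, h, Wq, bq, Wk, bk, Wv, bv, Wo, bo) {
  C <- ncol(X); d <- C %/% h
  stopifnot(d * h == C)
  lq <- linear_fwd(X, Wq, bq); lk <- linear_fwd(X, Wk, bk); lv <- linear_fwd(X, Wv, bv)
  to_heads <- function(Z) {              # (T*S, C) -> (T, d, h*S)
    dim(Z) <- c(Tlen, S, C)
    Z <- aperm(Z, c(1L, 3L, 2L))         # (T, C, S)
    dim(Z) <- c(Tlen, d, h * S)
    Z
  }
  Qh <- to_heads(lq$out); Kh <- to_heads(lk$out); Vh <- to_heads(lv$out)
  sc <- bmm(Qh, btrans(Kh)) / sqrt(d)    # (T, T, h*S)
  scm <- aperm(sc, c(2L, 1L, 3L))        # keys down the columns
  dim(scm) <- c(Tlen, Tlen * h * S)
  P <- softmax_cols(scm)
  Pa <- P; dim(Pa) <- c(Tlen, Tlen, h * S); Pa <- aperm(Pa, c(2L, 1L, 3L))
  Oh <- bmm(Pa, Vh)                      # (T, d, h*S)
  from_heads <- function(Z) {            # (T, d, h*S) -> (T*S, C)
    dim(Z) <- c(Tlen, d, h, S)
    Z <- aperm(Z, c(1L, 4L, 2L, 3L))     # (T, S, d, h)
    dim(Z) <- c(Tlen * S, C)
    Z
  }
  O <- from_heads(Oh)
  lo <- linear_fwd(O, Wo, bo)
  list(out = lo$out,
       cache = list(lq = lq, lk = lk, lv = lv, lo = lo, Qh = Qh, Kh = Kh, Vh = Vh,
                    P = P, Pa = Pa, Tlen = Tlen, S = S, h = h, d = d, C = C),
       attn = Pa)
}

mhsa_bwd <- function(cache, dY) {
  Tlen <- cache$Tlen; S <- cache$S; h <- cache$h; d <- cache$d; C <- cache$C
  glo <- linear_bwd(cache$lo$cache, dY)
  dO <- glo$dx
  dim(dO) <- c(Tlen, S, d, h)
  dOh <- aperm(dO, c(1L, 3L, 4L, 2L)); dim(dOh) <- c(Tlen, d, h * S)
  dPa <- bmm(dOh, btrans(cache$Vh))
  dVh <- bmm(btrans(cache$Pa), dOh)
  dPm <- aperm(dPa, c(2L, 1L, 3L)); dim(dPm) <- c(Tlen, Tlen * h * S)
  dscm <- softmax_cols_bwd(cache$P, dPm)
  dsc <- dscm; dim(dsc) <- c(Tlen, Tlen, h * S); dsc <- aperm(dsc, c(2L, 1L, 3L))
  dsc <- dsc / sqrt(d)
  dQh <- bmm(dsc, cache$Kh)
  dKh <- bmm(btrans(dsc), cache$Qh)
  from_heads_grad <- function(Z) {       # (T, d, h*S) -> (T*S, C)
    dim(Z) <- c(Tlen, d, h, S)
    Z <- aperm(Z, c(1L, 4L, 2L, 3L))
    dim(Z) <- c(Tlen * S, C)
    Z
  }
  glq <- linear_bwd(cache$lq$cache, from_heads_grad(dQh))
  glk <- linear_bwd(cache$lk$cache, from_heads_grad(dKh))
  glv <- linear_bwd(cache$lv$cache, from_heads_grad(dVh))
  list(dx = glq$dx + glk$dx + glv$dx,
       dWq = glq$dW, dbq = glq$db, dWk = glk$dW, dbk = glk$db,
       dWv = glv$dW, dbv = glv$db, dWo = glo$dW, dbo = glo$db)
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  keep <- 1 - rate
  mask <- (stats::runif(length(x)) < keep) / keep
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(mask, dy) if (is.null(mask)) dy else dy * mask
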