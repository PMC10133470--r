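# Independent naive-loop oracles. Deliberately written with explicit scalar
# loops and none of the package's vectorized code paths.

oracle_fft_bandpass_var <- function(x, rate, low, high) {
  # variance of x restricted to [low, high) Hz by hard FFT masking
  n <- length(x)
  sp <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * rate / n
  freqs <- pmin(freqs, rate - freqs)
  keep <- freqs >= low & freqs < high
  stats::var(Re(stats::fft(sp * keep, inverse = TRUE)) / n)
}

oracle_spatial <- function(Xh, W1, W2, bs, V, k_top, eps = 1e-5) {
  d <- dim(Xh); B <- d[1]; N <- d[2]; C <- d[3]; Tr <- d[4]
  S <- array(0, c(B, N, N))
  for (b in seq_len(B)) {
    M1 <- matrix(0, N, C)
    for (n in seq_len(N)) for (c in seq_len(C)) {
      for (t in seq_len(Tr)) M1[n, c] <- M1[n, c] + Xh[b, n, c, t] * W1[t]
    }
    Z <- matrix(0, N, N)
    for (n in seq_len(N)) for (j in seq_len(N)) {
      acc <- bs[n, j]
      for (c in seq_len(C)) acc <- acc + M1[n, c] * W2[c, j]
      Z[n, j] <- tanh(acc)
    }
    for (i in seq_len(N)) for (j in seq_len(N)) {
      acc <- 0
      for (m in seq_len(N)) acc <- acc + V[i, m] * Z[m, j]
      S[b, i, j] <- acc
    }
  }
  mu <- mean(S); v <- mean((S - mu)^2)
  Shat <- (S - mu) / sqrt(v + eps)
  A <- Shat
  for (b in seq_len(B)) for (i in seq_len(N)) {
    row <- Shat[b, i, ]
    kept <- order(row, decreasing = TRUE)[seq_len(min(k_top, N))]
    zeroed <- setdiff(seq_len(N), kept)
    A[b, i, zeroed] <- 0
  }
  list(A = A, pre = Shat)
}

oracle_temporal <- function(Xh, U3, U4, bt, V, eps = 1e-5) {
  d <- dim(Xh); B <- d[1]; N <- d[2]; C <- d[3]; Tr <- d[4]
  Tt <- array(0, c(B, Tr, Tr))
  for (b in seq_len(B)) {
    M1 <- matrix(0, Tr, C)
    for (t in seq_len(Tr)) for (c in seq_len(C)) {
      for (n in seq_len(N)) M1[t, c] <- M1[t, c] + Xh[b, n, c, t] * U3[n]
    }
    Z <- matrix(0, Tr, Tr)
    for (t in seq_len(Tr)) for (u in seq_len(Tr)) {
      acc <- bt[t, u]
      for (c in seq_len(C)) acc <- acc + M1[t, c] * U4[c, u]
      Z[t, u] <- tanh(acc)
    }
    for (t in seq_len(Tr)) for (u in seq_len(Tr)) {
      acc <- 0
      for (m in seq_len(Tr)) acc <- acc + V[t, m] * Z[m, u]
      Tt[b, t, u] <- acc
    }
  }
  mu <- mean(Tt); v <- mean((Tt - mu)^2)
  (Tt - mu) / sqrt(v + eps)
}

oracle_apply_temporal <- function(That, Xh) {
  d <- dim(Xh)
  out <- array(0, d)
  for (b in seq_len(d[1])) for (n in seq_len(d[2])) for (c in seq_len(d[3])) {
    for (t in seq_len(d[4])) {
      acc <- 0
      for (u in seq_len(d[4])) acc <- acc + That[b, t, u] * Xh[b, n, c, u]
      out[b, n, c, t] <- acc
    }
  }
  out
}

oracle_gat <- function(H, A, W, a1, a2, slope = 0.2) {
  d <- dim(H); B <- d[1]; N <- d[2]
  dynamic <- !is.matrix(A)
  G <- ncol(W[[1]]); K <- length(W)
  out <- array(0, c(B, N, G))
  alphas <- list()
  for (k in seq_len(K)) alphas[[k]] <- array(0, c(B, N, N))
  for (b in seq_len(B)) {
    Ab <- if (dynamic) A[b, , ] else A
    for (k in seq_len(K)) {
      Wh <- matrix(0, N, G)
      for (n in seq_len(N)) Wh[n, ] <- as.vector(H[b, n, ] %*% W[[k]])
      for (i in seq_len(N)) {
        nbrs <- union(which(Ab[i, ] != 0), i)
        e <- numeric(length(nbrs))
        for (q in seq_along(nbrs)) {
          j <- nbrs[q]
          raw <- sum(a1[[k]] * Wh[i, ]) + sum(a2[[k]] * Wh[j, ])
          e[q] <- if (raw > 0) raw else slope * raw
        }
        al <- exp(e - max(e)); al <- al / sum(al)
        for (q in seq_along(nbrs)) {
          j <- nbrs[q]
          alphas[[k]][b, i, j] <- al[q]
          w_edge <- if (dynamic) { if (Ab[i, j] != 0) Ab[i, j] else 1 } else 1
          out[b, i, ] <- out[b, i, ] + al[q] * w_edge * Wh[j, ] / K
        }
      }
    }
  }
  for (b in seq_len(B)) for (i in seq_len(N)) for (g in seq_len(G)) {
    v <- out[b, i, g]
    out[b, i, g] <- if (v > 0) v else exp(v) - 1
  }
  list(out = out, alphas = alphas)
}

oracle_transformer <- function(seq_in, pos, ln1_g, ln1_b, Wq, bq, Wk, bk, Wv, bv,
                               Wo, bo, ln2_g, ln2_b, ffW1, ffb1, ffW2, ffb2,
                               eps = 1e-5) {
  # single layer, single head, pre-norm; seq_in is (S, T, C)
  d <- dim(seq_in); S <- d[1]; Tn <- d[2]; C <- d[3]
  ln <- function(x, g, b) {
    mu <- mean(x); v <- mean((x - mu)^2)
    (x - mu) / sqrt(v + eps) * g + b
  }
  out <- array(0, d)
  for (s in seq_len(S)) {
    X <- matrix(seq_in[s, , ], Tn, C) + pos
    Xn <- t(apply(X, 1, ln, g = ln1_g, b = ln1_b))
    Q <- Xn %*% Wq + matrix(bq, Tn, C, byrow = TRUE)
    K <- Xn %*% Wk + matrix(bk, Tn, C, byrow = TRUE)
    V <- Xn %*% Wv + matrix(bv, Tn, C, byrow = TRUE)
    att <- matrix(0, Tn, C)
    for (t in seq_len(Tn)) {
      sc <- numeric(Tn)
      for (u in seq_len(Tn)) sc[u] <- sum(Q[t, ] * K[u, ]) / sqrt(C)
      p <- exp(sc - max(sc)); p <- p / sum(p)
      for (u in seq_len(Tn)) att[t, ] <- att[t, ] + p[u] * V[u, ]
    }
    O <- att %*% Wo + matrix(bo, Tn, C, byrow = TRUE)
    H1 <- X + O
    H1n <- t(apply(H1, 1, ln, g = ln2_g, b = ln2_b))
    FF <- pmax(H1n %*% ffW1 + matrix(ffb1, Tn, 2 * C, byrow = TRUE), 0) %*% ffW2 +
      matrix(ffb2, Tn, C, byrow = TRUE)
    out[s, , ] <- H1 + FF
  }
  out
}
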