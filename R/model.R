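#' Model configuration
#'
#' Defines the network variant and all architecture hyperparameters. The
#' eight variants form the ablation grid: `baseline` (multi-kernel 2-D
#' convolutions only), `tlb` (convolutions + transformer encoder), `sgat` /
#' `tgat` (graph attention driven by spatial / temporal attention), their
#' `_tlb` combinations, `stgat` (both attentions, no transformer) and
#' `stgate` (the full model).
#'
#' @param variant One of `"baseline"`, `"tlb"`, `"sgat"`, `"tgat"`,
#'   `"sgat_tlb"`, `"tgat_tlb"`, `"stgat"`, `"stgate"`.
#' @param n_classes Number of emotion classes.
#' @param n_channels Number of EEG channels N.
#' @param n_bands Feature bands F per channel (default 5).
#' @param t_in Input sequence length T in windows (default 10); the two
#'   unpadded 3x3 convolutions reduce it to `t_in - 4`.
#' @param conv_channels Convolution width C (default 32).
#' @param depth Transformer encoder depth (default 2).
#' @param heads Transformer head count (default 4); must divide C.
#' @param gat_heads Graph-attention head count K (default 4).
#' @param gat_out Graph-attention output width F' (default 32).
#' @param k_top Top-K kept per adjacency row (default 10).
#' @param k_nn Neighbours for the static kNN graph (default 10).
#' @param dropout Dropout rate for attention coefficients and the readout
#'   (default 0.3).
#' @return A `model_config` object.
#' @export
model_config <- function(variant = c("stgate", "baseline", "tlb", "sgat", "tgat",
                                     "sgat_tlb", "tgat_tlb", "stgat"),
                         n_classes, n_channels, n_bands = 5L, t_in = 10L,
                         conv_channels = 32L, depth = 2L, heads = 4L,
                         gat_heads = 4L, gat_out = 32L,
                         k_top = 10L, k_nn = 10L, dropout = 0.3) {
  variant <- match.arg(variant)
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  if (conv_channels %% heads != 0) {
    stop_config("conv_channels (%d) must be divisible by heads (%d)", conv_channels, heads)
  }
  if (t_in < 5L) stop_config("t_in must be >= 5 (two unpadded 3x3 convolutions need it)")
  if (n_bands != 5L) stop_config("n_bands must equal 5 for the fixed convolution stack")
  structure(list(
    variant = variant, n_classes = as.integer(n_classes),
    n_channels = as.integer(n_channels), n_bands = as.integer(n_bands),
    t_in = as.integer(t_in), t_r = as.integer(t_in - 4L),
    conv_channels = as.integer(conv_channels), depth = as.integer(depth),
    heads = as.integer(heads), gat_heads = as.integer(gat_heads),
    gat_out = as.integer(gat_out), k_top = as.integer(k_top),
    k_nn = as.integer(k_nn), dropout = dropout,
    has_tlb = variant %in% c("tlb", "sgat_tlb", "tgat_tlb", "stgate"),
    has_sgat = variant %in% c("sgat", "sgat_tlb", "stgat", "stgate"),
    has_tgat = variant %in% c("tgat", "tgat_tlb", "stgat", "stgate")
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s: N=%d classes=%d C=%d T=%d->%d depth=%d heads=%d K=%d k_top=%d\n",
              x$variant, x$n_channels, x$n_classes, x$conv_channels, x$t_in, x$t_r,
              x$depth, x$heads, x$gat_heads, x$k_top))
  invisible(x)
}

variant_names <- function() {
  c("baseline", "tlb", "sgat", "sgat_tlb", "tgat", "tgat_tlb", "stgat", "stgate")
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, identity-like normalization affines.
#' Only the parameter groups used by `cfg$variant` are created, so the full
#' model's parameter set is a strict superset of every ablated variant's.
#'
#' @param cfg A [model_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return List with `params` (named list of numeric arrays) and `state`
#'   (normalization running statistics).
#' @export
init_model <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- cfg$conv_channels; Tr <- cfg$t_r; N <- cfg$n_channels
  p <- list()
  p$conv_w1 <- array(glorot(9, C, fan_in = 9, fan_out = 9 * C), c(1, 3, 3, C))
  p$conv_b1 <- numeric(C)
  p$conv_w2 <- array(glorot(9 * C, C, fan_in = 9 * C, fan_out = 9 * C), c(C, 3, 3, C))
  p$conv_b2 <- numeric(C)
  p$conv_w3 <- array(glorot(C, C), c(C, 1, 1, C))
  p$conv_b3 <- numeric(C)
  if (cfg$has_tlb) {
    p$pos <- matrix(stats::rnorm(Tr * C, sd = 0.02), Tr, C)
    for (l in seq_len(cfg$depth)) {
      pre <- sprintf("enc%d_", l)
      p[[paste0(pre, "ln1_g")]] <- rep(1, C); p[[paste0(pre, "ln1_b")]] <- numeric(C)
      p[[paste0(pre, "Wq")]] <- glorot(C, C); p[[paste0(pre, "bq")]] <- numeric(C)
      p[[paste0(pre, "Wk")]] <- glorot(C, C); p[[paste0(pre, "bk")]] <- numeric(C)
      p[[paste0(pre, "Wv")]] <- glorot(C, C); p[[paste0(pre, "bv")]] <- numeric(C)
      p[[paste0(pre, "Wo")]] <- glorot(C, C); p[[paste0(pre, "bo")]] <- numeric(C)
      p[[paste0(pre, "ln2_g")]] <- rep(1, C); p[[paste0(pre, "ln2_b")]] <- numeric(C)
      p[[paste0(pre, "ff_W1")]] <- glorot(C, 2 * C); p[[paste0(pre, "ff_b1")]] <- numeric(2 * C)
      p[[paste0(pre, "ff_W2")]] <- glorot(2 * C, C); p[[paste0(pre, "ff_b2")]] <- numeric(C)
    }
  }
  if (cfg$has_sgat) {
    p$sa_W1 <- stats::rnorm(Tr, sd = 1 / sqrt(Tr))
    p$sa_W2 <- glorot(C, N)
    p$sa_bs <- matrix(0, N, N)
    p$sa_V <- glorot(N, N)
    p$sa_bn_g <- 1; p$sa_bn_b <- 0
  }
  if (cfg$has_tgat) {
    p$ta_U3 <- stats::rnorm(N, sd = 1 / sqrt(N))
    p$ta_U4 <- glorot(C, Tr)
    p$ta_bt <- matrix(0, Tr, Tr)
    p$ta_V <- glorot(Tr, Tr)
    p$ta_bn_g <- 1; p$ta_bn_b <- 0
  }
  if (cfg$has_sgat || cfg$has_tgat) {
    Fin <- C * Tr
    for (k in seq_len(cfg$gat_heads)) {
      p[[sprintf("gat%d_W", k)]] <- glorot(Fin, cfg$gat_out)
      p[[sprintf("gat%d_a1", k)]] <- stats::rnorm(cfg$gat_out, sd = 1 / sqrt(cfg$gat_out))
      p[[sprintf("gat%d_a2", k)]] <- stats::rnorm(cfg$gat_out, sd = 1 / sqrt(cfg$gat_out))
    }
    feat <- cfg$gat_out
  } else {
    feat <- C * Tr
  }
  p$out_W <- glorot(feat, cfg$n_classes)
  p$out_b <- numeric(cfg$n_classes)
  state <- list(sa_mean = 0, sa_var = 1, ta_mean = 0, ta_var = 1, bn_momentum = 0.1)
  list(params = p, state = state)
}

# ---- convolution stack -----------------------------------------------------

#' Per-electrode convolution stack
#'
#' Treats every electrode as a (band x time) image: two unpadded 3x3
#' convolutions (collapsing the five bands to one and trimming the time axis
#' by four) followed by a 1x1 convolution, ReLU between layers. Weights are
#' shared across electrodes.
#'
#' @param x Array `B x N x F x T`.
#' @param params Parameter list holding `conv_w*` / `conv_b*`.
#' @return Array `B x N x C x T_r` with `T_r = T - 4`.
#' @export
conv_stack_forward <- function(x, params) {
  f <- conv_stack_fwd_cached(x, params)
  f$out_bnct
}

conv_stack_fwd_cached <- function(x, params) {
  d <- dim(x)
  if (length(d) != 4L) stop_config("expected a B x N x F x T array")
  B <- d[1]; N <- d[2]; F <- d[3]; T <- d[4]
  if (F != 5L) stop_config("band axis has length %d; the convolution stack collapses exactly 5 bands", F)
  if (T < 5L) stop_config("time axis has length %d; the convolution stack needs >= 5", T)
  M <- B * N
  xi <- aperm(x, c(3L, 4L, 1L, 2L)); dim(xi) <- c(1L, F, T, M)
  c1 <- conv2d_fwd(xi, params$conv_w1, params$conv_b1)
  r1 <- relu_fwd(c1$out)
  c2 <- conv2d_fwd(r1, params$conv_w2, params$conv_b2)
  r2 <- relu_fwd(c2$out)
  c3 <- conv2d_fwd(r2, params$conv_w3, params$conv_b3)
  C <- dim(c3$out)[1]; Tr <- dim(c3$out)[3]
  h <- c3$out
  dim(h) <- c(C, Tr, M)
  out <- h; dim(out) <- c(C, Tr, B, N); out <- aperm(out, c(3L, 4L, 1L, 2L))
  list(out_bnct = out, h_ctm = h,
       cache = list(c1 = c1, a1 = c1$out, c2 = c2, a2 = c2$out, c3 = c3,
                    B = B, N = N, F = F, T = T, C = C, Tr = Tr))
}

conv_stack_bwd <- function(cache, dh_ctm) {
  B <- cache$B; N <- cache$N; C <- cache$C; Tr <- cache$Tr
  dh <- dh_ctm; dim(dh) <- c(C, 1L, Tr, B * N)
  g3 <- conv2d_bwd(cache$c3$cache, dh)
  dr2 <- relu_bwd(cache$a2, g3$dx)
  g2 <- conv2d_bwd(cache$c2$cache, dr2)
  dr1 <- relu_bwd(cache$a1, g2$dx)
  g1 <- conv2d_bwd(cache$c1$cache, dr1)
  dxi <- g1$dx; dim(dxi) <- c(cache$F, cache$T, B, N)
  dx <- aperm(dxi, c(3L, 4L, 1L, 2L))
  list(dx = dx,
       grads = list(conv_w1 = g1$dw, conv_b1 = g1$db,
                    conv_w2 = g2$dw, conv_b2 = g2$db,
                    conv_w3 = g3$dw, conv_b3 = g3$db))
}

# ---- transformer encoder ---------------------------------------------------

#' Transformer encoder over per-electrode sequences
#'
#' Adds a learned positional embedding, then `depth` pre-norm encoder layers
#' (multi-head self-attention and a 2C-wide feed-forward, each with a
#' residual connection). Depth 0 returns the input plus the positional
#' embedding.
#'
#' @param seq Array `S x T_r x C` (sequences x tokens x channels).
#' @param params Parameter list (`pos`, `enc*_`).
#' @param depth Number of encoder layers.
#' @param heads Head count.
#' @return Array of the same shape as `seq`.
#' @export
transformer_encode <- function(seq, params, depth, heads) {
  d <- dim(seq)
  stopifnot(length(d) == 3L)
  S <- d[1]; Tr <- d[2]; C <- d[3]
  X <- aperm(seq, c(2L, 1L, 3L)); dim(X) <- c(Tr * S, C)  # (T,S,C) tokens
  f <- encoder_fwd(X, Tr, S, params, depth, heads)
  out <- f$out; dim(out) <- c(Tr, S, C)
  aperm(out, c(2L, 1L, 3L))
}

encoder_fwd <- function(X, Tlen, S, params, depth, heads) {
  C <- ncol(X)
  pos <- params$pos
  Xp <- X + pos[rep(seq_len(Tlen), times = S), , drop = FALSE]
  caches <- vector("list", depth)
  H <- Xp
  for (l in seq_len(depth)) {
    pre <- sprintf("enc%d_", l)
    ln1 <- layernorm_fwd(H, params[[paste0(pre, "ln1_g")]], params[[paste0(pre, "ln1_b")]])
    at <- mhsa_fwd(ln1$out, Tlen, S, heads,
                   params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]],
                   params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]],
                   params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]],
                   params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]])
    H1 <- H + at$out
    ln2 <- layernorm_fwd(H1, params[[paste0(pre, "ln2_g")]], params[[paste0(pre, "ln2_b")]])
    l1 <- linear_fwd(ln2$out, params[[paste0(pre, "ff_W1")]], params[[paste0(pre, "ff_b1")]])
    a <- relu_fwd(l1$out)
    l2 <- linear_fwd(a, params[[paste0(pre, "ff_W2")]], params[[paste0(pre, "ff_b2")]])
    H2 <- H1 + l2$out
    caches[[l]] <- list(ln1 = ln1, at = at, ln2 = ln2, l1 = l1, a_pre = l1$out, l2 = l2)
    H <- H2
  }
  list(out = H, caches = caches, Tlen = Tlen, S = S)
}

encoder_bwd <- function(fw, params, depth, dH) {
  grads <- list()
  for (l in rev(seq_len(depth))) {
    pre <- sprintf("enc%d_", l)
    cc <- fw$caches[[l]]
    g2 <- linear_bwd(cc$l2$cache, dH)
    da <- relu_bwd(cc$a_pre, g2$dx)
    g1 <- linear_bwd(cc$l1$cache, da)
    gl2 <- layernorm_bwd(cc$ln2$cache, g1$dx)
    dH1 <- dH + gl2$dx
    gat <- mhsa_bwd(cc$at$cache, dH1)
    gl1 <- layernorm_bwd(cc$ln1$cache, gat$dx)
    dH <- dH1 + gl1$dx
    grads[[paste0(pre, "ff_W2")]] <- g2$dW; grads[[paste0(pre, "ff_b2")]] <- g2$db
    grads[[paste0(pre, "ff_W1")]] <- g1$dW; grads[[paste0(pre, "ff_b1")]] <- g1$db
    grads[[paste0(pre, "ln2_g")]] <- gl2$dg; grads[[paste0(pre, "ln2_b")]] <- gl2$db
    grads[[paste0(pre, "Wq")]] <- gat$dWq; grads[[paste0(pre, "bq")]] <- gat$dbq
    grads[[paste0(pre, "Wk")]] <- gat$dWk; grads[[paste0(pre, "bk")]] <- gat$dbk
    grads[[paste0(pre, "Wv")]] <- gat$dWv; grads[[paste0(pre, "bv")]] <- gat$dbv
    grads[[paste0(pre, "Wo")]] <- gat$dWo; grads[[paste0(pre, "bo")]] <- gat$dbo
    grads[[paste0(pre, "ln1_g")]] <- gl1$dg; grads[[paste0(pre, "ln1_b")]] <- gl1$db
  }
  Tlen <- fw$Tlen; S <- fw$S
  dpos <- rowsum(dH, group = rep(seq_len(Tlen), times = S))
  grads$pos <- dpos
  list(dx = dH, grads = grads)
}

#' Transformer-learning-block forward pass
#'
#' Convolution stack followed (for TLB variants) by the transformer encoder
#' over each electrode's reduced temporal sequence.
#'
#' @param x Array `B x N x F x T`.
#' @param params Parameter list from [init_model()].
#' @param cfg A [model_config()].
#' @return Encoded array `B x N x C x T_r`.
#' @export
tlb_forward <- function(x, params, cfg) {
  cs <- conv_stack_fwd_cached(x, params)
  if (!cfg$has_tlb) return(cs$out_bnct)
  C <- dim(cs$h_ctm)[1]; Tr <- dim(cs$h_ctm)[2]; M <- dim(cs$h_ctm)[3]
  seq <- aperm(cs$h_ctm, c(3L, 2L, 1L))  # (S=M, T, C)
  enc <- transformer_encode(seq, params, cfg$depth, cfg$heads)
  h <- aperm(enc, c(3L, 2L, 1L))         # (C, T, M)
  out <- h; dim(out) <- c(C, Tr, dim(x)[1], dim(x)[2])
  aperm(out, c(3L, 4L, 1L, 2L))
}
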