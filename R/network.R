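# Full-network forward and backward passes across the ablation grid.

gat_param_view <- function(params, n_heads) {
  list(W = lapply(seq_len(n_heads), function(k) params[[sprintf("gat%d_W", k)]]),
       a1 = lapply(seq_len(n_heads), function(k) params[[sprintf("gat%d_a1", k)]]),
       a2 = lapply(seq_len(n_heads), function(k) params[[sprintf("gat%d_a2", k)]]))
}

network_fwd <- function(x, params, cfg, state, train = FALSE, static_A = NULL) {
  d <- dim(x)
  if (length(d) != 4L) stop_config("input must be B x N x F x T")
  B <- d[1]; N <- d[2]
  if (N != cfg$n_channels) stop_config("input has %d channels, config expects %d", N, cfg$n_channels)
  needs_static <- (cfg$has_tgat && !cfg$has_sgat)
  if (needs_static && is.null(static_A)) {
    stop_config("variant '%s' uses a static kNN adjacency: static_A is required", cfg$variant)
  }
  cs <- conv_stack_fwd_cached(x, params)
  C <- cs$cache$C; Tr <- cs$cache$Tr
  cache <- list(cs = cs, cfg = cfg, dims = d)
  if (cfg$has_tlb) {
    Xtok <- aperm(cs$h_ctm, c(2L, 3L, 1L)); dim(Xtok) <- c(Tr * B * N, C)
    enc <- encoder_fwd(Xtok, Tr, B * N, params, cfg$depth, cfg$heads)
    h_ctm <- array(enc$out, c(Tr, B * N, C)); h_ctm <- aperm(h_ctm, c(3L, 1L, 2L))
    cache$enc <- enc
  } else {
    h_ctm <- cs$h_ctm
  }
  Xh <- h_ctm; dim(Xh) <- c(C, Tr, B, N); Xh <- aperm(Xh, c(3L, 4L, 1L, 2L))  # (B,N,C,T)
  cache$Xh <- Xh
  new_state <- state
  A_pre <- NULL
  if (cfg$has_sgat) {
    sa <- spatial_attention_fwd(Xh, params, cfg$k_top, state, train)
    cache$sa <- sa
    new_state$sa_mean <- sa$state$sa_mean; new_state$sa_var <- sa$state$sa_var
    A_use <- sa$A
    A_pre <- sa$A_pre_topk
  } else if (cfg$has_tgat) {
    A_use <- static_A
  } else {
    A_use <- NULL
  }
  if (cfg$has_tgat) {
    ta <- temporal_attention_fwd(Xh, params, state, train)
    cache$ta <- ta
    new_state$ta_mean <- ta$state$ta_mean; new_state$ta_var <- ta$state$ta_var
    ap <- apply_temporal_fwd(ta$That, Xh)
    cache$ap <- ap
    Xfin <- ap$out
  } else {
    Xfin <- Xh
  }
  if (cfg$has_sgat || cfg$has_tgat) {
    H <- array(Xfin, c(B, N, C * Tr))  # (B,N,C,T) contiguous -> flatten (C,T)
    gp <- gat_param_view(params, cfg$gat_heads)
    gat <- gat_layer_fwd(H, A_use, gp, cfg$gat_heads,
                         dropout = cfg$dropout, train = train)
    cache$gat <- gat
    nodes <- gat$out                   # (B, N, G)
    Gf <- dim(nodes)[3]
  } else {
    nodes <- array(Xfin, c(B, N, C * Tr))
    Gf <- C * Tr
  }
  nm <- nodes; dim(nm) <- c(B * N, Gf)
  pooled <- rowsum(nm, group = rep(seq_len(B), times = N)) / N
  dropr <- dropout_fwd(pooled, cfg$dropout, train)
  lin <- linear_fwd(dropr$out, params$out_W, params$out_b)
  cache$pool <- list(Gf = Gf, dropmask = dropr$mask, lin = lin)
  list(logits = lin$out, cache = cache, state = new_state, A_dynamic = cache$sa$A %||% NULL,
       A_pre_topk = A_pre)
}

network_bwd <- function(fw, params, cfg, dlogits) {
  cache <- fw$cache
  d <- cache$dims; B <- d[1]; N <- d[2]
  C <- cache$cs$cache$C; Tr <- cache$cs$cache$Tr
  grads <- list()
  gl <- linear_bwd(cache$pool$lin$cache, dlogits)
  grads$out_W <- gl$dW; grads$out_b <- gl$db
  dpooled <- dropout_bwd(cache$pool$dropmask, gl$dx)
  Gf <- cache$pool$Gf
  dnm <- (dpooled / N)[rep(seq_len(B), times = N), , drop = FALSE]  # (B*N, Gf)
  if (cfg$has_sgat || cfg$has_tgat) {
    dnodes <- array(dnm, c(B, N, Gf))
    gp <- gat_param_view(params, cfg$gat_heads)
    gg <- gat_layer_bwd(cache$gat, gp, dnodes)
    for (k in seq_len(cfg$gat_heads)) {
      grads[[sprintf("gat%d_W", k)]] <- gg$gW[[k]]
      grads[[sprintf("gat%d_a1", k)]] <- gg$ga1[[k]]
      grads[[sprintf("gat%d_a2", k)]] <- gg$ga2[[k]]
    }
    dXfin <- array(gg$dH, c(B, N, C, Tr))
    dXh <- array(0, c(B, N, C, Tr))
    if (cfg$has_tgat) {
      gap <- apply_temporal_bwd(cache$ap$cache, dXfin)
      dXh <- dXh + gap$dXh
      gta <- temporal_attention_bwd(cache$ta, params, gap$dThat)
      dXh <- dXh + gta$dXh
      for (nm2 in names(gta$grads)) grads[[nm2]] <- gta$grads[[nm2]]
    } else {
      dXh <- dXh + dXfin
    }
    if (cfg$has_sgat && !is.null(gg$dA)) {
      gsa <- spatial_attention_bwd(cache$sa, params, gg$dA)
      dXh <- dXh + gsa$dXh
      for (nm2 in names(gsa$grads)) grads[[nm2]] <- gsa$grads[[nm2]]
    }
  } else {
    dXh <- array(dnm, c(B, N, C, Tr))
  }
  dh_ctm <- aperm(dXh, c(3L, 4L, 1L, 2L)); dim(dh_ctm) <- c(C, Tr, B * N)
  if (cfg$has_tlb) {
    dtok <- aperm(dh_ctm, c(2L, 3L, 1L)); dim(dtok) <- c(Tr * B * N, C)
    genc <- encoder_bwd(cache$enc, params, cfg$depth, dtok)
    for (nm2 in names(genc$grads)) grads[[nm2]] <- genc$grads[[nm2]]
    dh2 <- array(genc$dx, c(Tr, B * N, C)); dh_ctm <- aperm(dh2, c(3L, 1L, 2L))
  }
  gcs <- conv_stack_bwd(cache$cs$cache, dh_ctm)
  for (nm2 in names(gcs$grads)) grads[[nm2]] <- gcs$grads[[nm2]]
  grads
}

#' Forward pass of the network
#'
#' Runs the variant-appropriate wiring: convolution stack, optional
#' transformer encoder, optional spatial attention (dynamic adjacency),
#' optional temporal attention, graph attention (for variants that use a
#' graph), then mean-over-nodes readout, dropout and a linear classifier.
#'
#' @param x Input features, `B x N x F x T`.
#' @param model Model list with `params`, `state` and `config`
#'   (see [init_model()], [model_config()]).
#' @param static_A Static `N x N` adjacency from [knn_graph()]; required for
#'   the `tgat` / `tgat_tlb` variants.
#' @param train Training mode (dropout and mini-batch normalization active).
#' @return List with `logits` (`B x n_classes`), `A_dynamic` (sparsified
#'   per-sample adjacency, when spatial attention is active), `A_pre_topk`
#'   (standardized scores before Top-K) and the updated normalization
#'   `state`.
#' @export
stgate_forward <- function(x, model, static_A = NULL, train = FALSE) {
  fw <- network_fwd(x, model$params, model$config, model$state,
                    train = train, static_A = static_A)
  list(logits = fw$logits, A_dynamic = fw$A_dynamic, A_pre_topk = fw$A_pre_topk,
       state = fw$state)
}

# Softmax cross-entropy loss and gradient for integer labels (1-based).
cross_entropy <- function(logits, labels) {
  B <- nrow(logits)
  lse <- logsumexp_rows(logits)
  picked <- logits[cbind(seq_len(B), labels)]
  loss <- mean(lse - picked)
  P <- exp(logits - lse)
  Y <- matrix(0, B, ncol(logits)); Y[cbind(seq_len(B), labels)] <- 1
  list(loss = loss, dlogits = (P - Y) / B)
}
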