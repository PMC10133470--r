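test_that("convolution stack obeys the unpadded shape contract", {
  cfg <- tiny_cfg(n_channels = 62L)
  mod <- init_model(cfg, seed = 1)
  x <- rand_x(2, 62)
  out <- conv_stack_forward(x, mod$params)
  expect_equal(dim(out), c(2L, 62L, 8L, 6L))
  expect_error(conv_stack_forward(rand_x(2, 62, T = 4L), mod$params), "time axis")
  expect_error(conv_stack_forward(rand_x(2, 62, F = 4L), mod$params), "band axis")
})

test_that("convolution stack is linear at zero and permutation-equivariant", {
  cfg <- tiny_cfg()
  mod <- init_model(cfg, seed = 2)
  zp <- mod$params
  zp$conv_b1 <- zp$conv_b1 * 0; zp$conv_b2 <- zp$conv_b2 * 0; zp$conv_b3 <- zp$conv_b3 * 0
  expect_true(all(conv_stack_forward(array(0, c(2, 5, 5, 10)), zp) == 0))
  x <- rand_x(2, 5, seed = 3)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  out <- conv_stack_forward(x, mod$params)
  out_p <- conv_stack_forward(x[, perm, , , drop = FALSE], mod$params)
  expect_equal(out_p, out[, perm, , , drop = FALSE], tolerance = 1e-12)
})

test_that("transformer encoder matches a dense single-head oracle", {
  C <- 4L; Tn <- 3L; S <- 2L
  set.seed(9)
  params <- list(
    pos = matrix(rnorm(Tn * C, sd = 0.5), Tn, C),
    enc1_ln1_g = runif(C, 0.5, 1.5), enc1_ln1_b = rnorm(C, sd = 0.2),
    enc1_Wq = matrix(rnorm(C * C, sd = 0.4), C, C), enc1_bq = rnorm(C, sd = 0.1),
    enc1_Wk = matrix(rnorm(C * C, sd = 0.4), C, C), enc1_bk = rnorm(C, sd = 0.1),
    enc1_Wv = matrix(rnorm(C * C, sd = 0.4), C, C), enc1_bv = rnorm(C, sd = 0.1),
    enc1_Wo = matrix(rnorm(C * C, sd = 0.4), C, C), enc1_bo = rnorm(C, sd = 0.1),
    enc1_ln2_g = runif(C, 0.5, 1.5), enc1_ln2_b = rnorm(C, sd = 0.2),
    enc1_ff_W1 = matrix(rnorm(C * 2 * C, sd = 0.4), C, 2 * C), enc1_ff_b1 = rnorm(2 * C, sd = 0.1),
    enc1_ff_W2 = matrix(rnorm(2 * C * C, sd = 0.4), 2 * C, C), enc1_ff_b2 = rnorm(C, sd = 0.1)
  )
  seq_in <- array(rnorm(S * Tn * C), c(S, Tn, C))
  got <- transformer_encode(seq_in, params, depth = 1L, heads = 1L)
  want <- oracle_transformer(seq_in, params$pos, params$enc1_ln1_g, params$enc1_ln1_b,
                             params$enc1_Wq, params$enc1_bq, params$enc1_Wk, params$enc1_bk,
                             params$enc1_Wv, params$enc1_bv, params$enc1_Wo, params$enc1_bo,
                             params$enc1_ln2_g, params$enc1_ln2_b,
                             params$enc1_ff_W1, params$enc1_ff_b1,
                             params$enc1_ff_W2, params$enc1_ff_b2)
  expect_equal(got, want, tolerance = 1e-5)
  # depth 0 is the identity plus the positional embedding
  got0 <- transformer_encode(seq_in, params, depth = 0L, heads = 1L)
  want0 <- seq_in
  for (s in seq_len(S)) want0[s, , ] <- want0[s, , ] + params$pos
  expect_equal(got0, want0, tolerance = 1e-12)
})

test_that("self-attention rows are probability distributions", {
  set.seed(10)
  X <- matrix(rnorm(6 * 4), 6, 4)
  f <- stgate:::mhsa_fwd(X, Tlen = 3L, S = 2L, h = 2L,
                         Wq = matrix(rnorm(16), 4), bq = rnorm(4),
                         Wk = matrix(rnorm(16), 4), bk = rnorm(4),
                         Wv = matrix(rnorm(16), 4), bv = rnorm(4),
                         Wo = matrix(rnorm(16), 4), bo = rnorm(4))
  sums <- apply(f$attn, c(1, 3), sum)  # per query row, per head-sequence
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("TLB output is deterministic in evaluation mode and baseline skips it", {
  cfg <- tiny_cfg("stgate")
  mod <- init_model(cfg, seed = 4)
  x <- rand_x(2, 5, seed = 5)
  expect_identical(tlb_forward(x, mod$params, cfg), tlb_forward(x, mod$params, cfg))
  cfgb <- tiny_cfg("baseline")
  modb <- init_model(cfgb, seed = 4)
  expect_equal(tlb_forward(x, modb$params, cfgb), conv_stack_forward(x, modb$params),
               tolerance = 1e-15)
})

test_that("spatial attention matches the naive loop oracle and Top-K contract", {
  set.seed(20)
  B <- 2L; N <- 5L; C <- 3L; Tr <- 4L
  Xh <- array(rnorm(B * N * C * Tr), c(B, N, C, Tr))
  p <- list(sa_W1 = rnorm(Tr), sa_W2 = matrix(rnorm(C * N), C, N),
            sa_bs = matrix(rnorm(N * N, sd = 0.3), N, N),
            sa_V = matrix(rnorm(N * N, sd = 0.5), N, N),
            sa_bn_g = 1, sa_bn_b = 0)
  got <- spatial_attention(Xh, p, k_top = 3L, train = TRUE)
  want <- oracle_spatial(Xh, p$sa_W1, p$sa_W2, p$sa_bs, p$sa_V, k_top = 3L)
  expect_equal(got$A, want$A, tolerance = 1e-5)
  expect_equal(got$A_pre_topk, want$pre, tolerance = 1e-5)
  expect_true(all(apply(got$A, c(1, 2), function(r) sum(r != 0)) == 3L))
  # zero parameters propagate to a zero (degenerate-guarded) adjacency
  p0 <- list(sa_W1 = rep(0, Tr), sa_W2 = matrix(0, C, N), sa_bs = matrix(0, N, N),
             sa_V = diag(N), sa_bn_g = 1, sa_bn_b = 0)
  got0 <- spatial_attention(Xh, p0, k_top = 3L, train = TRUE)
  expect_true(all(got0$A_pre_topk == 0))
})

test_that("temporal attention and its application match loop oracles", {
  set.seed(21)
  B <- 2L; N <- 5L; C <- 3L; Tr <- 4L
  Xh <- array(rnorm(B * N * C * Tr), c(B, N, C, Tr))
  p <- list(ta_U3 = rnorm(N), ta_U4 = matrix(rnorm(C * Tr), C, Tr),
            ta_bt = matrix(rnorm(Tr * Tr, sd = 0.3), Tr, Tr),
            ta_V = matrix(rnorm(Tr * Tr, sd = 0.5), Tr, Tr),
            ta_bn_g = 1, ta_bn_b = 0)
  got <- temporal_attention(Xh, p, train = TRUE)
  expect_equal(dim(got$That), c(B, Tr, Tr))
  want <- oracle_temporal(Xh, p$ta_U3, p$ta_U4, p$ta_bt, p$ta_V)
  expect_equal(got$That, want, tolerance = 1e-5)
  # zero weights and bias give a zero map
  p0 <- list(ta_U3 = rep(0, N), ta_U4 = matrix(0, C, Tr), ta_bt = matrix(0, Tr, Tr),
             ta_V = diag(Tr), ta_bn_g = 1, ta_bn_b = 0)
  expect_true(all(temporal_attention(Xh, p0, train = TRUE)$That == 0))
  # application: identity and zero maps, then a random map vs triple loop
  idT <- array(0, c(B, Tr, Tr)); for (b in 1:B) idT[b, , ] <- diag(Tr)
  expect_equal(apply_temporal(idT, Xh), Xh, tolerance = 1e-12)
  expect_true(all(apply_temporal(idT * 0, Xh) == 0))
  That <- array(rnorm(B * Tr * Tr), c(B, Tr, Tr))
  expect_equal(apply_temporal(That, Xh), oracle_apply_temporal(That, Xh),
               tolerance = 1e-10)
})

test_that("graph attention matches a brute-force oracle over all pairs", {
  set.seed(22)
  B <- 2L; N <- 3L; Fin <- 2L; G <- 2L
  H <- array(rnorm(B * N * Fin), c(B, N, Fin))
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)  # path graph 1-2-3
  W <- list(matrix(rnorm(Fin * G, sd = 0.5), Fin, G), matrix(rnorm(Fin * G, sd = 0.5), Fin, G))
  a1 <- list(rnorm(G), rnorm(G)); a2 <- list(rnorm(G), rnorm(G))
  got <- gat_layer(H, A, W, a1, a2)
  want <- oracle_gat(H, A, W, a1, a2)
  expect_equal(got$out, want$out, tolerance = 1e-6)
  # attention rows sum to one over each neighborhood, per head
  for (k in 1:2) {
    al <- array(got$alpha[[k]], c(B * N, N))
    expect_true(all(abs(rowSums(al) - 1) < 1e-6))
  }
  # zero attention vectors give uniform coefficients over the neighborhood
  a0 <- list(rep(0, G), rep(0, G))
  gu <- gat_layer(H, A, W[1], a0[1], a0[1])
  al <- array(gu$alpha[[1]], c(B, N, N))
  expect_equal(al[1, 1, ], c(1 / 2, 1 / 2, 0))       # self + one neighbour
  expect_equal(al[1, 2, ], c(1 / 3, 1 / 3, 1 / 3))   # self + two neighbours
  # dynamic (weighted) adjacency against the same oracle
  Ad <- array(rnorm(B * N * N), c(B, N, N))
  Ad[abs(Ad) < 0.5] <- 0
  gd <- gat_layer(H, Ad, W, a1, a2)
  wd <- oracle_gat(H, Ad, W, a1, a2)
  expect_equal(gd$out, wd$out, tolerance = 1e-6)
})

test_that("the network honours the variant wiring of the ablation grid", {
  x <- rand_x(3, 5, seed = 30)
  static_A <- knn_graph(make_montage(6)$coords2d[1:5, ], 2)
  for (v in variant_names()) {
    cfg <- tiny_cfg(v)
    mod <- init_model(cfg, seed = 31)
    fw <- stgate_forward(x, list(params = mod$params, state = mod$state, config = cfg),
                         static_A = static_A)
    expect_equal(dim(fw$logits), c(3L, 3L))
    probs <- exp(fw$logits - stgate:::logsumexp_rows(fw$logits))
    expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
    if (cfg$has_sgat) {
      expect_equal(dim(fw$A_dynamic), c(3L, 5L, 5L))
      expect_true(all(apply(fw$A_dynamic, c(1, 2), function(r) sum(r != 0)) ==
                        min(cfg$k_top, 5L)))
    } else {
      expect_null(fw$A_dynamic)
    }
  }
  # tgat without a static adjacency is a configuration error
  cfg_t <- tiny_cfg("tgat")
  mod_t <- init_model(cfg_t, seed = 31)
  expect_error(stgate_forward(x, list(params = mod_t$params, state = mod_t$state,
                                      config = cfg_t)), "static")
})

test_that("zeroing spatial-attention parameters changes stgate but cannot exist in tgat", {
  x <- rand_x(3, 5, seed = 32)
  static_A <- knn_graph(make_montage(6)$coords2d[1:5, ], 2)
  cfg <- tiny_cfg("stgate")
  mod <- init_model(cfg, seed = 33)
  base <- stgate_forward(x, list(params = mod$params, state = mod$state, config = cfg))
  pz <- mod$params
  for (nm in c("sa_W1", "sa_W2", "sa_bs", "sa_V")) pz[[nm]] <- pz[[nm]] * 0
  zeroed <- stgate_forward(x, list(params = pz, state = mod$state, config = cfg))
  expect_gt(max(abs(zeroed$logits - base$logits)), 1e-8)
  # the tgat variant has no spatial-attention parameters at all
  cfg_t <- tiny_cfg("tgat")
  mod_t <- init_model(cfg_t, seed = 33)
  expect_false(any(grepl("^sa_", names(mod_t$params))))
})

test_that("the full variant's parameters are a strict superset of each ablation's", {
  full <- names(init_model(tiny_cfg("stgate"), seed = 1)$params)
  for (v in setdiff(variant_names(), "stgate")) {
    sub <- names(init_model(tiny_cfg(v), seed = 1)$params)
    expect_true(all(sub %in% full), info = v)
    expect_gt(length(full), length(sub))
  }
})

test_that("gradients reach every parameter group of the active variant", {
  x <- rand_x(4, 5, seed = 40)
  y <- c(1L, 2L, 3L, 1L)
  static_A <- knn_graph(make_montage(6)$coords2d[1:5, ], 2)
  for (v in c("stgate", "tgat_tlb", "sgat", "baseline")) {
    cfg <- tiny_cfg(v)
    mod <- init_model(cfg, seed = 41)
    fw <- stgate:::network_fwd(x, mod$params, cfg, mod$state, train = TRUE,
                               static_A = static_A)
    ce <- stgate:::cross_entropy(fw$logits, y)
    g <- stgate:::network_bwd(fw, mod$params, cfg, ce$dlogits)
    for (nm in names(mod$params)) {
      expect_false(is.null(g[[nm]]), info = paste(v, nm))
      expect_gt(max(abs(g[[nm]])), 0, label = paste(v, nm, "gradient magnitude"))
    }
  }
})

test_that("evaluation-mode forward passes are bitwise repeatable", {
  x <- rand_x(2, 5, seed = 50)
  cfg <- tiny_cfg("stgate")
  mod <- init_model(cfg, seed = 51)
  m <- list(params = mod$params, state = mod$state, config = cfg)
  f1 <- stgate_forward(x, m)
  f2 <- stgate_forward(x, m)
  expect_identical(f1$logits, f2$logits)
  expect_identical(f1$A_dynamic, f2$A_dynamic)
})
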