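test_that("synthetic montage mirrors electrodes on the unit disc", {
  mont <- make_montage(24)
  expect_length(mont$labels, 24L)
  expect_equal(nrow(mont$symmetric_pairs), 12L)
  expect_true(all(sqrt(rowSums(mont$coords2d^2)) <= 1 + 1e-9))
  # left/right pairs mirror in x and share y
  for (p in seq_len(nrow(mont$symmetric_pairs))) {
    l <- mont$symmetric_pairs[p, 1]; r <- mont$symmetric_pairs[p, 2]
    expect_equal(mont$coords2d[l, 1], -mont$coords2d[r, 1])
    expect_equal(mont$coords2d[l, 2], mont$coords2d[r, 2])
  }
  expect_identical(make_montage(24), mont)
  expect_error(make_montage(3), "at least 4")
  expect_error(make_montage(7), "even")
})

test_that("class graphs have the prescribed edge count and expected overlap", {
  spec <- synthetic_spec()
  t1 <- sample_class_graphs(spec, 9)
  for (k in seq_len(spec$n_classes)) {
    G <- t1$class_graphs[[k]]
    expect_equal(sum(G[upper.tri(G)]), spec$edges_per_class)
    expect_identical(G, t(G))
    expect_true(all(diag(G) == 0))
  }
  expect_identical(sample_class_graphs(spec, 9), t1)
  # expected pairwise overlap of two uniform 10-edge graphs on 276 slots
  # is 10 * 10 / 276 ~ 0.362; Monte-Carlo mean within 3 standard errors
  ov <- vapply(1:1000, function(s) {
    tt <- sample_class_graphs(synthetic_spec(n_classes = 2), s)
    sum(tt$class_graphs[[1]] * tt$class_graphs[[2]]) / 2
  }, numeric(1))
  exp_ov <- 10 * 10 / 276
  expect_lt(abs(mean(ov) - exp_ov), 3 * stats::sd(ov) / sqrt(length(ov)))
})

test_that("recordings have the contracted shape and coupling raises correlation", {
  spec <- synthetic_spec(n_channels = 12, trial_seconds = 10)
  truth <- sample_class_graphs(spec, 3)
  rec <- generate_recording(1, 1, 1, spec, truth, seed = 3,
                            montage = make_montage(12))
  expect_equal(dim(rec$data), c(12L, 2000L))
  expect_true(all(is.finite(rec$data)))
  # mean |correlation| over true edges exceeds that over non-edges
  mont <- make_montage(12)
  edge_cor <- function(spec, n_trials, seed0) {
    tr <- sample_class_graphs(spec, 3)
    e_vals <- c(); n_vals <- c()
    for (i in seq_len(n_trials)) {
      r <- generate_recording(1 + i %% 3, 1, i, spec, tr, seed = seed0 + i, montage = mont)
      cm <- abs(stats::cor(t(r$data)))
      G <- tr$class_graphs[[1]]
      ut <- upper.tri(G)
      e_vals <- c(e_vals, cm[ut & G > 0])
      n_vals <- c(n_vals, cm[ut & G == 0])
    }
    c(edge = mean(e_vals), non = mean(n_vals))
  }
  cc <- edge_cor(spec, 30, 100)
  expect_gt(cc["edge"], cc["non"])
  # no coupling: difference statistically indistinguishable (small)
  spec0 <- synthetic_spec(n_channels = 12, trial_seconds = 10, coupling_strength = 0)
  cc0 <- edge_cor(spec0, 30, 200)
  expect_lt(abs(cc0["edge"] - cc0["non"]), 0.02)
})

test_that("coupled-pair correlation contrast grows with coupling strength", {
  mont <- make_montage(12)
  contrast <- vapply(c(0, 0.4, 0.8), function(cs) {
    spec <- synthetic_spec(n_channels = 12, trial_seconds = 10, coupling_strength = cs)
    tr <- sample_class_graphs(spec, 5)
    e_vals <- c(); n_vals <- c()
    for (i in 1:20) {
      r <- generate_recording(1, 1, i, spec, tr, seed = 300 + i, montage = mont)
      cm <- abs(stats::cor(t(r$data)))
      G <- tr$class_graphs[[1]]; ut <- upper.tri(G)
      e_vals <- c(e_vals, cm[ut & G > 0]); n_vals <- c(n_vals, cm[ut & G == 0])
    }
    mean(e_vals) - mean(n_vals)
  }, numeric(1))
  expect_true(all(diff(contrast) > 0))
})

test_that("dataset generation is counted, balanced and reproducible", {
  spec <- micro_spec()
  ds <- generate_dataset(spec, seed = 11)
  expect_length(ds$recordings, 3L * 2L * 2L)
  expect_equal(nrow(ds$manifest), 12L)
  tab <- table(ds$manifest$subject_id, ds$manifest$label)
  expect_true(all(tab == 2L))
  ds2 <- generate_dataset(spec, seed = 11)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$recordings[[5]]$data, ds2$recordings[[5]]$data)
  expect_false(identical(ds$recordings[[1]]$data,
                         generate_dataset(spec, seed = 12)$recordings[[1]]$data))
})

test_that("structure-recovery precision scores the union graph correctly", {
  spec <- synthetic_spec()
  truth <- sample_class_graphs(spec, 21)
  U <- Reduce(`+`, truth$class_graphs)
  n_union <- sum(U[upper.tri(U)] > 0)
  # the union graph itself recovers perfectly
  expect_equal(structure_recovery_score(U, truth, k = n_union), 1.0)
  expect_error(structure_recovery_score(U, truth, k = 1000), "exceeds")
  # random matrices score the union density on average (permutation oracle)
  set.seed(22)
  prec <- vapply(1:1000, function(i) {
    M <- matrix(rnorm(24 * 24), 24); M <- M + t(M)
    structure_recovery_score(M, truth, k = 10)
  }, numeric(1))
  expected <- n_union / (24 * 23 / 2)
  expect_lt(abs(mean(prec) - expected), 3 * stats::sd(prec) / sqrt(length(prec)))
})
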