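test_that("averaged adjacency is symmetric, order-invariant and matches streaming", {
  mc <- micro_cohort()
  cfg <- micro_model_cfg("stgate")
  m <- train(mc$samples, cfg, micro_tcfg(seed = 8, max_epochs = 1L))
  Am <- average_adjacency(m, mc$samples)
  expect_equal(Am, t(Am))
  # single sample: the average is that sample's (symmetrized) adjacency
  one <- list(x = mc$samples$x[1, , , , drop = FALSE], y = mc$samples$y[1])
  A1 <- average_adjacency(m, one)
  x1 <- stgate:::apply_standardizer(one$x, m$standardizer)
  fw <- stgate:::network_fwd(x1, m$params, m$config, m$state, train = FALSE)
  expect_equal(A1, (fw$A_pre_topk[1, , ] + t(fw$A_pre_topk[1, , ])) / 2,
               tolerance = 1e-12)
  # streaming one-at-a-time accumulation agrees with the batched mean
  acc <- matrix(0, 8, 8)
  for (i in seq_along(mc$samples$y)) {
    acc <- acc + average_adjacency(m, list(x = mc$samples$x[i, , , , drop = FALSE],
                                           y = mc$samples$y[i]))
  }
  expect_equal(acc / length(mc$samples$y), Am, tolerance = 1e-6)
  # order invariance
  perm <- rev(seq_along(mc$samples$y))
  Ap <- average_adjacency(m, list(x = mc$samples$x[perm, , , , drop = FALSE],
                                  y = mc$samples$y[perm]))
  expect_equal(Ap, Am, tolerance = 1e-9)
  # variants without spatial attention cannot be averaged
  mb <- train(mc$samples, micro_model_cfg("baseline"), micro_tcfg(seed = 8, max_epochs = 0L))
  expect_error(average_adjacency(mb, mc$samples), "spatial attention")
})

test_that("global top-edge selection is exact and bounded", {
  set.seed(30)
  M <- matrix(rnorm(16), 4); M <- (M + t(M)) / 2; diag(M) <- 0
  rownames(M) <- colnames(M) <- paste0("E", 1:4)
  top <- top_edges_global(M, n = 3)
  # brute force: rank all upper-triangle entries
  ut <- which(upper.tri(M), arr.ind = TRUE)
  ord <- order(M[ut], decreasing = TRUE)
  expect_equal(top$edges$weight, M[ut][ord][1:3])
  expect_equal(sum(top$matrix[upper.tri(top$matrix)] != 0), 3L)
  # keeping all pairs is the identity on the off-diagonal
  all6 <- top_edges_global(M, n = 6)
  expect_equal(all6$matrix[upper.tri(all6$matrix)], M[upper.tri(M)])
  expect_error(top_edges_global(M, n = 7), "must be in")
  # default n = 10 retains exactly ten entries
  big <- matrix(rnorm(24 * 24), 24); big <- (big + t(big)) / 2; diag(big) <- 0
  t10 <- top_edges_global(big)
  expect_equal(sum(t10$matrix[upper.tri(t10$matrix)] != 0), 10L)
})

test_that("topographic export writes a consistent table whose round trip is exact", {
  mont <- make_montage(8)
  edges <- data.frame(label_i = c("E01", "E03"), label_j = c("E02", "E05"),
                      weight = c(1.5, 0.25), stringsAsFactors = FALSE)
  path <- file.path(tempdir(), "topo_test")
  res <- export_topomap(edges, mont, path)
  tab <- read.delim(res$table, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab, edges)
  # empty edge list still writes a header-only table
  res0 <- export_topomap(edges[0, ], mont, file.path(tempdir(), "topo_empty"))
  tab0 <- read.delim(res0$table, stringsAsFactors = FALSE)
  expect_equal(nrow(tab0), 0L)
  expect_equal(names(tab0), c("label_i", "label_j", "weight"))
  expect_error(export_topomap(data.frame(label_i = "ZZ", label_j = "E01", weight = 1),
                              mont, file.path(tempdir(), "topo_bad")), "unknown electrode")
})
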