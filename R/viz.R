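#' Average the learned dynamic adjacency over a dataset
#'
#' Runs the model in evaluation mode over all samples and averages the
#' per-sample dynamic adjacency elementwise, then symmetrizes as
#' `(A + t(A)) / 2`. By default the standardized pre-Top-K scores are
#' averaged (Top-K averaging would bias toward frequently selected but weak
#' edges); set `pre_topk = FALSE` to average the sparsified matrices.
#'
#' @param model A trained `stgate_model` whose variant includes spatial
#'   attention.
#' @param samples Sample list from [build_samples()].
#' @param pre_topk Average pre-Top-K standardized scores (default TRUE).
#' @param batch_size Forward-pass batch size.
#' @return Symmetric N x N matrix.
#' @export
average_adjacency <- function(model, samples, pre_topk = TRUE, batch_size = 32L) {
  cfg <- model$config
  if (!cfg$has_sgat) {
    stop_config("variant '%s' has no spatial attention; no dynamic adjacency to average",
                cfg$variant)
  }
  x <- samples$x
  if (!is.null(model$standardizer)) x <- apply_standardizer(x, model$standardizer)
  S <- dim(x)[1]; N <- dim(x)[2]
  acc <- matrix(0, N, N); total <- 0L
  for (b in seq_len(ceiling(S / batch_size))) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, S)
    fw <- network_fwd(x[idx, , , , drop = FALSE], model$params, cfg, model$state,
                      train = FALSE, static_A = model$static_A)
    A <- if (pre_topk) fw$A_pre_topk else fw$A_dynamic
    for (i in seq_along(idx)) acc <- acc + A[i, , ]
    total <- total + length(idx)
  }
  Am <- acc / total
  (Am + t(Am)) / 2
}

#' Globally strongest edges of an averaged adjacency
#'
#' Selects the `n` largest upper-triangle entries globally (distinct from
#' the per-row Top-K used inside the network) and zeroes the rest.
#'
#' @param A_mean Symmetric N x N matrix.
#' @param n Number of edges to keep (default 10).
#' @param labels Optional channel labels (defaults to dimnames or indices).
#' @return List with `edges` (data frame: label_i, label_j, weight, ranked
#'   decreasing) and `matrix` (A_mean with all other entries zeroed).
#' @export
top_edges_global <- function(A_mean, n = 10L, labels = NULL) {
  N <- nrow(A_mean)
  stopifnot(ncol(A_mean) == N)
  if (max(abs(A_mean - t(A_mean))) > 1e-8) stop_config("A_mean must be symmetric")
  npairs <- N * (N - 1) / 2
  if (n < 1L || n > npairs) stop_config("n must be in 1..%d", npairs)
  if (is.null(labels)) labels <- rownames(A_mean) %||% as.character(seq_len(N))
  ut <- which(upper.tri(A_mean), arr.ind = TRUE)
  vals <- A_mean[ut]
  ord <- order(vals, decreasing = TRUE)[seq_len(n)]
  keep <- ut[ord, , drop = FALSE]
  M <- matrix(0, N, N, dimnames = dimnames(A_mean))
  M[keep] <- A_mean[keep]
  M[keep[, c(2, 1), drop = FALSE]] <- A_mean[keep]
  edges <- data.frame(label_i = labels[keep[, 1]], label_j = labels[keep[, 2]],
                      weight = vals[ord], stringsAsFactors = FALSE)
  list(edges = edges, matrix = M)
}

#' Export a topographic map of adjacency edges
#'
#' Writes a tab-separated edge table and a vector-graphics scalp plot
#' (electrodes at their 2-D positions, edge line width proportional to
#' weight). The table is written first, so a plotting failure never
#' corrupts it.
#'
#' @param edges Edge data frame from [top_edges_global()] (columns label_i,
#'   label_j, weight).
#' @param montage An [electrode_montage()] covering all edge labels.
#' @param path Output path stem; writes `<path>.tsv` and `<path>.svg`
#'   (falls back to `<path>.pdf` if SVG is unavailable).
#' @return Invisibly, a list with `table` and `plot` file paths (`plot` is
#'   `NA` if plotting failed).
#' @export
export_topomap <- function(edges, montage, path) {
  stopifnot(is.data.frame(edges), all(c("label_i", "label_j", "weight") %in% names(edges)))
  unknown <- setdiff(c(edges$label_i, edges$label_j), montage$labels)
  if (length(unknown)) stop_config("unknown electrode label(s): %s", paste(unknown, collapse = ", "))
  tsv <- paste0(path, ".tsv")
  utils::write.table(edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  plot_path <- NA_character_
  draw <- function() {
    xy <- montage$coords2d
    r <- max(sqrt(rowSums(xy^2))) * 1.15 + 1e-9
    graphics::plot(NA, xlim = c(-r, r) * 1.1, ylim = c(-r, r) * 1.2, asp = 1,
                   axes = FALSE, xlab = "", ylab = "", main = "Averaged adjacency: strongest edges")
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(r * cos(th), r * sin(th))
    graphics::lines(c(-0.08, 0, 0.08) * r, c(1, 1.12, 1) * r)  # nose marker
    if (nrow(edges)) {
      wmax <- max(abs(edges$weight))
      for (i in seq_len(nrow(edges))) {
        a <- match(edges$label_i[i], montage$labels)
        b <- match(edges$label_j[i], montage$labels)
        lw <- 0.5 + 4 * abs(edges$weight[i]) / max(wmax, 1e-12)
        graphics::segments(xy[a, 1], xy[a, 2], xy[b, 1], xy[b, 2],
                           lwd = lw, col = "#d95f02")
      }
    }
    graphics::points(xy[, 1], xy[, 2], pch = 21, bg = "white", cex = 1.4)
    graphics::text(xy[, 1], xy[, 2], montage$labels, cex = 0.45)
  }
  ok <- tryCatch({
    svg_path <- paste0(path, ".svg")
    grDevices::svg(svg_path, width = 6, height = 6)
    draw()
    grDevices::dev.off()
    plot_path <<- svg_path
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    ok2 <- tryCatch({
      pdf_path <- paste0(path, ".pdf")
      grDevices::pdf(pdf_path, width = 6, height = 6)
      draw()
      grDevices::dev.off()
      plot_path <<- pdf_path
      TRUE
    }, error = function(e) FALSE)
    if (!ok2) warning("plot device unavailable; edge table written anyway")
  }
  invisible(list(table = tsv, plot = plot_path))
}
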