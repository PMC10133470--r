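#' Synthetic cohort specification
#'
#' Parameters of the synthetic EEG generator. The defaults describe the
#' standard study cohort: 8 subjects, 24 channels at 200 Hz, 3 classes with
#' 6 trials each of 20 s, class identity carried by 10 coupled channel pairs
#' per class at coupling strength 0.8, with log-normal per-subject channel
#' gains (sd 0.2) and additive subject noise (sd 0.5).
#'
#' @param n_subjects,n_channels,rate,trials_per_class,n_classes,trial_seconds
#'   Cohort geometry.
#' @param coupling_strength Amplitude of the shared band-limited oscillator
#'   injected into both endpoints of a coupled pair.
#' @param subject_gain_sd Log-scale sd of per-subject, per-channel gains.
#' @param subject_noise_sd Sd of additive white subject noise.
#' @param edges_per_class Coupled pairs per class graph.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_subjects = 8L, n_channels = 24L, rate = 200,
                           trials_per_class = 6L, n_classes = 3L,
                           trial_seconds = 20, coupling_strength = 0.8,
                           subject_gain_sd = 0.2, subject_noise_sd = 0.5,
                           edges_per_class = 10L) {
  stopifnot(n_subjects >= 1, n_channels >= 4, rate > 0, trials_per_class >= 1,
            n_classes >= 2, trial_seconds > 0, coupling_strength >= 0,
            subject_gain_sd >= 0, subject_noise_sd >= 0, edges_per_class >= 1)
  if (edges_per_class > n_channels * (n_channels - 1) / 2) {
    stop_config("edges_per_class exceeds the number of available pairs")
  }
  structure(list(n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
                 rate = rate, trials_per_class = as.integer(trials_per_class),
                 n_classes = as.integer(n_classes), trial_seconds = trial_seconds,
                 coupling_strength = coupling_strength,
                 subject_gain_sd = subject_gain_sd, subject_noise_sd = subject_noise_sd,
                 edges_per_class = as.integer(edges_per_class)),
            class = "synthetic_spec")
}

#' Synthetic electrode montage on a unit disc
#'
#' Places `n` electrodes (n even, >= 4) on concentric rings of the unit
#' disc, mirrored left/right. Labels carry odd (left) / even (right)
#' suffixes so symmetric pairs are derivable by label mirroring.
#'
#' @param n_channels Even channel count >= 4.
#' @return An [electrode_montage()] with `n/2` symmetric pairs.
#' @export
make_montage <- function(n_channels) {
  n <- as.integer(n_channels)
  if (n < 4L) stop_config("need at least 4 channels")
  if (n %% 2L != 0L) stop_config("n_channels must be even for mirrored pairs")
  npairs <- n %/% 2L
  nrings <- max(1L, ceiling(npairs / 4L))
  per_ring <- ceiling(npairs / nrings)
  labels <- character(n); coords <- matrix(0, n, 2)
  pidx <- 0L
  for (r in seq_len(nrings)) {
    radius <- r / (nrings + 0.5)
    in_ring <- min(per_ring, npairs - pidx)
    if (in_ring <= 0L) break
    for (j in seq_len(in_ring)) {
      pidx <- pidx + 1L
      # mirrored pair at polar angle theta from the vertical axis
      theta <- pi * (j - 0.5) / in_ring / 2
      xl <- -radius * sin(theta); yl <- radius * cos(theta)
      li <- 2L * pidx - 1L; ri <- 2L * pidx
      labels[li] <- sprintf("E%02d", li)
      labels[ri] <- sprintf("E%02d", ri)
      coords[li, ] <- c(xl, yl)
      coords[ri, ] <- c(-xl, yl)
    }
  }
  electrode_montage(labels, coords)
}

#' Sample per-class ground-truth coupling graphs
#'
#' Each class receives `edges_per_class` distinct undirected edges drawn
#' uniformly without replacement; classes are drawn independently, so
#' overlap between class graphs is possible and simply recorded.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A `ground_truth`: list with `class_graphs` (list of binary
#'   symmetric N x N matrices), `class_edges` (E x 2 index matrices),
#'   `edge_bands` (band index per edge) and `seed`.
#' @export
sample_class_graphs <- function(spec, seed = 1L) {
  set.seed(seed)
  N <- spec$n_channels
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  graphs <- vector("list", spec$n_classes)
  edges <- vector("list", spec$n_classes)
  bands <- vector("list", spec$n_classes)
  for (k in seq_len(spec$n_classes)) {
    sel <- sample.int(nrow(pairs), spec$edges_per_class)
    e <- pairs[sel, , drop = FALSE]
    G <- matrix(0L, N, N)
    G[e] <- 1L; G[e[, c(2, 1), drop = FALSE]] <- 1L
    graphs[[k]] <- G
    edges[[k]] <- e
    # class signal rides on the emotion-relevant high bands: alpha/beta/gamma
    bands[[k]] <- ((seq_len(nrow(e)) - 1L) %% 3L) + 1L
  }
  structure(list(class_graphs = graphs, class_edges = edges,
                 edge_bands = bands, seed = as.integer(seed)),
            class = "ground_truth")
}

# band edges for the latent oscillators (alpha, beta, low gamma)
latent_band_edges <- function(rate) {
  list(c(8, 13), c(14, 30), c(31, min(45, 0.45 * rate)))
}

# 1/f-shaped background noise via spectral shaping of white noise
pink_noise <- function(n, rate) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f * 0)  # one-sided magnitudes handled by symmetry below
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1] <- 0
  half <- floor(n / 2)
  if (half > 1) shape[(n - half + 2):n] <- shape[seq(half, 2)]
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

band_limited_noise <- function(n, rate, edges) {
  bf <- band_filter(rate, edges[1], edges[2])
  x <- iir_filtfilt_cpp(bf$b, bf$a, stats::rnorm(n))
  s <- stats::sd(x)
  if (s < 1e-12) x else x / s
}

#' Generate one synthetic recording
#'
#' Each channel is 1/f background noise plus shared band-limited latent
#' oscillators: every edge of the class's coupling graph carries one latent
#' (alpha, beta or gamma band) added to both endpoint channels with
#' amplitude `coupling_strength`. The whole channel is then scaled by a
#' per-subject log-normal gain and corrupted by subject-specific white
#' noise, so coupled pairs show elevated band-limited coherence and class
#' identity is encoded in which channels and bands carry extra power.
#'
#' @param subject Subject index (1-based).
#' @param class_k Class index (1-based).
#' @param trial Trial index within subject and class.
#' @param spec A [synthetic_spec()].
#' @param truth A `ground_truth` from [sample_class_graphs()].
#' @param seed Integer seed; every (subject, class, trial) combination maps
#'   to a distinct deterministic RNG stream.
#' @param montage Montage supplying channel labels.
#' @return A [raw_recording()].
#' @export
generate_recording <- function(subject, class_k, trial, spec, truth, seed = 1L,
                               montage = make_montage(spec$n_channels)) {
  if (class_k > spec$n_classes) stop_config("class %d out of range", class_k)
  n <- as.integer(round(spec$trial_seconds * spec$rate))
  N <- spec$n_channels
  # distinct stream per (seed, subject, class, trial); subject gains drawn
  # from a subject-only stream so they are stable across trials
  set.seed((seed * 131L + subject) %% .Machine$integer.max)
  gains <- exp(stats::rnorm(N, 0, spec$subject_gain_sd))
  set.seed((seed * 7919L + subject * 1009L + class_k * 101L + trial) %% .Machine$integer.max)
  X <- matrix(0, N, n)
  for (ch in seq_len(N)) X[ch, ] <- pink_noise(n, spec$rate)
  edges <- truth$class_edges[[class_k]]
  bands <- latent_band_edges(spec$rate)
  for (ei in seq_len(nrow(edges))) {
    z <- band_limited_noise(n, spec$rate, bands[[truth$edge_bands[[class_k]][ei]]])
    i <- edges[ei, 1]; j <- edges[ei, 2]
    X[i, ] <- X[i, ] + spec$coupling_strength * z
    X[j, ] <- X[j, ] + spec$coupling_strength * z
  }
  X <- X * gains
  if (spec$subject_noise_sd > 0) {
    X <- X + matrix(stats::rnorm(N * n, 0, spec$subject_noise_sd), N, n)
  }
  raw_recording(X, spec$rate, montage$labels,
                subject_id = sprintf("S%02d", subject),
                trial_id = sprintf("S%02d_c%d_t%d", subject, class_k, trial),
                label = class_k)
}

#' Generate a full synthetic cohort
#'
#' `n_subjects x n_classes x trials_per_class` recordings plus the ground
#' truth and a manifest data frame. Fully seeded and deterministic.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List with `recordings`, `truth`, `manifest` (data frame:
#'   subject_id, trial_id, label), `montage`, `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), seed = 1L) {
  truth <- sample_class_graphs(spec, seed)
  montage <- make_montage(spec$n_channels)
  recs <- list()
  rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (k in seq_len(spec$n_classes)) {
      for (t in seq_len(spec$trials_per_class)) {
        rec <- generate_recording(s, k, t, spec, truth, seed = seed, montage = montage)
        recs[[length(recs) + 1L]] <- rec
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = rec$subject_id, trial_id = rec$trial_id,
          label = rec$label, stringsAsFactors = FALSE)
      }
    }
  }
  list(recordings = recs, truth = truth, manifest = do.call(rbind, rows),
       montage = montage, spec = spec)
}

#' Structure-recovery precision of an averaged adjacency
#'
#' Fraction of the k strongest off-diagonal (upper-triangle) entries of the
#' symmetrized averaged adjacency that are true edges of the union of the
#' class coupling graphs.
#'
#' @param A_mean N x N averaged adjacency (symmetrized internally).
#' @param truth A `ground_truth`.
#' @param k Number of top entries scored (default 10).
#' @return Precision in `[0, 1]`.
#' @export
structure_recovery_score <- function(A_mean, truth, k = 10L) {
  N <- nrow(A_mean)
  stopifnot(ncol(A_mean) == N)
  npairs <- N * (N - 1) / 2
  if (k > npairs) stop_config("k = %d exceeds the %d available pairs", k, npairs)
  As <- (A_mean + t(A_mean)) / 2
  ut <- which(upper.tri(As), arr.ind = TRUE)
  vals <- As[ut]
  top <- ut[order(vals, decreasing = TRUE)[seq_len(k)], , drop = FALSE]
  U <- Reduce(`+`, truth$class_graphs)
  mean(U[top] > 0)
}
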