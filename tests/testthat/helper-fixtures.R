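# Shared fixtures. Everything is generated in code; the micro-cohort is
# memoized so several test files can reuse it without regenerating.

.fixture_env <- new.env(parent = emptyenv())

tiny_cfg <- function(variant = "stgate", n_channels = 5L, n_classes = 3L) {
  model_config(variant, n_classes = n_classes, n_channels = n_channels,
               t_in = 10L, conv_channels = 8L, depth = 1L, heads = 2L,
               gat_heads = 2L, gat_out = 6L, k_top = 3L, k_nn = 2L, dropout = 0)
}

rand_x <- function(B, N, F = 5L, T = 10L, seed = 1L) {
  set.seed(seed)
  array(stats::rnorm(B * N * F * T), c(B, N, F, T))
}

sine_recording <- function(freq, rate = 200, seconds = 5, n_channels = 2L,
                           noise_sd = 0, label = 1L) {
  t <- seq(0, seconds - 1 / rate, by = 1 / rate)
  base <- sin(2 * pi * freq * t)
  data <- matrix(rep(base, n_channels), nrow = n_channels, byrow = TRUE)
  if (noise_sd > 0) data <- data + matrix(stats::rnorm(length(data), 0, noise_sd),
                                          nrow = n_channels)
  raw_recording(data, rate, sprintf("E%02d", seq_len(n_channels)),
                subject_id = "S01", trial_id = "t1", label = label)
}

micro_spec <- function() {
  synthetic_spec(n_subjects = 3L, n_channels = 8L, trials_per_class = 2L,
                 n_classes = 2L, trial_seconds = 20)
}

micro_cohort <- function() {
  if (is.null(.fixture_env$micro)) {
    spec <- micro_spec()
    ds <- generate_dataset(spec, seed = 42L)
    tensors <- lapply(ds$recordings, extract_features, cfg = feature_config("DE"))
    samples <- build_samples(tensors, t_in = 10L)
    .fixture_env$micro <- list(ds = ds, tensors = tensors, samples = samples)
  }
  .fixture_env$micro
}

micro_model_cfg <- function(variant = "stgate") {
  model_config(variant, n_classes = 2L, n_channels = 8L, t_in = 10L,
               conv_channels = 8L, depth = 1L, heads = 2L, gat_heads = 2L,
               gat_out = 8L, k_top = 3L, k_nn = 3L, dropout = 0.3)
}

micro_tcfg <- function(seed = 1L, max_epochs = 30L) {
  train_config(learning_rate = 1e-3, batch_size = 16L, loss_stop_threshold = 0.15,
               max_epochs = max_epochs, seed = seed)
}
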