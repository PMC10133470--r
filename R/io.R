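#' Write a feature store
#'
#' One array file per trial (RDS, bit-exact round trip) plus a tab-separated
#' manifest with columns subject_id, trial_id, label, path, feature_kind,
#' bands, window_seconds.
#'
#' @param tensors List of `feature_tensor` objects with consistent shapes
#'   and bands.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest file.
#' @export
write_feature_store <- function(tensors, dir) {
  stopifnot(length(tensors) > 0)
  dims <- dim(tensors[[1]]$values)[-1]
  kinds <- unique(vapply(tensors, function(t) t$feature_kind, character(1)))
  if (length(kinds) != 1L) stop_config("mixed feature kinds in one store: %s", paste(kinds, collapse = ", "))
  for (t in tensors) {
    if (!identical(dim(t$values)[-1], dims)) {
      stop_config("tensor shape drift at trial %s", t$trial_id)
    }
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(tensors, function(t) {
    fn <- sprintf("%s_%s.rds", t$subject_id, t$trial_id)
    saveRDS(t$values, file.path(dir, fn))
    data.frame(subject_id = t$subject_id, trial_id = t$trial_id, label = t$label,
               path = fn, feature_kind = t$feature_kind,
               bands = paste(t$band_names, collapse = ","),
               window_seconds = t$window_seconds, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mpath
}

#' Read a feature store
#'
#' @param dir Directory written by [write_feature_store()].
#' @return List with `tensors` (list of `feature_tensor`) and `manifest`.
#' @export
read_feature_store <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop_config("no manifest.tsv in %s", dir)
  manifest <- utils::read.table(mpath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE, colClasses = "character")
  manifest$label <- as.integer(manifest$label)
  manifest$window_seconds <- as.numeric(manifest$window_seconds)
  tensors <- vector("list", nrow(manifest))
  shape <- NULL
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$path[i])
    if (!file.exists(f)) stop_config("missing array file %s (trial %s)", f, manifest$trial_id[i])
    vals <- tryCatch(readRDS(f), error = function(e) {
      stop_config("corrupted array file %s (trial %s)", f, manifest$trial_id[i])
    })
    if (!is.array(vals) || length(dim(vals)) != 3L) {
      stop_config("corrupted array file %s (trial %s)", f, manifest$trial_id[i])
    }
    if (is.null(shape)) shape <- dim(vals)[-1]
    else if (!identical(dim(vals)[-1], shape)) {
      stop_config("shape drift in %s (trial %s)", f, manifest$trial_id[i])
    }
    tensors[[i]] <- structure(list(
      values = vals, band_names = strsplit(manifest$bands[i], ",")[[1]],
      window_seconds = manifest$window_seconds[i],
      subject_id = manifest$subject_id[i], trial_id = manifest$trial_id[i],
      label = manifest$label[i], feature_kind = manifest$feature_kind[i]
    ), class = "feature_tensor")
  }
  list(tensors = tensors, manifest = manifest)
}

# ---- run configuration -----------------------------------------------------

default_run_config <- function() {
  list(
    feature_kind = "DE", window_seconds = 1.0, t_in = 10L,
    variant = "stgate", conv_channels = 32L, depth = 2L, heads = 4L,
    gat_heads = 4L, gat_out = 32L, k_top = 10L, k_nn = 10L, dropout = 0.3,
    learning_rate = 1e-5, batch_size = 16L, loss_stop_threshold = 0.15,
    max_epochs = 200L, seed = 1L
  )
}

config_ranges <- list(
  feature_kind = c("DE", "PSD", "DASM", "RASM", "ASM"),
  variant = NULL  # validated against variant_names()
)

#' Load a run configuration
#'
#' Reads a YAML key-value file, overlaying it on the default configuration
#' (the reference training protocol: learning rate 1e-5, batch 16, dropout
#' 0.3, Top-K 10, loss stop 0.15). Unknown keys and out-of-range values are
#' rejected with messages naming the key.
#'
#' @param path Path to a YAML file; an empty or missing-keys file yields
#'   the full default configuration.
#' @return Named list of validated settings.
#' @export
load_config <- function(path) {
  defaults <- default_run_config()
  user <- if (file.size(path) == 0) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  num_pos <- c("window_seconds", "learning_rate", "loss_stop_threshold")
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) stop_config("config key '%s' must be a positive number", k)
  }
  int_pos <- c("t_in", "conv_channels", "depth", "heads", "gat_heads", "gat_out",
               "k_top", "k_nn", "batch_size", "max_epochs", "seed")
  for (k in int_pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] != round(cfg[[k]])) {
      stop_config("config key '%s' must be a non-negative integer", k)
    }
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  if (!is.numeric(cfg$dropout) || cfg$dropout < 0 || cfg$dropout >= 1) {
    stop_config("config key 'dropout' must be in [0, 1)")
  }
  if (!cfg$feature_kind %in% config_ranges$feature_kind) {
    stop_config("config key 'feature_kind' must be one of %s",
                paste(config_ranges$feature_kind, collapse = ", "))
  }
  if (!cfg$variant %in% variant_names()) {
    stop_config("config key 'variant' must be one of %s", paste(variant_names(), collapse = ", "))
  }
  cfg
}

#' Serialize a run configuration
#' @param cfg Configuration list from [load_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# ---- checkpointing ---------------------------------------------------------

#' Save a trained model checkpoint
#'
#' Parameter store (RDS) plus a JSON sidecar recording the variant, class
#' count, channel count and architecture settings.
#'
#' @param model A `stgate_model`.
#' @param path Path stem; writes `<path>.rds` and `<path>.json`.
#' @return Invisibly, the two paths.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, paste0(path, ".rds"))
  side <- model$config[c("variant", "n_classes", "n_channels", "n_bands", "t_in",
                         "conv_channels", "depth", "heads", "gat_heads", "gat_out",
                         "k_top", "k_nn", "dropout")]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(params = paste0(path, ".rds"), sidecar = paste0(path, ".json")))
}

#' Load a model checkpoint
#' @param path Path stem used in [save_checkpoint()].
#' @return The `stgate_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(paste0(path, ".rds"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar)
    if (!identical(as.character(side$variant), model$config$variant)) {
      stop_config("checkpoint sidecar variant (%s) disagrees with parameters (%s)",
                  side$variant, model$config$variant)
    }
  }
  model
}

#' Read a recording from an EDF file
#'
#' Minimal European-Data-Format reader for continuous (EDF, not EDF+D)
#' recordings: parses the fixed-width header and 2-byte little-endian
#' samples, applies the per-channel physical scaling, and selects channels
#' by label.
#'
#' @param path EDF file path.
#' @param channels Optional character vector of channel labels to keep.
#' @param subject_id,trial_id,label Metadata attached to the result.
#' @return A [raw_recording()].
#' @export
read_edf <- function(path, channels = NULL, subject_id = "edf", trial_id = basename(path),
                     label = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8)                                   # version
  hdr(80); hdr(80); hdr(8); hdr(8)         # patient, recording, date, time
  nbytes <- as.integer(hdr(8))
  hdr(44)
  ndr <- as.integer(hdr(8))
  dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  labs <- trimws(vapply(seq_len(ns), function(i) hdr(16), character(1)))
  for (i in seq_len(ns)) hdr(80)           # transducer
  for (i in seq_len(ns)) hdr(8)            # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  for (i in seq_len(ns)) hdr(80)           # prefiltering
  nsamp <- as.integer(vapply(seq_len(ns), function(i) hdr(8), character(1)))
  for (i in seq_len(ns)) hdr(32)           # reserved
  if (length(unique(nsamp)) != 1L) stop_config("mixed per-record sample counts are not supported")
  rate <- nsamp[1] / dur
  data <- matrix(0, ns, ndr * nsamp[1])
  for (r in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE, endian = "little")
      scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      data[i, ((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <- (raw - dmin[i]) * scale + pmin[i]
    }
  }
  rownames(data) <- labs
  if (!is.null(channels)) {
    missing <- setdiff(channels, labs)
    if (length(missing)) stop_config("channel(s) not in EDF: %s", paste(missing, collapse = ", "))
    data <- data[channels, , drop = FALSE]
    labs <- channels
  }
  raw_recording(data, rate, labs, subject_id, trial_id, label)
}
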