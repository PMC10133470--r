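#' Feature extraction configuration
#'
#' @param feature_kind One of `"DE"`, `"PSD"`, `"DASM"`, `"RASM"`, `"ASM"`.
#' @param bands List of [band_spec()]; defaults to the five canonical bands.
#' @param window_seconds Analysis window length in seconds (default 1, the
#'   common convention for DE features).
#' @param stride_seconds Hop between window starts; defaults to
#'   `window_seconds` (non-overlapping windows).
#' @param smoothing Optional moving-average length (in windows) applied along
#'   the time axis after extraction; `NULL` (default) disables smoothing.
#' @param var_floor Variance floor applied before logarithms (default 1e-12).
#' @return A `feature_config` object.
#' @export
feature_config <- function(feature_kind = c("DE", "PSD", "DASM", "RASM", "ASM"),
                           bands = default_bands(),
                           window_seconds = 1.0,
                           stride_seconds = window_seconds,
                           smoothing = NULL,
                           var_floor = 1e-12) {
  feature_kind <- match.arg(feature_kind)
  if (window_seconds <= 0) stop_config("window_seconds must be positive")
  if (stride_seconds <= 0) stop_config("stride_seconds must be positive")
  if (!length(bands)) stop_config("at least one band is required")
  if (!is.null(smoothing)) stopifnot(smoothing >= 1)
  structure(list(feature_kind = feature_kind, bands = bands,
                 window_seconds = window_seconds, stride_seconds = stride_seconds,
                 smoothing = smoothing, var_floor = var_floor),
            class = "feature_config")
}

# Cache of Butterworth coefficients keyed by (rate, low, high).
.filter_cache <- new.env(parent = emptyenv())

band_filter <- function(rate, low, high) {
  key <- paste(rate, low, high, sep = "|")
  bf <- .filter_cache[[key]]
  if (is.null(bf)) {
    nyq <- rate / 2
    bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
    .filter_cache[[key]] <- bf
  }
  bf
}

#' Decompose a recording into frequency bands
#'
#' Applies a zero-phase (forward-backward) order-4 Butterworth band-pass per
#' band, so band energy is not time-shifted relative to the input. Open-ended
#' bands are capped at 0.45 x the sampling rate.
#'
#' @param rec A [raw_recording()].
#' @param bands List of [band_spec()].
#' @return A 3-D array, channels x samples x bands, with band names on the
#'   third dimension.
#' @export
bandpass_decompose <- function(rec, bands = default_bands()) {
  stopifnot(inherits(rec, "raw_recording"))
  check_finite(rec$data, "recording data")
  nch <- nrow(rec$data); ns <- ncol(rec$data)
  out <- array(0, c(nch, ns, length(bands)),
               dimnames = list(rec$channel_labels, NULL, band_names(bands)))
  for (bi in seq_along(bands)) {
    edges <- resolve_band(bands[[bi]], rec$rate)
    bf <- band_filter(rec$rate, edges["low"], edges["high"])
    for (ci in seq_len(nch)) {
      out[ci, , bi] <- iir_filtfilt_cpp(bf$b, bf$a, rec$data[ci, ])
    }
  }
  out
}

#' Cut a signal into fixed-length windows
#'
#' Windows start every `stride_seconds`; a trailing partial window is
#' discarded. Returns an empty list (with a warning) when the signal is
#' shorter than one window.
#'
#' @param signal_mat Channels x samples numeric matrix.
#' @param rate Sampling rate in Hz.
#' @param window_seconds,stride_seconds Window length and hop in seconds.
#' @return List of channels x window-samples matrices.
#' @export
segment_windows <- function(signal_mat, rate, window_seconds = 1.0,
                            stride_seconds = window_seconds) {
  stopifnot(is.matrix(signal_mat))
  win <- as.integer(round(window_seconds * rate))
  stride <- as.integer(round(stride_seconds * rate))
  if (win < 2L) stop_config("window of %d samples is too short (need >= 2)", win)
  if (stride < 1L) stop_config("stride must be at least one sample")
  ns <- ncol(signal_mat)
  if (ns < win) {
    warning(sprintf("signal (%d samples) shorter than one window (%d samples); no windows produced",
                    ns, win))
    return(list())
  }
  nwin <- (ns - win) %/% stride + 1L
  starts <- (seq_len(nwin) - 1L) * stride + 1L
  lapply(starts, function(s) signal_mat[, s:(s + win - 1L), drop = FALSE])
}

#' Differential entropy of a window (Gaussian assumption)
#'
#' `0.5 * log(2 * pi * e * var(x))` in nats, the standard closed form for a
#' band-filtered EEG window under a Gaussian model. The variance is floored
#' at `var_floor` before the logarithm so degenerate (constant) windows give
#' a finite value.
#'
#' @param window Numeric vector, length >= 2.
#' @param var_floor Variance floor (default 1e-12).
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(window, var_floor = 1e-12) {
  stopifnot(length(window) >= 2L)
  v <- stats::var(window)
  if (v < var_floor) {
    warning("degenerate (near-constant) window: variance floored", call. = FALSE)
    v <- var_floor
  }
  0.5 * log(2 * pi * exp(1) * v)
}

#' Band power of a window (periodogram average)
#'
#' Mean periodogram power over the frequency bins falling in `[low, high)`;
#' returned on the natural-log scale by default.
#'
#' @param window Numeric vector, length >= 8.
#' @param rate Sampling rate in Hz.
#' @param band A [band_spec()].
#' @param log Take `log(power + eps)` (default `TRUE`).
#' @param eps Additive guard inside the logarithm.
#' @return Scalar band power (log scale unless `log = FALSE`).
#' @export
power_spectral_density <- function(window, rate, band, log = TRUE, eps = 1e-12) {
  n <- length(window)
  stopifnot(n >= 8L)
  edges <- resolve_band(band, rate)
  sp <- Mod(stats::fft(window))^2 / n
  freqs <- (seq_len(n) - 1L) * rate / n
  keep <- freqs >= edges["low"] & freqs < edges["high"] & freqs <= rate / 2
  if (!any(keep)) {
    stop_config("band '%s' contains no frequency bin at n=%d, rate=%g Hz", band$name, n, rate)
  }
  p <- mean(sp[keep])
  if (log) log(p + eps) else p
}

#' Hemispheric asymmetry features from DE tensors
#'
#' DASM is the left-right difference of DE values over symmetric electrode
#' pairs, RASM their ratio (denominator epsilon-guarded), and ASM the
#' concatenation of DASM and RASM along the pair axis.
#'
#' @param de T x N x F differential-entropy array.
#' @param montage [electrode_montage()] providing symmetric pairs.
#' @param kind `"DASM"`, `"RASM"` or `"ASM"`.
#' @param eps Denominator guard for RASM.
#' @return T x P x F array (P doubled for ASM).
#' @export
asymmetry_features <- function(de, montage, kind = c("DASM", "RASM", "ASM"),
                               eps = 1e-8) {
  kind <- match.arg(kind)
  stopifnot(length(dim(de)) == 3L)
  pairs <- montage$symmetric_pairs
  if (!nrow(pairs)) stop_config("montage has no symmetric pairs; cannot compute %s", kind)
  left <- de[, pairs[, 1], , drop = FALSE]
  right <- de[, pairs[, 2], , drop = FALSE]
  dasm <- left - right
  if (kind == "DASM") return(dasm)
  denom <- ifelse(abs(right) < eps, sign(right) * eps + (right == 0) * eps, right)
  rasm <- left / denom
  if (kind == "RASM") return(rasm)
  out <- array(0, c(dim(de)[1], 2L * nrow(pairs), dim(de)[3]))
  out[, seq_len(nrow(pairs)), ] <- dasm
  out[, nrow(pairs) + seq_len(nrow(pairs)), ] <- rasm
  out
}

#' Extract a per-trial feature tensor
#'
#' Pipeline: band decomposition, windowing, then a per-window per-band scalar
#' feature (DE or PSD); asymmetry kinds are derived from the DE tensor using
#' the montage's symmetric pairs. Optional moving-average smoothing along the
#' window axis. Deterministic given its inputs.
#'
#' @param rec A [raw_recording()].
#' @param cfg A [feature_config()].
#' @param montage An [electrode_montage()] (required for asymmetry kinds).
#' @return A `feature_tensor`: list with `values` (T x N x F array),
#'   `band_names`, `window_seconds`, `subject_id`, `trial_id`, `label`,
#'   `feature_kind`.
#' @export
extract_features <- function(rec, cfg = feature_config(), montage = NULL) {
  stopifnot(inherits(rec, "raw_recording"), inherits(cfg, "feature_config"))
  ctx <- sprintf("subject=%s trial=%s", rec$subject_id, rec$trial_id)
  base_kind <- if (cfg$feature_kind %in% c("DASM", "RASM", "ASM")) "DE" else cfg$feature_kind
  stack <- withCallingHandlers(
    bandpass_decompose(rec, cfg$bands),
    error = function(e) stop_config("feature extraction failed (%s): %s", ctx, conditionMessage(e))
  )
  nb <- length(cfg$bands)
  vals <- NULL
  for (bi in seq_len(nb)) {
    wins <- segment_windows(stack[, , bi, drop = TRUE], rec$rate,
                            cfg$window_seconds, cfg$stride_seconds)
    if (!length(wins)) stop_config("recording too short for one window (%s)", ctx)
    if (is.null(vals)) vals <- array(0, c(length(wins), nrow(rec$data), nb))
    for (wi in seq_along(wins)) {
      w <- wins[[wi]]
      if (base_kind == "DE") {
        n <- ncol(w)
        rm <- rowMeans(w)
        vv <- pmax((rowSums(w * w) - n * rm * rm) / (n - 1), cfg$var_floor)
        v <- 0.5 * log(2 * pi * exp(1) * vv)
      } else {
        v <- apply(w, 1L, power_spectral_density, rate = rec$rate, band = cfg$bands[[bi]])
      }
      vals[wi, , bi] <- v
    }
  }
  if (cfg$feature_kind %in% c("DASM", "RASM", "ASM")) {
    if (is.null(montage)) stop_config("montage required for %s features (%s)", cfg$feature_kind, ctx)
    vals <- asymmetry_features(vals, montage, cfg$feature_kind)
  }
  if (!is.null(cfg$smoothing) && cfg$smoothing > 1) {
    vals <- moving_average_t(vals, cfg$smoothing)
  }
  structure(list(values = vals, band_names = band_names(cfg$bands),
                 window_seconds = cfg$window_seconds,
                 subject_id = rec$subject_id, trial_id = rec$trial_id,
                 label = rec$label, feature_kind = cfg$feature_kind),
            class = "feature_tensor")
}

# Centered moving average along the first (window) axis with edge shrinkage.
moving_average_t <- function(vals, len) {
  T <- dim(vals)[1]
  half <- (len - 1L) %/% 2L
  out <- vals
  for (t in seq_len(T)) {
    lo <- max(1L, t - half); hi <- min(T, t + half)
    slab <- vals[lo:hi, , , drop = FALSE]
    out[t, , ] <- apply(slab, c(2L, 3L), mean)
  }
  out
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %s subject=%s trial=%s label=%d: %d windows x %d channels x %d bands\n",
              x$feature_kind, x$subject_id, x$trial_id, x$label, d[1], d[2], d[3]))
  invisible(x)
}
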