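#' A single-trial multichannel EEG recording
#'
#' Thin container for one trial: a channels x samples matrix in microvolts,
#' its sampling rate, channel labels and trial metadata.
#'
#' @param data Numeric matrix, channels x samples.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Character vector, one unique label per channel.
#' @param subject_id,trial_id Identifiers (coerced to character).
#' @param label Integer class index (1-based).
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(data, rate, channel_labels, subject_id, trial_id, label) {
  stopifnot(is.matrix(data), is.numeric(data))
  check_finite(data, sprintf("recording subject=%s trial=%s", subject_id, trial_id))
  if (length(channel_labels) != nrow(data)) {
    stop_config("channel_labels length (%d) != number of channels (%d)",
                length(channel_labels), nrow(data))
  }
  if (anyDuplicated(channel_labels)) stop_config("channel labels must be unique")
  stopifnot(rate > 0)
  structure(list(
    data = data, rate = rate, channel_labels = as.character(channel_labels),
    subject_id = as.character(subject_id), trial_id = as.character(trial_id),
    label = as.integer(label)
  ), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject=%s trial=%s label=%d: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, x$label, nrow(x$data), ncol(x$data), x$rate))
  invisible(x)
}

#' Electrode montage
#'
#' Channel labels, 2-D projected scalp coordinates and the list of symmetric
#' left/right electrode pairs used by asymmetry features.
#'
#' @param labels Character vector of N channel names.
#' @param coords2d N x 2 numeric matrix of projected positions.
#' @param symmetric_pairs Optional two-column integer matrix of
#'   (left index, right index) pairs; derived from labels when `NULL`
#'   (see [derive_symmetric_pairs()]).
#' @return An `electrode_montage` object.
#' @export
electrode_montage <- function(labels, coords2d, symmetric_pairs = NULL) {
  labels <- as.character(labels)
  coords2d <- as.matrix(coords2d)
  stopifnot(ncol(coords2d) == 2L, nrow(coords2d) == length(labels))
  check_finite(coords2d, "montage coordinates")
  if (anyDuplicated(labels)) stop_config("montage labels must be unique")
  if (is.null(symmetric_pairs)) symmetric_pairs <- derive_symmetric_pairs(labels)
  if (length(symmetric_pairs)) {
    symmetric_pairs <- matrix(as.integer(symmetric_pairs), ncol = 2L)
    bad <- symmetric_pairs < 1L | symmetric_pairs > length(labels)
    if (any(bad)) stop_config("symmetric pair indices out of range")
    if (any(symmetric_pairs[, 1] == symmetric_pairs[, 2])) {
      stop_config("a symmetric pair may not pair an electrode with itself")
    }
  } else {
    symmetric_pairs <- matrix(integer(0), ncol = 2L)
  }
  structure(list(labels = labels, coords2d = coords2d,
                 symmetric_pairs = symmetric_pairs),
            class = "electrode_montage")
}

#' Derive left/right symmetric pairs from electrode labels
#'
#' Follows the 10/20 numbering convention: labels ending in an odd number sit
#' over the left hemisphere and pair with the same prefix ending in the next
#' even number (F3 with F4, E1 with E2, ...). Labels without a trailing
#' number (midline, e.g. Fz, Cz) are unpaired.
#'
#' @param labels Character vector of channel names.
#' @return Two-column integer matrix of (left, right) indices.
#' @export
derive_symmetric_pairs <- function(labels) {
  m <- regmatches(labels, regexec("^(.*?)([0-9]+)$", labels))
  prefix <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, character(1))
  num <- vapply(m, function(g) if (length(g)) as.integer(g[3]) else NA_integer_, integer(1))
  pairs <- NULL
  for (i in seq_along(labels)) {
    if (is.na(num[i]) || num[i] %% 2L == 0L) next
    j <- which(!is.na(num) & prefix == prefix[i] & num == num[i] + 1L)
    if (length(j) == 1L) pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) matrix(integer(0), ncol = 2L) else pairs
}

#' Standard 62-channel extended 10/20 montage
#'
#' Labels, projected 2-D coordinates and the 27 symmetric left/right pairs for
#' the 62-channel cap commonly used in EEG emotion studies. Loaded from a
#' plain-text table shipped with the package.
#'
#' @return An [electrode_montage()] with 62 channels.
#' @export
montage_62 <- function() {
  path <- system.file("extdata", "montage62.tsv", package = "stgate", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  labels <- tab$label
  pairs <- derive_symmetric_pairs(labels)
  electrode_montage(labels, cbind(tab$x, tab$y), pairs)
}
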