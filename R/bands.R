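#' Frequency band specification
#'
#' A band is a named frequency interval in Hz. `high = Inf` marks an open-ended
#' band (gamma); downstream filtering caps it at 0.45 x the sampling rate.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param low Lower edge in Hz.
#' @param high Upper edge in Hz; may be `Inf` for an open-ended band.
#' @return A `band_spec` object.
#' @export
#' @examples
#' band_spec("alpha", 8, 13)
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(low) || low < 0) stop_config("band '%s': low edge must be finite and >= 0", name)
  if (is.finite(high) && high <= low) {
    stop_config("band '%s': high edge (%g) must exceed low edge (%g)", name, high, low)
  }
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' The five canonical EEG bands
#'
#' delta (1-3 Hz), theta (4-7 Hz), alpha (8-13 Hz), beta (14-30 Hz) and
#' gamma (>31 Hz, open-ended).
#'
#' @return A list of five [band_spec()] objects.
#' @export
default_bands <- function() {
  list(
    band_spec("delta", 1, 3),
    band_spec("theta", 4, 7),
    band_spec("alpha", 8, 13),
    band_spec("beta", 14, 30),
    band_spec("gamma", 31, Inf)
  )
}

band_names <- function(bands) vapply(bands, function(b) b$name, character(1))

# Resolve a band's edges against a sampling rate: open-ended high edges are
# capped at 0.45 * rate; any edge at or above Nyquist is a configuration error.
resolve_band <- function(band, rate) {
  high <- if (is.finite(band$high)) band$high else 0.45 * rate
  nyq <- rate / 2
  if (band$low >= nyq || high > nyq) {
    stop_config("band '%s' [%g, %g] Hz exceeds the Nyquist frequency (%g Hz) at rate %g Hz",
                band$name, band$low, high, nyq, rate)
  }
  if (high <= band$low) {
    stop_config("band '%s': capped high edge (%g) does not exceed low edge (%g)",
                band$name, high, band$low)
  }
  c(low = band$low, high = high)
}
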