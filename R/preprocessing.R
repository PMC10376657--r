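#' Band-pass filter specification
#'
#' Butterworth band-pass used to suppress cardiac (~1 Hz and above),
#' respiratory (~0.3 Hz) and slow drift components while keeping the
#' task-locked hemodynamics. Defaults: 4th order, 0.01-0.15 Hz.
#'
#' @param order Total band-pass filter order (must be even; `order/2` poles
#'   per band edge).
#' @param low_cut,high_cut Cutoff frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, low_cut = 0.01, high_cut = 0.15, fs = 9.19) {
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < fs / 2))
    stop("cutoffs must satisfy 0 < low_cut < high_cut < fs/2", call. = FALSE)
  if (order < 2 || order != round(order) || order %% 2 != 0)
    stop("`order` must be a positive even integer", call. = FALSE)
  structure(list(order = as.integer(order), low_cut = low_cut,
                 high_cut = high_cut, fs = fs),
            class = "filter_spec")
}

# n poles per edge give a band-pass of total order 2n; the very low
# normalized low cut (0.01 Hz at fs/2 = 4.595 Hz) makes higher-order
# recursions ill-conditioned, so the total order is kept at spec$order.
butter_coefs <- function(spec) {
  signal::butter(spec$order %/% 2L,
                 c(spec$low_cut, spec$high_cut) / (spec$fs / 2),
                 type = "pass")
}

#' Band-pass filter a session
#'
#' Applies the Butterworth band-pass to every channel of the full session
#' (before any trial segmentation, so filter transients never sit inside
#' short analysis windows). Zero-phase by default (forward-backward
#' `filtfilt`), which preserves the latency of the initial dip; a causal
#' single pass is available via `zero_phase = FALSE`.
#'
#' @param series An `hb_time_series` (or plain numeric matrix/vector).
#' @param spec A `filter_spec`.
#' @param zero_phase Logical; forward-backward filtering if `TRUE`.
#' @return Filtered object of the same type and shape.
#' @export
bandpass <- function(series, spec = filter_spec(), zero_phase = TRUE) {
  stopifnot(inherits(spec, "filter_spec"))
  bf <- butter_coefs(spec)
  apply_filter <- function(x) {
    if (length(x) < 3 * 2 * spec$order)
      stop("series shorter than the filter warm-up", call. = FALSE)
    if (zero_phase) signal::filtfilt(bf, x) else signal::filter(bf, x)
  }
  if (inherits(series, "hb_time_series")) {
    if (abs(series$fs - spec$fs) > 1e-9)
      stop("series and filter sampling rates differ", call. = FALSE)
    series$data <- t(apply(series$data, 1, apply_filter))
    series
  } else if (is.matrix(series)) {
    t(apply(series, 1, apply_filter))
  } else {
    apply_filter(as.numeric(series))
  }
}

#' Analytic magnitude response of the band-pass at a frequency
#'
#' Evaluates |H(e^{jw})| of the designed digital filter at frequency `f` Hz;
#' with `zero_phase = TRUE` the squared magnitude (the forward-backward
#' response) is returned.
#'
#' @param spec A `filter_spec`.
#' @param f Frequency in Hz.
#' @param zero_phase Match the response of [bandpass()]'s default.
#' @return Gain (linear scale).
#' @export
bandpass_gain <- function(spec, f, zero_phase = TRUE) {
  bf <- butter_coefs(spec)
  z <- exp(-1i * 2 * pi * f / spec$fs)
  g <- vapply(z, function(zz) {
    num <- sum(bf$b * zz^(0:(length(bf$b) - 1)))
    den <- sum(bf$a * zz^(0:(length(bf$a) - 1)))
    Mod(num / den)
  }, numeric(1))
  if (zero_phase) g^2 else g
}
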