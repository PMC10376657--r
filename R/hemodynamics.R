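#' Three-gamma canonical HRF parameters
#'
#' The canonical hemodynamic response function (cHRF) is a signed sum of three
#' gamma-density kernels: an early negative component (the initial dip, a
#' transient decrease of dHbO reflecting local oxygen extraction), the main
#' positive blood-flow response, and a late negative undershoot:
#' \deqn{cHRF(t) = \sum_i s_i A_i \, \gamma(t; a_i, b_i)}
#' with signs fixed to (-1, +1, -1). Each kernel is a normalized gamma density,
#' so A_i is (approximately) the unsigned area of component i.
#'
#' Defaults place the dip extremum near 2 s with the dip complete by about
#' 4 s, the main peak near 6 s, and the undershoot peak near 16 s.
#'
#' @param dip,main,undershoot Named lists with elements `A` (amplitude >= 0),
#'   `shape` (> 0) and `scale` (> 0) of the gamma-density kernel.
#' @return An object of class `gamma_hrf_params`.
#' @examples
#' p <- gamma_hrf_params()
#' t <- seq(0, 30, by = 1/9.19)
#' h <- chrf(t, p)  # dips below zero before ~3.5 s, peaks near 6 s
#' @export
gamma_hrf_params <- function(dip = list(A = 0.35, shape = 6, scale = 0.4),
                             main = list(A = 1.0, shape = 7, scale = 1.0),
                             undershoot = list(A = 0.35, shape = 17, scale = 1.0)) {
  comps <- list(dip = dip, main = main, undershoot = undershoot)
  for (nm in names(comps)) {
    cmp <- comps[[nm]]
    if (!all(c("A", "shape", "scale") %in% names(cmp)))
      stop("HRF component `", nm, "` needs fields A, shape, scale", call. = FALSE)
    if (cmp$A < 0) stop("HRF amplitude must be >= 0 in `", nm, "`", call. = FALSE)
    if (cmp$shape <= 0 || cmp$scale <= 0)
      stop("HRF gamma shape and scale must be > 0 in `", nm, "`", call. = FALSE)
  }
  structure(list(dip = dip, main = main, undershoot = undershoot,
                 signs = c(dip = -1, main = 1, undershoot = -1)),
            class = "gamma_hrf_params")
}

#' Evaluate the canonical HRF on a time grid
#'
#' @param t_grid Non-negative, increasing times in seconds.
#' @param params A `gamma_hrf_params`.
#' @param components Which components to include; dropping `"dip"` yields the
#'   delayed (blood-flow only) response used to model spatial spread of the
#'   conventional hemodynamic response.
#' @return Numeric vector of cHRF values (same length as `t_grid`).
#' @export
chrf <- function(t_grid, params = gamma_hrf_params(),
                 components = c("dip", "main", "undershoot")) {
  stopifnot(inherits(params, "gamma_hrf_params"))
  if (any(t_grid < 0) || is.unsorted(t_grid))
    stop("`t_grid` must be non-negative and increasing", call. = FALSE)
  components <- match.arg(components, c("dip", "main", "undershoot"),
                          several.ok = TRUE)
  out <- numeric(length(t_grid))
  for (nm in components) {
    cmp <- params[[nm]]
    out <- out + params$signs[[nm]] * cmp$A *
      stats::dgamma(t_grid, shape = cmp$shape, scale = cmp$scale)
  }
  out
}

#' Designed HRF: cHRF convolved with the task boxcar
#'
#' Causal discrete convolution of the sampled cHRF with the task boxcar,
#' scaled by `1/fs` (so it discretizes the continuous-time convolution
#' integral) and truncated to the boxcar's length.
#'
#' @param chrf_samples cHRF sampled on the same grid as `boxcar`.
#' @param boxcar 0/1 task indicator (e.g. from [trial_boxcar()]).
#' @param fs Sampling rate in Hz.
#' @return A `design_regressor`: list with `samples`, `fs`, `window_s` (NA
#'   until windowed).
#' @export
dhrf <- function(chrf_samples, boxcar, fs) {
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  n <- length(boxcar)
  m <- length(chrf_samples)
  if (m == 0L || n == 0L) stop("empty inputs to dhrf()", call. = FALSE)
  full <- signal::conv(as.numeric(boxcar), as.numeric(chrf_samples)) / fs
  structure(list(samples = full[seq_len(n)], fs = fs, window_s = NA_real_),
            class = "design_regressor")
}

#' Restrict a design regressor to an analysis window
#'
#' Keeps the first `floor(window_s * fs)` samples, i.e. the regressor over
#' `[onset, onset + window_s)`. Windows 0.5-4 s isolate the initial dip;
#' 14 s covers the delayed conventional response.
#'
#' @param reg A `design_regressor`.
#' @param window_s Window length in seconds (0 < window_s <= trial length).
#' @return A windowed `design_regressor` with `window_s` set.
#' @export
restrict_window <- function(reg, window_s) {
  stopifnot(inherits(reg, "design_regressor"))
  if (!is.numeric(window_s) || window_s <= 0)
    stop("`window_s` must be positive", call. = FALSE)
  k <- as.integer(floor(window_s * reg$fs))
  if (k > length(reg$samples))
    stop(sprintf("window of %g s (%d samples) exceeds the %d-sample trial grid",
                 window_s, k, length(reg$samples)), call. = FALSE)
  structure(list(samples = reg$samples[seq_len(k)], fs = reg$fs,
                 window_s = window_s),
            class = "design_regressor")
}

#' Per-trial design regressor for a protocol
#'
#' Convenience wrapper: samples the cHRF on the trial grid (trial length at
#' `fs`, extended so the convolution tail is complete) and convolves it with
#' the single-trial boxcar.
#'
#' @param protocol A `session_protocol`.
#' @param params A `gamma_hrf_params`.
#' @param components Passed to [chrf()].
#' @return A `design_regressor` of length `trial_n_samples(protocol)`.
#' @export
trial_dhrf <- function(protocol, params = gamma_hrf_params(),
                       components = c("dip", "main", "undershoot")) {
  n <- trial_n_samples(protocol)
  t <- (seq_len(n) - 1) / protocol$fs
  dhrf(chrf(t, params, components), trial_boxcar(protocol), protocol$fs)
}

#' Save/load HRF parameters as YAML
#' @param params A `gamma_hrf_params`.
#' @param path File path.
#' @export
write_hrf_yaml <- function(params, path) {
  yaml::write_yaml(params[c("dip", "main", "undershoot")], path)
  invisible(path)
}

#' @rdname write_hrf_yaml
#' @export
read_hrf_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  gamma_hrf_params(dip = x$dip, main = x$main, undershoot = x$undershoot)
}

#' Export a regressor to CSV for inspection
#' @param reg A `design_regressor`.
#' @param path File path.
#' @export
write_regressor_csv <- function(reg, path) {
  df <- data.frame(sample_index = seq_along(reg$samples),
                   time_s = (seq_along(reg$samples) - 1) / reg$fs,
                   dhrf = reg$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
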