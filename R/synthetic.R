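#' Multi-channel dHbO time series
#'
#' Container for one session of relative oxyhemoglobin concentration change
#' (dHbO, in micromolar) across the optode patch.
#'
#' @param data Channels x samples numeric matrix (µM).
#' @param protocol A `session_protocol`.
#' @param geometry A `channel_geometry`.
#' @param truth Optional `activation_profile` ground truth.
#' @param subject,session Optional identifiers.
#' @return An object of class `hb_time_series`.
#' @export
hb_time_series <- function(data, protocol, geometry, truth = NULL,
                           subject = NA_integer_, session = NA_character_) {
  data <- as.matrix(data)
  if (nrow(data) != n_channels(geometry))
    stop("data must have one row per geometry channel", call. = FALSE)
  if (ncol(data) != protocol_n_samples(protocol))
    stop("data must have floor(total_duration * fs) columns", call. = FALSE)
  rownames(data) <- geometry$channel_ids
  structure(list(data = data, fs = protocol$fs, protocol = protocol,
                 geometry = geometry, truth = truth,
                 subject = subject, session = session),
            class = "hb_time_series")
}

#' @export
print.hb_time_series <- function(x, ...) {
  cat(sprintf("hb_time_series: %d channels x %d samples @ %g Hz%s\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (!is.null(x$truth)) paste0(" [", x$truth$class_label, "]") else ""))
  invisible(x)
}

#' Spatial activation ground truth for one task class
#'
#' Which channels of the patch respond to the task, at what dHbO amplitude.
#' `spread_channels` model the lower spatial specificity of the delayed
#' blood-flow response: they receive the delayed response at `spread_frac`
#' of the amplitude with the initial dip attenuated to `spread_dip_frac` of
#' its footprint value — perfusion spreads beyond the neuronally active
#' site, while the metabolic dip stays concentrated on `active_channels`.
#'
#' @param class_label `"RHTF"` (thumb) or `"RHLF"` (little finger).
#' @param active_channels Channel ids carrying the full response.
#' @param amplitude Peak dHbO response amplitude in µM (scalar or one per
#'   active channel).
#' @param jitter_sd Log-scale SD of the multiplicative per-trial amplitude
#'   jitter (lognormal, so amplitudes stay positive).
#' @param spread_channels Channel ids carrying the spread response.
#' @param spread_frac Amplitude fraction for spread channels.
#' @param spread_dip_frac Fraction of the dip amplitude retained on spread
#'   channels (the dip attenuates, rather than vanishes, outside the
#'   neuronally active site).
#' @return An object of class `activation_profile`.
#' @export
activation_profile <- function(class_label = c("RHTF", "RHLF"),
                               active_channels, amplitude = 0.3,
                               jitter_sd = 0.15,
                               spread_channels = character(0),
                               spread_frac = 0.6,
                               spread_dip_frac = 0) {
  class_label <- match.arg(class_label)
  if (any(amplitude < 0)) stop("`amplitude` must be >= 0", call. = FALSE)
  if (!length(amplitude) %in% c(1L, length(active_channels)))
    stop("`amplitude` must be scalar or one per active channel", call. = FALSE)
  structure(list(class_label = class_label,
                 active_channels = as.character(active_channels),
                 amplitude = amplitude, jitter_sd = jitter_sd,
                 spread_channels = as.character(spread_channels),
                 spread_frac = spread_frac,
                 spread_dip_frac = spread_dip_frac),
            class = "activation_profile")
}

#' Physiological noise model parameters
#'
#' Superposition of cardiac, respiratory and Mayer-wave oscillations (random
#' phase per channel), a linear baseline drift, and white measurement noise.
#' Defaults: cardiac 1.2 Hz, respiratory 0.3 Hz, Mayer waves 0.1 Hz, drift
#' 0.002 µM/s. The white-noise SD is set so that single-trial full-trial
#' t-values on active channels land mostly between 2 and 8 — the regime
#' where thresholding at 1.65 is informative.
#'
#' @param cardiac,respiratory,mayer Lists with `freq` (Hz) and `amp` (µM).
#' @param drift_slope Linear drift in µM/s.
#' @param white_sd White noise SD in µM.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(cardiac = list(freq = 1.2, amp = 0.10),
                         respiratory = list(freq = 0.3, amp = 0.10),
                         mayer = list(freq = 0.1, amp = 0.015),
                         drift_slope = 0.002, white_sd = 0.30) {
  for (cmp in list(cardiac, respiratory, mayer)) {
    if (cmp$freq <= 0) stop("noise frequencies must be > 0", call. = FALSE)
    if (cmp$amp < 0) stop("noise amplitudes must be >= 0", call. = FALSE)
  }
  if (white_sd < 0) stop("`white_sd` must be >= 0", call. = FALSE)
  structure(list(cardiac = cardiac, respiratory = respiratory, mayer = mayer,
                 drift_slope = drift_slope, white_sd = white_sd),
            class = "noise_params")
}

#' Zero-noise parameters (for noiseless constructions)
#' @export
no_noise <- function() {
  noise_params(cardiac = list(freq = 1.2, amp = 0),
               respiratory = list(freq = 0.3, amp = 0),
               mayer = list(freq = 0.1, amp = 0),
               drift_slope = 0, white_sd = 0)
}

noise_matrix <- function(noise, n_ch, n, fs) {
  t <- (seq_len(n) - 1) / fs
  out <- matrix(0, n_ch, n)
  for (cmp in list(noise$cardiac, noise$respiratory, noise$mayer)) {
    if (cmp$amp > 0) {
      phases <- stats::runif(n_ch, 0, 2 * pi)
      out <- out + cmp$amp * sin(outer(phases, 2 * pi * cmp$freq * t, `+`))
    }
  }
  if (noise$drift_slope != 0)
    out <- out + matrix(noise$drift_slope * t, n_ch, n, byrow = TRUE)
  if (noise$white_sd > 0)
    out <- out + matrix(stats::rnorm(n_ch * n, 0, noise$white_sd), n_ch, n)
  out
}

#' Simulate one finger-tapping fNIRS session
#'
#' Active channels carry `amplitude * jitter * dhrf` time-locked to every
#' trial onset; spread channels (if any) carry `dhrf_spread` (typically the
#' dip-attenuated response) at `spread_frac` of the amplitude with the same
#' per-trial jitter; all channels receive physiological + white noise.
#' Reproducible for a fixed seed.
#'
#' @param protocol A `session_protocol`.
#' @param geometry A `channel_geometry`.
#' @param profile An `activation_profile`.
#' @param noise A `noise_params`.
#' @param dhrf A per-trial `design_regressor` sampled at the protocol rate.
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @param dhrf_spread Optional `design_regressor` for spread channels
#'   (defaults to `dhrf` when spread channels are present).
#' @param amplitude_scale Multiplier on the profile amplitude (used by
#'   [make_cohort()] for subject-level variation).
#' @return An `hb_time_series` with `truth = profile`.
#' @export
simulate_session <- function(protocol, geometry, profile, noise, dhrf,
                             seed = NULL, dhrf_spread = NULL,
                             amplitude_scale = 1) {
  stopifnot(inherits(dhrf, "design_regressor"))
  if (abs(dhrf$fs - protocol$fs) > 1e-9)
    stop("dhrf sampling rate does not match the protocol", call. = FALSE)
  unknown <- setdiff(c(profile$active_channels, profile$spread_channels),
                     geometry$channel_ids)
  if (length(unknown))
    stop("profile channels not in geometry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- protocol_n_samples(protocol)
  n_ch <- n_channels(geometry)
  bp <- build_protocol(protocol)
  amps <- rep_len(profile$amplitude, length(profile$active_channels)) *
    amplitude_scale
  jitter <- if (profile$jitter_sd > 0 && protocol$n_trials > 0)
    exp(stats::rnorm(protocol$n_trials, 0, profile$jitter_sd)) else
      rep(1, protocol$n_trials)

  data <- matrix(0, n_ch, n)
  add_response <- function(data, channels, channel_amps, reg) {
    idx <- match(channels, geometry$channel_ids)
    for (k in seq_along(bp$onsets)) {
      o <- bp$onsets[k]
      len <- min(length(reg$samples), n - o + 1L)
      seg <- o:(o + len - 1L)
      for (j in seq_along(idx))
        data[idx[j], seg] <- data[idx[j], seg] +
          channel_amps[j] * jitter[k] * reg$samples[seq_len(len)]
    }
    data
  }
  if (length(profile$active_channels))
    data <- add_response(data, profile$active_channels, amps, dhrf)
  if (length(profile$spread_channels)) {
    if (is.null(dhrf_spread)) dhrf_spread <- dhrf
    spread_amp <- rep_len(mean(amps) * profile$spread_frac,
                          length(profile$spread_channels))
    data <- add_response(data, profile$spread_channels, spread_amp, dhrf_spread)
  }
  data <- data + noise_matrix(noise, n_ch, n, protocol$fs)
  hb_time_series(data, protocol, geometry, truth = profile)
}

#' Simulate a labelled cohort of tapping sessions
#'
#' Two sessions per subject (one per task class), with a subject-level
#' amplitude factor drawn once (lognormal) and per-trial jitter on top. The
#' per-trial design regressor is normalized to unit peak magnitude so profile
#' amplitudes are peak dHbO in µM.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_trials Trials per session.
#' @param profile_RHTF,profile_RHLF `activation_profile`s for the two classes.
#' @param noise A `noise_params`.
#' @param seed Integer master seed.
#' @param protocol A `session_protocol` (trial count overridden by `n_trials`).
#' @param geometry A `channel_geometry`.
#' @param hrf A `gamma_hrf_params`.
#' @param subject_sd Log-scale SD of the subject-level amplitude factor.
#' @return An object of class `fnirs_cohort`: list with `sessions` (list of
#'   `hb_time_series`), `labels`, `subjects`, and the shared inputs.
#' @export
make_cohort <- function(n_subjects, n_trials, profile_RHTF, profile_RHLF,
                        noise = noise_params(), seed = 1,
                        protocol = session_protocol(),
                        geometry = grid_geometry(),
                        hrf = gamma_hrf_params(), subject_sd = 0.2) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  protocol <- session_protocol(protocol$pre_rest_s, protocol$post_rest_s,
                               n_trials, protocol$task_s, protocol$rest_s,
                               protocol$fs)
  if (setequal(profile_RHTF$active_channels, profile_RHLF$active_channels))
    message("note: the two class profiles have identical active channel sets")
  reg_full <- trial_dhrf(protocol, hrf)
  # spread channels: full delayed response, dip attenuated by spread_dip_frac
  q <- profile_RHTF$spread_dip_frac
  hrf_spread <- gamma_hrf_params(
    dip = utils::modifyList(hrf$dip, list(A = hrf$dip$A * q)),
    main = hrf$main, undershoot = hrf$undershoot)
  reg_delayed <- trial_dhrf(protocol, hrf_spread)
  reg_full$samples <- reg_full$samples / max(abs(reg_full$samples))
  reg_delayed$samples <- reg_delayed$samples / max(abs(reg_delayed$samples))

  set.seed(seed)
  subj_scale <- exp(stats::rnorm(n_subjects, 0, subject_sd))
  sessions <- vector("list", 2L * n_subjects)
  labels <- character(2L * n_subjects)
  subjects <- integer(2L * n_subjects)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    for (profile in list(profile_RHTF, profile_RHLF)) {
      i <- i + 1L
      ses <- simulate_session(protocol, geometry, profile, noise,
                              dhrf = reg_full, seed = NULL,
                              dhrf_spread = reg_delayed,
                              amplitude_scale = subj_scale[s])
      ses$subject <- s
      ses$session <- sprintf("S%02d_%s", s, profile$class_label)
      sessions[[i]] <- ses
      labels[i] <- profile$class_label
      subjects[i] <- s
    }
  }
  structure(list(sessions = sessions, labels = labels, subjects = subjects,
                 protocol = protocol, geometry = geometry, hrf = hrf,
                 noise = noise, seed = seed),
            class = "fnirs_cohort")
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  cat(sprintf("fnirs_cohort: %d sessions (%d subjects x 2 classes), %d trials each\n",
              length(x$sessions), length(unique(x$subjects)),
              x$protocol$n_trials))
  invisible(x)
}

#' Default disjoint activation footprints for the two tapping tasks
#'
#' Two adjacent 6-channel footprints on the default 6x6 patch, with a shared
#' spread ring between and around them. The delayed (blood-flow) response
#' covers the whole union region — both footprints and the ring — at the
#' same amplitude for both classes, so only the initial dip is
#' footprint-specific: the embodiment of the premise that the dip localizes
#' neuronal activity while the delayed response does not distinguish
#' sub-areas of one small patch.
#'
#' @param amplitude Peak dHbO amplitude in µM.
#' @param jitter_sd Per-trial amplitude jitter (log-scale SD).
#' @return List with elements `RHTF` and `RHLF` (`activation_profile`s).
#' @export
default_profiles <- function(amplitude = 0.3, jitter_sd = 0.15) {
  ch <- function(ij) sprintf("CH%02d", ij)  # grid index = x + 6*(y-1)
  # thumb: columns 2-3, rows 2-4; little finger: columns 4-5, rows 2-4
  rhtf <- ch(c(8, 9, 14, 15, 20, 21))
  rhlf <- ch(c(10, 11, 16, 17, 22, 23))
  spread <- ch(c(2, 3, 4, 5, 7, 12, 13, 18, 19, 24, 26, 27, 28, 29))
  list(
    RHTF = activation_profile("RHTF", rhtf, amplitude, jitter_sd,
                              spread_channels = union(spread, rhlf),
                              spread_frac = 1.0, spread_dip_frac = 0.45),
    RHLF = activation_profile("RHLF", rhlf, amplitude, jitter_sd,
                              spread_channels = union(spread, rhtf),
                              spread_frac = 1.0, spread_dip_frac = 0.45))
}
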