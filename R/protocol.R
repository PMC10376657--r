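#' Session protocol for a block-design finger-tapping experiment
#'
#' Describes one fNIRS session: a pre-rest baseline, `n_trials` trials of
#' task + rest, and a post-rest tail, sampled at `fs` Hz. Defaults reproduce
#' the standard motor-cortex tapping paradigm: 60 s pre-rest, six 30 s trials
#' (10 s tapping, 20 s rest) and 10 s post-rest at 9.19 Hz.
#'
#' @param pre_rest_s Pre-rest duration in seconds.
#' @param post_rest_s Post-rest duration in seconds.
#' @param n_trials Number of task trials (>= 0).
#' @param task_s Task (tapping) duration per trial, seconds.
#' @param rest_s Rest duration per trial, seconds.
#' @param fs Sampling rate in Hz.
#' @return An object of class `session_protocol`.
#' @examples
#' p <- session_protocol()
#' protocol_duration(p)  # 250 s
#' @export
session_protocol <- function(pre_rest_s = 60, post_rest_s = 10, n_trials = 6,
                             task_s = 10, rest_s = 20, fs = 9.19) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("invalid protocol: sampling rate `fs` must be a positive number", call. = FALSE)
  for (nm in c("pre_rest_s", "post_rest_s", "task_s", "rest_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid protocol: `", nm, "` must be a positive duration", call. = FALSE)
  }
  if (!is.numeric(n_trials) || n_trials < 0 || n_trials != round(n_trials))
    stop("invalid protocol: `n_trials` must be a non-negative integer", call. = FALSE)
  structure(list(pre_rest_s = pre_rest_s, post_rest_s = post_rest_s,
                 n_trials = as.integer(n_trials), task_s = task_s,
                 rest_s = rest_s, fs = fs),
            class = "session_protocol")
}

#' @rdname session_protocol
#' @param protocol A `session_protocol`.
#' @export
protocol_duration <- function(protocol) {
  with(protocol, pre_rest_s + n_trials * (task_s + rest_s) + post_rest_s)
}

#' Number of samples in a session (floor of duration times sampling rate)
#' @param protocol A `session_protocol`.
#' @export
protocol_n_samples <- function(protocol) {
  as.integer(floor(protocol_duration(protocol) * protocol$fs))
}

#' Samples per trial on the trial grid
#' @param protocol A `session_protocol`.
#' @export
trial_n_samples <- function(protocol) {
  as.integer(floor((protocol$task_s + protocol$rest_s) * protocol$fs))
}

#' Build the per-sample task boxcar for a session protocol
#'
#' Labels every sample of the session as task (1) or rest (0). Sample i
#' (1-based) sits at time (i-1)/fs; it is a task sample when that time falls
#' in `[onset, onset + task_s)` of some trial.
#'
#' @param protocol A `session_protocol`.
#' @return A list with `boxcar` (0/1 integer vector over the whole session),
#'   `onsets` (1-based sample index of the first task sample of each trial),
#'   and `time_s` (per-sample times).
#' @export
build_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "session_protocol"))
  n <- protocol_n_samples(protocol)
  time_s <- (seq_len(n) - 1) / protocol$fs
  boxcar <- integer(n)
  onsets <- integer(0)
  if (protocol$n_trials > 0) {
    trial_len <- protocol$task_s + protocol$rest_s
    starts <- protocol$pre_rest_s + (seq_len(protocol$n_trials) - 1) * trial_len
    for (s in starts) {
      in_task <- time_s >= s & time_s < s + protocol$task_s
      boxcar[in_task] <- 1L
      onsets <- c(onsets, which(in_task)[1L])
    }
  }
  list(boxcar = boxcar, onsets = onsets, time_s = time_s)
}

#' Single-trial task boxcar on the trial grid
#'
#' One trial of `task_s` on / `rest_s` off sampled at `fs`; this is the
#' protocol convolved with the canonical HRF to form the per-trial design
#' regressor.
#'
#' @param protocol A `session_protocol`.
#' @return 0/1 integer vector of length `trial_n_samples(protocol)`.
#' @export
trial_boxcar <- function(protocol) {
  n <- trial_n_samples(protocol)
  t <- (seq_len(n) - 1) / protocol$fs
  as.integer(t < protocol$task_s)
}

#' @export
print.session_protocol <- function(x, ...) {
  cat(sprintf(
    "fNIRS session protocol: %g s pre-rest + %d x (%g s task + %g s rest) + %g s post-rest @ %g Hz (%d samples)\n",
    x$pre_rest_s, x$n_trials, x$task_s, x$rest_s, x$post_rest_s, x$fs,
    protocol_n_samples(x)))
  invisible(x)
}
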