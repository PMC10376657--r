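#' t-map thresholding and rendering parameters
#'
#' @param t_crt Critical t-value; a channel is active when `t > t_crt` and
#'   `p < alpha`. 1.65 is the one-sided 5% critical value at large df.
#' @param alpha p-value threshold.
#' @param image_size Side length of the rendered square image in pixels.
#' @param colormap `"jet"` (256-entry blue-to-red table) or `"gray"`.
#' @param interpolation `"kernel"` (Gaussian-kernel scattered-data weighting)
#'   or `"nearest"`.
#' @return An object of class `tmap_params`.
#' @export
tmap_params <- function(t_crt = 1.65, alpha = 0.05, image_size = 227,
                        colormap = c("jet", "gray"),
                        interpolation = c("kernel", "nearest")) {
  if (t_crt <= 0) stop("`t_crt` must be > 0", call. = FALSE)
  if (image_size < 32) stop("`image_size` must be >= 32", call. = FALSE)
  structure(list(t_crt = t_crt, alpha = alpha,
                 image_size = as.integer(image_size),
                 colormap = match.arg(colormap),
                 interpolation = match.arg(interpolation)),
            class = "tmap_params")
}

#' Threshold and normalize channel t-values into activation values
#'
#' A channel's activation is its t-value when `t > t_crt` and `p < alpha`
#' (strict inequalities) and 0 otherwise; surviving values are then divided
#' by their maximum so any non-degenerate map spans (0, 1].
#'
#' @param t,p Per-channel t- and p-values (equal length).
#' @param params A `tmap_params`.
#' @return Activation values in `[0, 1]`, zeros where nothing survives.
#' @examples
#' t_to_activation(c(2, 4, 1), c(0.03, 0.001, 0.2))  # 0.5, 1, 0
#' @export
t_to_activation <- function(t, p, params = tmap_params()) {
  if (length(t) != length(p)) stop("`t` and `p` lengths differ", call. = FALSE)
  v <- ifelse(is.finite(t) & t > params$t_crt & p < params$alpha, t, 0)
  v[is.infinite(t) & t > 0 & p < params$alpha] <- Inf
  if (any(is.infinite(v))) {           # exact fits dominate: they saturate at 1
    v <- ifelse(is.infinite(v), 1, 0)
  } else if (max(v) > 0) {
    v <- v / max(v)
  }
  v
}

#' Fixed 256-entry jet-like colormap
#'
#' The classic piecewise-linear blue-cyan-yellow-red table, fixed so rendered
#' images are bit-reproducible.
#'
#' @param n Number of entries.
#' @return n x 3 matrix of RGB values in `[0, 1]`.
#' @export
jet_colormap <- function(n = 256) {
  u <- seq(0, 1, length.out = n)
  ramp <- function(x) pmax(0, pmin(1, 1.5 - 4 * abs(x)))
  cbind(r = ramp(u - 0.75), g = ramp(u - 0.5), b = ramp(u - 0.25))
}

# Precompute (and cache) the pixel-by-channel interpolation weight matrix.
# Interpolation is linear in the channel values, so rendering is one
# matrix-vector product per map.
.render_cache <- new.env(parent = emptyenv())

interp_weights <- function(geometry, size, interpolation) {
  key <- paste(interpolation, size, paste(signif(geometry$xy, 10), collapse = ","),
               sep = "|")
  hit <- .render_cache[[key]]
  if (!is.null(hit)) return(hit)
  px <- (seq_len(size) - 0.5) / size
  grid <- cbind(rep(px, times = size), rep(px, each = size))  # (x, y) rows
  d2 <- outer(grid[, 1], geometry$xy[, 1], `-`)^2 +
        outer(grid[, 2], geometry$xy[, 2], `-`)^2
  if (interpolation == "nearest") {
    nn <- max.col(-d2, ties.method = "first")
    W <- matrix(0, nrow(grid), n_channels(geometry))
    W[cbind(seq_len(nrow(grid)), nn)] <- 1
  } else {
    nnd <- apply(d2, 2, function(col) sqrt(min(col[col > 1e-12])))
    spacing <- stats::median(apply(
      as.matrix(stats::dist(geometry$xy)), 1,
      function(r) min(r[r > 0])))
    sigma <- 0.5 * spacing
    W <- exp(-d2 / (2 * sigma^2))
    W <- W / rowSums(W)
  }
  .render_cache[[key]] <- W
  W
}

#' Render channel activation values as a topographic t-map image
#'
#' Scatters the per-channel activation values over the patch, interpolates
#' onto a square pixel grid (Gaussian-kernel weighting by default; nearest
#' neighbour as fallback/by request), quantizes to 8-bit levels, and maps
#' through the fixed colormap to an RGB image. Deterministic.
#'
#' @param channel_values Activation values in `[0, 1]`, one per channel.
#' @param geometry A `channel_geometry`.
#' @param params A `tmap_params`.
#' @return `image_size x image_size x 3` array in `[0, 1]`.
#' @export
render_tmap <- function(channel_values, geometry, params = tmap_params()) {
  if (length(channel_values) != n_channels(geometry))
    stop("need one value per geometry channel", call. = FALSE)
  interpolation <- params$interpolation
  if (interpolation == "kernel" && n_channels(geometry) < 3) {
    message("fewer than 3 channels: falling back to nearest-neighbour rendering")
    interpolation <- "nearest"
  }
  size <- params$image_size
  W <- interp_weights(geometry, size, interpolation)
  v <- as.numeric(W %*% pmin(1, pmax(0, channel_values)))
  v <- round(pmin(1, pmax(0, v)) * 255)                    # 8-bit quantization
  cmap <- if (params$colormap == "jet") jet_colormap(256) else
    cbind(seq(0, 1, length.out = 256), seq(0, 1, length.out = 256),
          seq(0, 1, length.out = 256))
  cmap <- round(cmap * 255) / 255      # 8-bit entries: PNG round-trips exactly
  rgb <- cmap[v + 1, , drop = FALSE]
  # grid rows iterate x fastest with y blocks; image[row=y, col=x]
  img <- array(0, c(size, size, 3))
  for (ch in 1:3)
    img[, , ch] <- t(matrix(rgb[, ch], nrow = size))[size:1, , drop = FALSE]
  img
}

#' Per-channel windowed robust fits for one trial
#'
#' Regresses each channel's samples over `[onset, onset + window_s)` on the
#' equally windowed design regressor and assembles the thresholded,
#' normalized, rendered t-map.
#'
#' @param series An `hb_time_series` (typically band-pass filtered).
#' @param onset 1-based sample index of the trial onset.
#' @param reg The per-trial `design_regressor` (full trial grid).
#' @param window_s Analysis window in seconds.
#' @param params A `tmap_params`.
#' @param render Render the image (set `FALSE` to keep only channel values).
#' @param df Degrees-of-freedom convention, see [robust_fit()].
#' @return An object of class `tmap`: `channel_values`, `t_raw`, `p`,
#'   `image` (or NULL), `label`, `subject`, `trial`, `window_s`.
#' @export
fit_trial_tmap <- function(series, onset, reg, window_s,
                           params = tmap_params(), render = TRUE,
                           df = "n-2") {
  wreg <- restrict_window(reg, window_s)
  k <- length(wreg$samples)
  if (onset + k - 1L > ncol(series$data))
    stop("window extends past the end of the session", call. = FALSE)
  seg <- onset:(onset + k - 1L)
  nch <- nrow(series$data)
  t_raw <- numeric(nch); p <- numeric(nch)
  for (c in seq_len(nch)) {
    fit <- robust_fit(series$data[c, seg], wreg$samples, df = df)
    t_raw[c] <- fit$t; p[c] <- fit$p
  }
  cv <- t_to_activation(t_raw, p, params)
  img <- if (render) render_tmap(cv, series$geometry, params) else NULL
  structure(list(channel_values = cv, t_raw = t_raw, p = p, image = img,
                 label = if (!is.null(series$truth)) series$truth$class_label
                         else NA_character_,
                 subject = series$subject, trial = NA_integer_,
                 window_s = window_s),
            class = "tmap")
}

#' Build the full image dataset from a cohort
#'
#' One t-map per (session, trial, window): band-pass filters each session,
#' fits every channel in every requested window of every trial, and stacks
#' the rendered images. Per-interval dataset size is
#' `n_subjects * n_trials` per class; combining the eight dip windows
#' multiplies it by 8.
#'
#' @param cohort An `fnirs_cohort`.
#' @param windows Analysis windows in seconds (default the eight initial-dip
#'   windows 0.5-4 s).
#' @param params A `tmap_params`.
#' @param fspec A `filter_spec`, or NULL to skip filtering.
#' @param hrf A `gamma_hrf_params` (defaults to the cohort's).
#' @param progress Print progress.
#' @return An object of class `image_dataset`: `images` (H x W x 3 x N
#'   array), `labels` (factor RHLF/RHTF), `meta` (data.frame with subject,
#'   session, trial, window_s).
#' @export
build_tmap_dataset <- function(cohort, windows = seq(0.5, 4, by = 0.5),
                               params = tmap_params(),
                               fspec = filter_spec(fs = cohort$protocol$fs),
                               hrf = cohort$hrf, progress = FALSE) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  if (any(windows > cohort$protocol$task_s + cohort$protocol$rest_s))
    stop("window longer than the trial", call. = FALSE)
  size <- params$image_size
  n_maps <- length(cohort$sessions) * cohort$protocol$n_trials * length(windows)
  if (n_maps == 0L)
    return(structure(list(images = array(0, c(size, size, 3, 0)),
                          labels = factor(character(0), c("RHLF", "RHTF")),
                          meta = data.frame()),
                     class = "image_dataset"))
  reg <- trial_dhrf(cohort$protocol, hrf)
  images <- array(0, c(size, size, 3, n_maps))
  labels <- character(n_maps)
  meta <- data.frame(subject = integer(n_maps), session = character(n_maps),
                     trial = integer(n_maps), window_s = numeric(n_maps),
                     stringsAsFactors = FALSE)
  i <- 0L
  for (ses in cohort$sessions) {
    f <- if (is.null(fspec)) ses else bandpass(ses, fspec)
    onsets <- build_protocol(ses$protocol)$onsets
    for (tr in seq_along(onsets)) {
      for (w in windows) {
        i <- i + 1L
        tm <- fit_trial_tmap(f, onsets[tr], reg, w, params)
        images[, , , i] <- tm$image
        labels[i] <- tm$label
        meta$subject[i] <- ses$subject
        meta$session[i] <- ses$session
        meta$trial[i] <- tr
        meta$window_s[i] <- w
      }
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(images = images,
                 labels = factor(labels, levels = c("RHLF", "RHTF")),
                 meta = meta),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("image_dataset: %d images (%d x %d x 3); classes: %s\n",
              dim(x$images)[4], dim(x$images)[1], dim(x$images)[2],
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset an image dataset
#' @param ds An `image_dataset`.
#' @param idx Integer indices.
#' @export
subset_dataset <- function(ds, idx) {
  structure(list(images = ds$images[, , , idx, drop = FALSE],
                 labels = ds$labels[idx],
                 meta = ds$meta[idx, , drop = FALSE]),
            class = "image_dataset")
}

#' Surviving-channel set of a t-map
#'
#' Channels whose activation value is positive (i.e. passed the t and p
#' thresholds); used to compare against the ground-truth active set.
#' @param tm A `tmap` (or numeric channel values).
#' @param geometry Optional geometry for channel ids.
#' @export
surviving_channels <- function(tm, geometry = NULL) {
  v <- if (inherits(tm, "tmap")) tm$channel_values else as.numeric(tm)
  idx <- which(v > 0)
  if (!is.null(geometry)) geometry$channel_ids[idx] else idx
}

#' Jaccard overlap between two channel sets
#' @param a,b Vectors (channel ids or indices).
#' @export
jaccard <- function(a, b) {
  if (length(union(a, b)) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
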