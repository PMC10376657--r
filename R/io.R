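#' Write/read a session as long-format CSV
#'
#' Columns: subject, session, channel, sample_index, time_s, dHbO. The
#' protocol and geometry travel in a JSON sidecar (`<path>.meta.json`), so a
#' round trip reconstructs the full object.
#'
#' @param series An `hb_time_series`.
#' @param path CSV path.
#' @export
write_session_csv <- function(series, path) {
  n <- ncol(series$data)
  nch <- nrow(series$data)
  df <- data.frame(
    subject = series$subject,
    session = series$session,
    channel = rep(series$geometry$channel_ids, each = n),
    sample_index = rep(seq_len(n), times = nch),
    time_s = rep((seq_len(n) - 1) / series$fs, times = nch),
    dHbO = as.vector(t(series$data)))
  utils::write.csv(df, path, row.names = FALSE)
  p <- series$protocol
  jsonlite::write_json(
    list(protocol = list(pre_rest_s = p$pre_rest_s, post_rest_s = p$post_rest_s,
                         n_trials = p$n_trials, task_s = p$task_s,
                         rest_s = p$rest_s, fs = p$fs),
         geometry = list(id = series$geometry$channel_ids,
                         x = series$geometry$xy[, 1],
                         y = series$geometry$xy[, 2])),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  p <- meta$protocol
  protocol <- session_protocol(p$pre_rest_s, p$post_rest_s, p$n_trials,
                               p$task_s, p$rest_s, p$fs)
  geometry <- channel_geometry(meta$geometry$id,
                               cbind(meta$geometry$x, meta$geometry$y))
  n <- max(df$sample_index)
  data <- matrix(NA_real_, n_channels(geometry), n)
  idx <- match(df$channel, geometry$channel_ids)
  data[cbind(idx, df$sample_index)] <- df$dHbO
  hb_time_series(data, protocol, geometry,
                 subject = df$subject[1], session = df$session[1])
}

#' Write a t-map as PNG with a JSON metadata sidecar
#'
#' The image is 8-bit RGB; because rendering already quantizes to 8-bit
#' levels, write-then-read round-trips the pixel data exactly. The sidecar
#' (`<path>.json`) carries subject, trial, window, label and the raw t-values.
#'
#' @param tm A `tmap` with a rendered image.
#' @param path PNG path.
#' @export
write_tmap_png <- function(tm, path) {
  if (is.null(tm$image)) stop("t-map has no rendered image", call. = FALSE)
  png::writePNG(tm$image, path)
  jsonlite::write_json(
    list(label = tm$label, subject = tm$subject, trial = tm$trial,
         window_s = tm$window_s, t_raw = tm$t_raw, p = tm$p,
         channel_values = tm$channel_values),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tmap_png
#' @export
read_tmap_png <- function(path) {
  img <- png::readPNG(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(channel_values = meta$channel_values, t_raw = meta$t_raw,
                 p = meta$p, image = img, label = meta$label,
                 subject = meta$subject, trial = meta$trial,
                 window_s = meta$window_s),
            class = "tmap")
}

#' Dataset manifest with checksums
#'
#' Records every artifact file with its MD5 checksum; [verify_manifest()]
#' recomputes the checksums and fails on any mismatch.
#'
#' @param files Character vector of file paths.
#' @param path Manifest CSV path.
#' @export
write_manifest <- function(files, path) {
  df <- data.frame(file = basename(files),
                   md5 = unname(tools::md5sum(files)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param dir Directory holding the files named in the manifest.
#' @export
verify_manifest <- function(path, dir = dirname(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  actual <- unname(tools::md5sum(file.path(dir, df$file)))
  bad <- which(is.na(actual) | actual != df$md5)
  if (length(bad))
    stop("integrity error: checksum mismatch for ",
         paste(df$file[bad], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
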