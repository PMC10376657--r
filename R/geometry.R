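#' Channel geometry for an fNIRS optode patch
#'
#' Planar coordinates of measurement channels within the patch, normalized to
#' the unit square. The default emulates a dense 36-channel patch over the
#' left motor cortex (C3): a regular 6x6 grid spanning [0.1, 0.9]^2.
#'
#' @param channel_ids Character or integer channel identifiers.
#' @param xy Numeric matrix (n x 2) of planar coordinates in [0,1]^2.
#' @param emitter,detector Optional per-channel metadata labels.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(channel_ids, xy, emitter = NULL, detector = NULL) {
  channel_ids <- as.character(channel_ids)
  xy <- as.matrix(xy)
  if (nrow(xy) != length(channel_ids) || ncol(xy) != 2L)
    stop("`xy` must be an n x 2 matrix with one row per channel", call. = FALSE)
  if (anyDuplicated(channel_ids))
    stop("channel identifiers must be unique", call. = FALSE)
  if (anyDuplicated(xy, MARGIN = 1))
    stop("channel coordinates must be pairwise distinct", call. = FALSE)
  structure(list(channel_ids = channel_ids, xy = xy,
                 emitter = emitter, detector = detector),
            class = "channel_geometry")
}

#' @rdname channel_geometry
#' @param nx,ny Grid dimensions (nx * ny channels).
#' @param lo,hi Extent of the grid within the unit square.
#' @export
grid_geometry <- function(nx = 6, ny = 6, lo = 0.1, hi = 0.9) {
  gx <- seq(lo, hi, length.out = nx)
  gy <- seq(lo, hi, length.out = ny)
  xy <- as.matrix(expand.grid(x = gx, y = gy))
  channel_geometry(sprintf("CH%02d", seq_len(nx * ny)), xy)
}

#' @rdname channel_geometry
#' @param geometry A `channel_geometry`.
#' @export
n_channels <- function(geometry) length(geometry$channel_ids)

#' Read/write channel geometry as JSON
#'
#' The on-disk form is a JSON array of `{id, x, y}` records.
#'
#' @param geometry A `channel_geometry`.
#' @param path File path.
#' @export
write_geometry_json <- function(geometry, path) {
  df <- data.frame(id = geometry$channel_ids,
                   x = geometry$xy[, 1], y = geometry$xy[, 2])
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  if (!file.exists(path))
    stop("geometry file not found: ", path, call. = FALSE)
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  channel_geometry(df$id, cbind(df$x, df$y))
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("channel_geometry: %d channels in [%.2f, %.2f] x [%.2f, %.2f]\n",
              n_channels(x), min(x$xy[, 1]), max(x$xy[, 1]),
              min(x$xy[, 2]), max(x$xy[, 2])))
  invisible(x)
}
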