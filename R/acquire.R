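#' Sensor frames and acquisition modes
#'
#' The simulated camera exposes a 640x480 sensor matrix and delivers
#' 320x240 (QVGA) images in one of two modes:
#'
#' * **normal** — the full field of view, subsampled by a factor of 2 in
#'   both directions (even rows and columns, phase 0);
#' * **zoom** — a full-resolution 320x240 window cropped from the sensor,
#'   displaced to follow a previously detected fruit.
#'
#' All coordinates in this package are `(row, col)`, 0-based, origin at
#' the top-left.
#'
#' @param base an `480 x 640 x 3` RGB array (8-bit channels).
#' @param mode `"normal"` or `"zoom"`.
#' @param window_origin 0-based `(row, col)` of the zoom window's
#'   top-left corner in sensor coordinates.
#' @return an object of class `sensor_frame`.
#' @export
sensor_frame <- function(base, mode = c("normal", "zoom"),
                         window_origin = c(0L, 0L)) {
  check_rgb_image(base)
  if (!identical(dim(base)[1:2], c(480L, 640L)))
    stop("the sensor base image must be 480 rows x 640 cols")
  mode <- match.arg(mode)
  window_origin <- as.integer(window_origin)
  if (mode == "zoom") check_zoom_origin(window_origin)
  structure(list(base = base, mode = mode, window_origin = window_origin),
            class = "sensor_frame")
}

check_zoom_origin <- function(origin) {
  if (length(origin) != 2L || anyNA(origin))
    stop("`origin` must be a (row, col) pair")
  if (origin[1L] < 0L || origin[2L] < 0L ||
      origin[1L] + 240L > 480L || origin[2L] + 320L > 640L)
    stop("zoom window (origin + 240 x 320) must fit inside the 640 x 480 sensor")
  invisible(origin)
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat("<sensor_frame> 640 x 480, mode:", x$mode)
  if (x$mode == "zoom")
    cat(sprintf(", window origin (%d, %d)", x$window_origin[1L], x$window_origin[2L]))
  cat("\n")
  invisible(x)
}

#' Acquire a QVGA image in normal (subsampled) mode
#'
#' Subsamples the 640x480 sensor by a factor of 2 along rows and columns
#' (`output(i, j) = base(2i, 2j)`), covering the full field of view.
#'
#' @param frame a [sensor_frame()].
#' @return a `240 x 320 x 3` RGB array.
#' @export
acquire_normal <- function(frame) {
  stopifnot(inherits(frame, "sensor_frame"))
  frame$base[seq.int(1L, 480L, 2L), seq.int(1L, 640L, 2L), , drop = FALSE]
}

#' Acquire a QVGA image in zoom (cropped-window) mode
#'
#' Crops a full-resolution 320x240 window at `origin` from the sensor:
#' `output(i, j) = base(origin_row + i, origin_col + j)`. Out-of-bounds
#' windows are an error; there is no silent clamping.
#'
#' @param frame a [sensor_frame()].
#' @param origin 0-based `(row, col)` top-left of the window; defaults to
#'   the frame's stored `window_origin`.
#' @return a `240 x 320 x 3` RGB array.
#' @export
acquire_zoom <- function(frame, origin = frame$window_origin) {
  stopifnot(inherits(frame, "sensor_frame"))
  origin <- as.integer(origin)
  check_zoom_origin(origin)
  frame$base[origin[1L] + seq_len(240L), origin[2L] + seq_len(320L), , drop = FALSE]
}

#' Zoom window origin centered on a normal-mode centroid
#'
#' Maps a centroid detected in the QVGA normal-mode image back to sensor
#' coordinates (x2) and returns the top-left origin that centers the
#' 320x240 zoom window on it, clamped so the window stays inside the
#' 640x480 sensor. This is the re-centering step of the tracking loop:
#' after a fruit is selected in the wide view, the next frame zooms onto
#' it at full resolution.
#'
#' @param centroid_qvga 0-based `(row, col)` with row in `[0, 239]` and
#'   col in `[0, 319]`.
#' @return an integer 0-based `(row, col)` origin.
#' @export
zoom_origin_from_centroid <- function(centroid_qvga) {
  c_rc <- as.numeric(centroid_qvga)
  if (length(c_rc) != 2L || anyNA(c_rc) ||
      c_rc[1L] < 0 || c_rc[1L] > 239 || c_rc[2L] < 0 || c_rc[2L] > 319)
    stop("centroid must be (row, col) with row in [0, 239] and col in [0, 319]")
  origin <- round(2 * c_rc) - c(120L, 160L)
  as.integer(pmin(pmax(origin, c(0L, 0L)), c(480L - 240L, 640L - 320L)))
}
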