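#' Threshold rules on RGB565 channel bins
#'
#' The non-LUT segmentation baselines: a pixel is foreground iff every
#' constrained channel condition holds on its decoded bin indices, with
#' strict inequalities. Bounds are expressed on the bin scales (red and
#' blue 0-31, green 0-63). The three classic shapes are single-channel
#' thresholds (`R > 16`), conjunctive RGB thresholds
#' (`R > 16 & G < 55 & B < 12`) and three-channel intervals
#' (`32 > R > 12 & 55 > G > 10 & 16 > B > 12`); all are expressed here
#' as optional lower/upper bounds per channel.
#'
#' @param r_gt,r_lt,g_gt,g_lt,b_gt,b_lt optional scalar bounds: the
#'   channel bin must be strictly greater than `*_gt` and strictly less
#'   than `*_lt`. At least one bound must be given.
#' @return an object of class `threshold_rule`.
#' @examples
#' rule <- threshold_rule(r_gt = 16, g_lt = 55, b_lt = 12)
#' @export
threshold_rule <- function(r_gt = NULL, r_lt = NULL, g_gt = NULL, g_lt = NULL,
                           b_gt = NULL, b_lt = NULL) {
  bounds <- list(r_gt = r_gt, r_lt = r_lt, g_gt = g_gt, g_lt = g_lt,
                 b_gt = b_gt, b_lt = b_lt)
  if (all(vapply(bounds, is.null, logical(1L))))
    stop("a threshold rule needs at least one bound")
  maxes <- c(r = 31, g = 63, b = 31)
  for (nm in names(bounds)) {
    v <- bounds[[nm]]
    if (is.null(v)) next
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("bound `", nm, "` must be a scalar")
    ch_max <- maxes[[substr(nm, 1L, 1L)]]
    # upper bounds are exclusive, so ch_max + 1 is legal (spans the range)
    hi_cap <- if (endsWith(nm, "lt")) ch_max + 1 else ch_max
    if (v < 0 || v > hi_cap)
      stop(sprintf("bound `%s` = %s outside channel range [0, %d]", nm, v, hi_cap))
  }
  for (ch in c("r", "g", "b")) {
    lo <- bounds[[paste0(ch, "_gt")]]; hi <- bounds[[paste0(ch, "_lt")]]
    if (!is.null(lo) && !is.null(hi) && lo >= hi)
      stop(sprintf("channel %s: lower bound %s must be below upper bound %s",
                   toupper(ch), lo, hi))
  }
  structure(bounds, class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  parts <- character(0L)
  for (ch in c("r", "g", "b")) {
    lo <- x[[paste0(ch, "_gt")]]; hi <- x[[paste0(ch, "_lt")]]
    if (!is.null(lo) && !is.null(hi))
      parts <- c(parts, sprintf("%s > %s > %s", hi, toupper(ch), lo))
    else if (!is.null(lo)) parts <- c(parts, sprintf("%s > %s", toupper(ch), lo))
    else if (!is.null(hi)) parts <- c(parts, sprintf("%s < %s", toupper(ch), hi))
  }
  cat("<threshold_rule>", paste(parts, collapse = " & "), "\n")
  invisible(x)
}

#' Segment an image with a threshold rule
#'
#' @param codes integer matrix of RGB565 codes, or an RGB array
#'   (quantized first).
#' @param rule a [threshold_rule()].
#' @return a logical mask of the image's dimensions.
#' @export
threshold_segment <- function(codes, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (is.array(codes) && length(dim(codes)) == 3L) codes <- quantize_image(codes)
  ch <- decode_rgb565(as.vector(codes))
  keep <- rep(TRUE, nrow(ch))
  idx <- c(r = 1L, g = 2L, b = 3L)
  for (cn in c("r", "g", "b")) {
    lo <- rule[[paste0(cn, "_gt")]]; hi <- rule[[paste0(cn, "_lt")]]
    if (!is.null(lo)) keep <- keep & ch[, idx[[cn]]] > lo
    if (!is.null(hi)) keep <- keep & ch[, idx[[cn]]] < hi
  }
  dim(keep) <- dim(codes)
  keep
}

#' Centroid of a binary mask
#'
#' The unweighted mean `(row, col)` of the foreground pixels, 0-based —
#' the tracking target handed to the harvesting gripper. An empty mask
#' yields a no-detection value (`support = 0`, `NA` coordinates) rather
#' than an error, so the tracking loop can react to detection loss.
#'
#' @param mask a logical matrix.
#' @return an object of class `centroid` with fields `row`, `col`
#'   (fractional, 0-based) and `support` (foreground pixel count).
#' @export
compute_centroid <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L)
    return(structure(list(row = NA_real_, col = NA_real_, support = 0L),
                     class = "centroid"))
  rows <- (idx - 1L) %% nrow(mask)
  cols <- (idx - 1L) %/% nrow(mask)
  structure(list(row = mean(rows), col = mean(cols), support = n),
            class = "centroid")
}

#' @rdname compute_centroid
#' @param x a `centroid`.
#' @return `has_detection()` returns `TRUE` iff the centroid has support.
#' @export
has_detection <- function(x) {
  stopifnot(inherits(x, "centroid"))
  x$support > 0L
}

#' @export
print.centroid <- function(x, ...) {
  if (has_detection(x))
    cat(sprintf("<centroid> (%.2f, %.2f), support %d\n", x$row, x$col, x$support))
  else cat("<centroid> no detection\n")
  invisible(x)
}

#' Restrict a mask to its largest connected component
#'
#' Used to pick one fruit out of a multi-fruit segmentation before
#' computing the tracking centroid. Components are found on the pixel
#' grid graph (via igraph) under 4- or 8-connectivity; ties in size are
#' broken in favor of the component whose first pixel comes earliest in
#' row-major scan order. An empty mask is returned unchanged.
#'
#' @param mask a logical matrix.
#' @param connectivity 4 or 8.
#' @return a logical matrix of the same dimensions.
#' @export
largest_component <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  fg <- which(mask)
  if (length(fg) == 0L) return(mask)
  h <- nrow(mask)
  node <- integer(length(mask)); node[fg] <- seq_along(fg)
  rows <- (fg - 1L) %% h; cols <- (fg - 1L) %/% h
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0L)
  for (off in offsets) {
    nr <- rows + off[1L]; nc <- cols + off[2L]
    ok <- nr >= 0L & nr < h & nc >= 0L & nc < ncol(mask)
    nb <- node[nc[ok] * h + nr[ok] + 1L]
    has <- nb > 0L
    edges <- c(edges, rbind(node[fg[ok]][has], nb[has]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  winners <- which(sizes == max(sizes))
  # fg is sorted by linear index = row-major within columns; for the
  # spec's row-major-by-rows tie rule, order candidate first-pixels by
  # (row, col)
  best <- winners[1L]
  if (length(winners) > 1L) {
    first_key <- vapply(winners, function(w) {
      i <- fg[comp == w]
      min((i - 1L) %% h * ncol(mask) + (i - 1L) %/% h)
    }, numeric(1L))
    best <- winners[which.min(first_key)]
  }
  out <- matrix(FALSE, h, ncol(mask))
  out[fg[comp == best]] <- TRUE
  out
}

#' One step of the normal/zoom tracking loop
#'
#' Acquires an image in the current mode, quantizes and segments it with
#' the LUT, optionally keeps only the largest component, and computes the
#' centroid. State transitions follow the acquisition model: a detection
#' in normal mode switches the next frame to a zoom window centered on
#' the detected fruit (coordinates scaled x2 to the sensor); an empty
#' segmentation in zoom mode falls back to normal mode to reacquire the
#' full field of view.
#'
#' @param frame a [sensor_frame()] (the current sensor content).
#' @param lut a [segmentation_lut()].
#' @param state a list with `mode` (`"normal"` or `"zoom"`) and
#'   `window_origin` (0-based `(row, col)`); defaults to normal mode.
#' @param use_largest keep only the largest connected component before
#'   the centroid (single-target tracking)?
#' @return a list with `centroid` (class `centroid`, in the coordinates
#'   of the acquired 320x240 image), `mode` (the mode that produced it),
#'   `mask`, and `next_state`.
#' @export
track_step <- function(frame, lut, state = list(mode = "normal",
                                                window_origin = c(0L, 0L)),
                       use_largest = TRUE) {
  stopifnot(inherits(frame, "sensor_frame"), inherits(lut, "segmentation_lut"))
  mode <- match.arg(state$mode, c("normal", "zoom"))
  img <- if (mode == "normal") acquire_normal(frame)
         else acquire_zoom(frame, state$window_origin)
  mask <- segment_image(quantize_image(img), lut)
  if (use_largest) mask <- largest_component(mask)
  cen <- compute_centroid(mask)
  next_state <- if (has_detection(cen) && mode == "normal") {
    list(mode = "zoom",
         window_origin = zoom_origin_from_centroid(c(cen$row, cen$col)))
  } else if (!has_detection(cen) && mode == "zoom") {
    list(mode = "normal", window_origin = c(0L, 0L))
  } else {
    list(mode = mode, window_origin = as.integer(state$window_origin))
  }
  list(centroid = cen, mode = mode, mask = mask, next_state = next_state)
}
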