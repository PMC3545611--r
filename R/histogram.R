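#' 3D color histograms over the RGB565 bin grid
#'
#' A count per RGB565 bin, accumulated from pixels manually (or, here,
#' synthetically) labeled as red peach across training images. Because
#' the histogram bins are the RGB565 bins themselves, training and
#' inference quantization coincide exactly: every color ever observed on
#' a training fruit maps to a bin that the derived LUT will recognize.
#'
#' @param counts integer vector of 65,536 non-negative counts (defaults
#'   to an empty histogram).
#' @return an object of class `color_hist3d` with fields `counts` and
#'   `total`.
#' @seealso [accumulate()], [histogram_to_lut()]
#' @export
color_histogram3d <- function(counts = integer(LUT_N)) {
  counts <- as.integer(counts)
  if (length(counts) != LUT_N || anyNA(counts) || any(counts < 0L))
    stop("`counts` must be 65,536 non-negative integers")
  structure(list(counts = counts, total = sum(counts)), class = "color_hist3d")
}

#' @export
print.color_hist3d <- function(x, ...) {
  cat(sprintf("<color_hist3d> 32 x 64 x 32 bins, %d pixels over %d occupied bins\n",
              x$total, sum(x$counts > 0L)))
  invisible(x)
}

#' Accumulate labeled fruit pixels into a histogram
#'
#' For every pixel where `fruit_mask` is true, the count of that pixel's
#' RGB565 bin increments by one. Accumulation is order-independent, so
#' training images may be folded in any sequence.
#'
#' @param hist a [color_histogram3d()].
#' @param img an `H x W x 3` RGB array (quantized internally) or an
#'   integer matrix of RGB565 codes.
#' @param fruit_mask logical `H x W` mask selecting fruit pixels.
#' @return the updated `color_hist3d`.
#' @export
accumulate <- function(hist, img, fruit_mask) {
  stopifnot(inherits(hist, "color_hist3d"))
  codes <- if (is.matrix(img)) img else quantize_image(img)
  if (!is.logical(fruit_mask) || !identical(dim(fruit_mask), dim(codes)))
    stop("`fruit_mask` must be a logical mask with the image's dimensions")
  add <- tabulate(codes[fruit_mask] + 1L, nbins = LUT_N)
  color_histogram3d(hist$counts + add)
}

#' Fit a color histogram from training images
#'
#' Folds [accumulate()] over parallel lists of images and fruit masks.
#'
#' @param images list of RGB arrays or code matrices.
#' @param fruit_masks list of logical masks, parallel to `images`.
#' @return a `color_hist3d`.
#' @export
fit_histogram <- function(images, fruit_masks) {
  if (length(images) != length(fruit_masks))
    stop("`images` and `fruit_masks` must have the same length")
  hist <- color_histogram3d()
  for (i in seq_along(images)) hist <- accumulate(hist, images[[i]], fruit_masks[[i]])
  hist
}

#' Threshold a histogram into a segmentation LUT
#'
#' A bin is labeled 1 iff its value is strictly greater than the
#' threshold. At the default threshold of zero this marks every bin that
#' ever received a training pixel, so training-set recall is 100% by
#' construction. In `"count"` mode the threshold is compared against raw
#' counts; in `"probability"` mode against `counts / total`, which is
#' the natural scale for nonzero thresholds (at zero the two modes
#' select identical bins).
#'
#' @param hist a [color_histogram3d()].
#' @param threshold non-negative scalar; strict inequality.
#' @param mode `"count"` or `"probability"`.
#' @inheritParams segmentation_lut
#' @return a [segmentation_lut()] with provenance `"histogram"`.
#' @export
histogram_to_lut <- function(hist, threshold = 0, mode = c("count", "probability"),
                             layout = c("bitpacked", "byte")) {
  stopifnot(inherits(hist, "color_hist3d"))
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop("`threshold` must be a non-negative scalar")
  values <- if (mode == "count") hist$counts
            else if (hist$total > 0L) hist$counts / hist$total
            else numeric(LUT_N)
  segmentation_lut(values > threshold, layout = match.arg(layout),
                   provenance = "histogram")
}

#' Persist a color histogram
#'
#' Raw 32-bit little-endian counts (65,536 entries, 256 KB) plus a JSON
#' sidecar `<path>.json` with `{total, dims}`.
#'
#' @param hist a [color_histogram3d()].
#' @param path payload file path.
#' @return `load_histogram()` returns the `color_hist3d`.
#' @export
save_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "color_hist3d"))
  writeBin(hist$counts, path, size = 4L, endian = "little")
  jsonlite::write_json(list(total = hist$total, dims = LUT_DIMS),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_histogram
#' @export
load_histogram <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!identical(as.integer(meta$dims), LUT_DIMS))
    stop("unsupported histogram dims in sidecar")
  counts <- readBin(path, what = "integer", n = LUT_N + 1L, size = 4L,
                    endian = "little")
  if (length(counts) != LUT_N)
    stop(sprintf("histogram payload has %d entries; expected %d",
                 length(counts), LUT_N))
  hist <- color_histogram3d(counts)
  if (hist$total != meta$total)
    stop("histogram total disagrees with sidecar")
  hist
}
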