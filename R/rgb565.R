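#' RGB565 color codes
#'
#' The 16-bit RGB565 code packs an 8-bit RGB triple into 5 bits of red
#' (bits 15..11), 6 bits of green (bits 10..5) and 5 bits of blue
#' (bits 4..0) by truncating the low-order bits of each channel. Its
#' 65,536 possible values form the index space of a [segmentation_lut()].
#'
#' Quantization is by truncation (right shift), not rounding, so the bin
#' grid used when accumulating a training histogram is identical to the
#' one indexed at segmentation time.
#'
#' @param r,g,b integer vectors of 8-bit channel values in `[0, 255]`.
#' @return `encode_rgb565()` returns an integer vector of codes in
#'   `[0, 65535]`.
#' @examples
#' encode_rgb565(255, 0, 0)  # 0xF800 = 63488
#' decode_rgb565(63488)      # r5 = 31, g6 = 0, b5 = 0
#' @export
encode_rgb565 <- function(r, g, b) {
  r <- as.integer(r); g <- as.integer(g); b <- as.integer(b)
  if (anyNA(r) || anyNA(g) || anyNA(b) ||
      any(r < 0L | r > 255L) || any(g < 0L | g > 255L) || any(b < 0L | b > 255L)) {
    stop("channel values must be integers in [0, 255]")
  }
  (r %/% 8L) * 2048L + (g %/% 4L) * 32L + (b %/% 8L)
}

#' @rdname encode_rgb565
#' @param code integer vector of RGB565 codes in `[0, 65535]`.
#' @return `decode_rgb565()` returns an integer matrix with columns
#'   `r5` (0-31), `g6` (0-63) and `b5` (0-31), one row per code.
#' @export
decode_rgb565 <- function(code) {
  code <- as.integer(code)
  if (anyNA(code) || any(code < 0L | code > 65535L)) {
    stop("RGB565 codes must be integers in [0, 65535]")
  }
  cbind(r5 = code %/% 2048L,
        g6 = (code %/% 32L) %% 64L,
        b5 = code %% 32L)
}

#' @rdname encode_rgb565
#' @details `expand_rgb565()` maps a code back to a representative 8-bit
#'   RGB triple by bit replication (`r5 << 3 | r5 >> 2`, and likewise for
#'   the other channels), the conventional 565-to-888 expansion. This is
#'   the RGB point that stands for a bin when a continuous-space
#'   classifier (such as a linear color model set) is tabulated into a
#'   LUT.
#' @return `expand_rgb565()` returns an integer matrix with columns
#'   `r`, `g`, `b` in `[0, 255]`.
#' @export
expand_rgb565 <- function(code) {
  ch <- decode_rgb565(code)
  cbind(r = ch[, 1L] * 8L + ch[, 1L] %/% 4L,
        g = ch[, 2L] * 4L + ch[, 2L] %/% 16L,
        b = ch[, 3L] * 8L + ch[, 3L] %/% 4L)
}

check_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("an RGB image must be an H x W x 3 array")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("RGB channel values must lie in [0, 255]")
  invisible(img)
}

#' Quantize an 8-bit RGB image to RGB565 codes
#'
#' Applies [encode_rgb565()] per pixel. The result is an integer matrix of
#' codes with the same height and width as the input; it is the form in
#' which images are segmented against a [segmentation_lut()].
#'
#' @param img an `H x W x 3` array of 8-bit channel values in `[0, 255]`.
#' @return an integer `H x W` matrix of RGB565 codes.
#' @export
quantize_image <- function(img) {
  check_rgb_image(img)
  codes <- encode_rgb565(img[, , 1L], img[, , 2L], img[, , 3L])
  dim(codes) <- dim(img)[1:2]
  codes
}

#' Expand an RGB565 code matrix back to an 8-bit RGB image
#'
#' Inverse-direction companion of [quantize_image()]: each code becomes its
#' bit-replicated representative triple. Quantization is lossy, so this
#' recovers the bin representative, not the original pixel.
#'
#' @param codes integer matrix of RGB565 codes.
#' @return an `H x W x 3` integer array.
#' @export
expand_image <- function(codes) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix of RGB565 codes")
  rgb <- expand_rgb565(as.vector(codes))
  array(c(rgb[, 1L], rgb[, 2L], rgb[, 3L]), dim = c(dim(codes), 3L))
}
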