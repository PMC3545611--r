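LUT_DIMS <- c(32L, 64L, 32L)
LUT_N <- 65536L

#' 3D segmentation look-up tables over the RGB565 bin grid
#'
#' A segmentation LUT stores one fruit/not-fruit bit for each of the
#' 32 x 64 x 32 = 65,536 RGB565 bins, so segmenting a pixel is a single
#' table read indexed by its 16-bit color code. Two physical layouts are
#' supported:
#'
#' * `"byte"` — one byte per bin, 65,536 bytes (64 KB); the code indexes
#'   the byte directly.
#' * `"bitpacked"` — eight bins per byte, 8,192 bytes (8 KB); the high 13
#'   bits of the code select the byte and the low 3 bits the bit within
#'   it, least-significant-bit first.
#'
#' The logical content is independent of the layout: [convert_layout()]
#' round-trips exactly, and segmentation through either layout yields
#' identical masks.
#'
#' @param bins logical vector of length 65,536, indexed by `code + 1`.
#' @param layout `"byte"` or `"bitpacked"`.
#' @param provenance how the table was built: `"lcm"` (linear color
#'   models), `"histogram"`, or `"explicit"`.
#' @return an object of class `segmentation_lut` holding the raw layout
#'   bytes.
#' @seealso [build_lut()], [segment_image()], [save_lut()]
#' @export
segmentation_lut <- function(bins, layout = c("bitpacked", "byte"),
                             provenance = c("explicit", "lcm", "histogram")) {
  layout <- match.arg(layout)
  provenance <- match.arg(provenance)
  bins <- as.logical(bins)
  if (length(bins) != LUT_N || anyNA(bins))
    stop("`bins` must be 65,536 non-missing logical values")
  structure(list(data = pack_lut_bins(bins, layout),
                 layout = layout, provenance = provenance),
            class = "segmentation_lut")
}

pack_lut_bins <- function(bins, layout) {
  switch(layout,
         byte = as.raw(bins),
         bitpacked = packBits(bins, type = "raw"))
}

#' @rdname segmentation_lut
#' @param lut a `segmentation_lut`.
#' @return `lut_bins()` returns the logical vector of all 65,536 bins.
#' @export
lut_bins <- function(lut) {
  stopifnot(inherits(lut, "segmentation_lut"))
  switch(lut$layout,
         byte = as.logical(lut$data),
         bitpacked = as.logical(rawToBits(lut$data)))
}

#' @rdname segmentation_lut
#' @return `lut_popcount()` returns the number of bins set to 1.
#' @export
lut_popcount <- function(lut) sum(lut_bins(lut))

#' @export
print.segmentation_lut <- function(x, ...) {
  cat(sprintf("<segmentation_lut> 32 x 64 x 32 bins, layout: %s (%d bytes), provenance: %s\n",
              x$layout, length(x$data), x$provenance))
  cat(sprintf("  popcount: %d / %d bins set\n", lut_popcount(x), LUT_N))
  invisible(x)
}

#' Build a segmentation LUT from an arbitrary pixel classifier
#'
#' Tabulates `classifier` over all 65,536 RGB565 codes. The classifier is
#' evaluated once per code; from then on, segmentation is a memory read.
#' If the classifier accepts a vector of codes and returns one logical
#' per code it is called once; otherwise it is called code by code.
#'
#' @param classifier a function mapping an RGB565 code (integer in
#'   `[0, 65535]`) to a single logical.
#' @inheritParams segmentation_lut
#' @return a [segmentation_lut()].
#' @examples
#' lut <- build_lut(function(code) decode_rgb565(code)[, "r5"] >= 16)
#' lut_popcount(lut)  # 32768: half the red range
#' @export
build_lut <- function(classifier, layout = c("bitpacked", "byte"),
                      provenance = c("explicit", "lcm", "histogram")) {
  codes <- 0:(LUT_N - 1L)
  bins <- tryCatch({
    out <- classifier(codes)
    if (length(out) == LUT_N) as.logical(out) else NULL
  }, error = function(e) NULL)
  if (is.null(bins)) {
    bins <- logical(LUT_N)
    for (code in codes) {
      v <- tryCatch(classifier(code), error = function(e) {
        stop(sprintf("classifier failed on code %d: %s", code, conditionMessage(e)),
             call. = FALSE)
      })
      if (length(v) != 1L || is.na(v))
        stop(sprintf("classifier returned a non-logical for code %d", code))
      bins[code + 1L] <- as.logical(v)
    }
  }
  if (anyNA(bins)) stop("classifier produced missing values")
  segmentation_lut(bins, layout = layout, provenance = provenance)
}

#' Look up RGB565 codes in a segmentation LUT
#'
#' Routes through the physical layout: in byte layout the 16-bit code
#' indexes the byte directly; in bit-packed layout `code >> 3` selects
#' the byte and `code & 7` the bit (LSB-first). Both layouts return the
#' same logical values for the same table.
#'
#' @param lut a [segmentation_lut()].
#' @param code integer vector of RGB565 codes.
#' @return a logical vector.
#' @export
lut_lookup <- function(lut, code) {
  stopifnot(inherits(lut, "segmentation_lut"))
  code <- as.integer(code)
  if (anyNA(code) || any(code < 0L | code > 65535L))
    stop("RGB565 codes must be integers in [0, 65535]")
  switch(lut$layout,
    byte = as.integer(lut$data[code + 1L]) != 0L,
    bitpacked = {
      byte <- as.integer(lut$data[code %/% 8L + 1L])
      bitwAnd(byte, bitwShiftL(1L, code %% 8L)) != 0L
    })
}

#' Segment an image with a LUT
#'
#' Applies [lut_lookup()] to every pixel code, producing a binary mask of
#' the same dimensions. This is the whole per-frame cost of LUT-based
#' detection: one table read per pixel.
#'
#' @param codes an integer matrix of RGB565 codes (see
#'   [quantize_image()]), or an `H x W x 3` RGB array which is quantized
#'   first.
#' @param lut a [segmentation_lut()].
#' @return a logical `H x W` mask.
#' @export
segment_image <- function(codes, lut) {
  if (is.array(codes) && length(dim(codes)) == 3L) codes <- quantize_image(codes)
  if (!is.matrix(codes)) stop("`codes` must be a code matrix or RGB array")
  mask <- lut_lookup(lut, as.vector(codes))
  dim(mask) <- dim(codes)
  mask
}

#' @rdname segment_image
#' @param object a `segmentation_lut`.
#' @param newdata image to segment (code matrix or RGB array).
#' @param ... unused.
#' @export
predict.segmentation_lut <- function(object, newdata, ...) {
  segment_image(newdata, object)
}

#' Convert a LUT between byte and bit-packed layouts
#'
#' The logical content is preserved exactly; converting there and back is
#' the identity on the stored bytes.
#'
#' @param lut a [segmentation_lut()].
#' @param target `"byte"` or `"bitpacked"`.
#' @return a [segmentation_lut()] in the target layout.
#' @export
convert_layout <- function(lut, target = c("bitpacked", "byte")) {
  stopifnot(inherits(lut, "segmentation_lut"))
  target <- match.arg(target)
  if (identical(lut$layout, target)) return(lut)
  segmentation_lut(lut_bins(lut), layout = target, provenance = lut$provenance)
}

#' Persist a segmentation LUT
#'
#' The LUT is written as its raw layout bytes (8,192 bytes bit-packed or
#' 65,536 bytes byte-coded) alongside a JSON sidecar
#' `<path>.json` recording `{layout, provenance, dims: [32, 64, 32]}`.
#' Bit-exact round trip; a payload whose size disagrees with the sidecar
#' dims is rejected.
#'
#' @param lut a [segmentation_lut()].
#' @param path file path for the raw payload (conventionally `.lut`).
#' @return `save_lut()` returns `path` invisibly; `load_lut()` returns
#'   the [segmentation_lut()].
#' @export
save_lut <- function(lut, path) {
  stopifnot(inherits(lut, "segmentation_lut"))
  writeBin(lut$data, path)
  jsonlite::write_json(
    list(layout = lut$layout, provenance = lut$provenance, dims = LUT_DIMS),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname save_lut
#' @export
load_lut <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!identical(as.integer(meta$dims), LUT_DIMS))
    stop("unsupported LUT dims in sidecar: ", paste(meta$dims, collapse = "x"))
  expected <- switch(meta$layout,
                     byte = LUT_N,
                     bitpacked = LUT_N %/% 8L,
                     stop("unknown layout in sidecar: ", meta$layout))
  data <- readBin(path, what = "raw", n = expected + 1L)
  if (length(data) != expected)
    stop(sprintf("LUT payload is %d bytes; %s layout requires %d",
                 length(data), meta$layout, expected))
  lut <- structure(list(data = data, layout = meta$layout,
                        provenance = meta$provenance),
                   class = "segmentation_lut")
  lut
}

#' Serialized size of masks and images
#'
#' `mask_bytes()` packs a binary mask into its physical representation:
#' bit-packed (8 pixels per byte; 9,600 bytes = 9.4 KB for a 320x240
#' mask) or byte-coded (76,800 bytes = 75 KB), the two in-memory mask
#' codings the detector trades off for speed. `image_bytes_rgb565()`
#' serializes an RGB565 code matrix as little-endian 16-bit words
#' (153,600 bytes = 150 KB at QVGA size).
#'
#' @param mask a logical matrix.
#' @param layout `"bitpacked"` or `"byte"`.
#' @return a raw vector.
#' @export
mask_bytes <- function(mask, layout = c("bitpacked", "byte")) {
  layout <- match.arg(layout)
  stopifnot(is.matrix(mask), is.logical(mask))
  v <- as.vector(mask)
  switch(layout,
         byte = as.raw(v),
         bitpacked = {
           pad <- (-length(v)) %% 8L
           packBits(c(v, logical(pad)), type = "raw")
         })
}

#' @rdname mask_bytes
#' @param codes an integer matrix of RGB565 codes.
#' @export
image_bytes_rgb565 <- function(codes) {
  stopifnot(is.matrix(codes))
  writeBin(as.integer(codes), raw(), size = 2L, endian = "little")
}
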