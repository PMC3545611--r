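#' Read and write 8-bit RGB images
#'
#' PNG files go through the png package; binary PPM (P6, maxval 255) is
#' read and written directly since no installed package handles it.
#' Either way the in-memory form is an `H x W x 3` integer array of
#' 8-bit channel values.
#'
#' @param path file path ending in `.png` or `.ppm`.
#' @return `read_image()` returns an `H x W x 3` integer array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
    if (dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE]
    return(array(as.integer(round(px * 255)), dim = dim(px)))
  }
  if (ext == "ppm") return(read_ppm(path))
  stop("unsupported image format: .", ext)
}

#' @rdname read_image
#' @param img an `H x W x 3` array of channel values in `[0, 255]`.
#' @export
write_image <- function(img, path) {
  check_rgb_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext == "ppm") {
    write_ppm(img, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PPM header")
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
                                if (length(c2) == 0L || c2 == "\n") break } }
      else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  if (token() != "P6") stop("not a binary PPM (P6) file")
  w <- as.integer(token()); h <- as.integer(token()); maxval <- as.integer(token())
  if (is.na(w) || is.na(h) || maxval != 255L)
    stop("unsupported PPM header (need maxval 255)")
  raw <- readBin(con, what = "raw", n = 3L * w * h)
  if (length(raw) != 3L * w * h) stop("truncated PPM payload")
  vals <- as.integer(raw)
  # PPM stores interleaved RGB in row-major order
  arr <- array(vals, dim = c(3L, w, h))
  aperm(arr, c(3L, 2L, 1L))
}

write_ppm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", dim(img)[2L], dim(img)[1L]), con,
            eos = NULL)
  writeBin(as.raw(aperm(img, c(3L, 2L, 1L))), con)
  invisible(path)
}

#' Persist binary masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNGs with foreground 255 and
#' background 0; any nonzero pixel reads back as foreground.
#'
#' @param mask a logical matrix.
#' @param path a `.png` path.
#' @return `read_mask()` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px > 0
}

#' Persist RGB565 code matrices as raw 16-bit streams
#'
#' Little-endian 16-bit words in row-major order (matching how the frame
#' buffer delivers pixels), with a JSON sidecar `<path>.json` holding
#' `{height, width, format: "RGB565"}`.
#'
#' @param codes an integer matrix of RGB565 codes.
#' @param path payload file path.
#' @return `load_rgb565()` returns the code matrix.
#' @export
save_rgb565 <- function(codes, path) {
  stopifnot(is.matrix(codes))
  row_major <- as.integer(t(codes))
  writeBin(writeBin(row_major, raw(), size = 2L, endian = "little"), path)
  jsonlite::write_json(list(height = nrow(codes), width = ncol(codes),
                            format = "RGB565"),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_rgb565
#' @export
load_rgb565 <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!identical(meta$format, "RGB565")) stop("sidecar format is not RGB565")
  n <- meta$height * meta$width
  vals <- readBin(path, what = "integer", n = n + 1L, size = 2L,
                  endian = "little", signed = FALSE)
  if (length(vals) != n) stop("RGB565 payload size disagrees with sidecar")
  matrix(vals, nrow = meta$height, byrow = TRUE)
}
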