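#' Linear color models in RGB space
#'
#' A linear color model represents the colors of one object class (a
#' peach skin variant, foliage, branches, sky, ...) as a line segment in
#' 3D RGB space plus a distance tolerance. The segment captures how the
#' object's color slides along an illumination locus — from dark to
#' brightly lit — so a single model extrapolates color/illumination
#' relationships that a histogram can only memorize. A pixel belongs to
#' the class of the nearest segment, provided it lies within that model's
#' cylinder radius.
#'
#' @param label class name, e.g. `"bright-peach"` or `"leaf-dark"`.
#' @param p0,p1 numeric RGB triples in `[0, 255]^3`, the segment
#'   endpoints; must differ.
#' @param radius Euclidean distance tolerance in RGB units; positive.
#' @return an object of class `linear_color_model`.
#' @seealso [fit_color_model()], [model_set()], [classify_pixel()]
#' @export
linear_color_model <- function(label, p0, p1, radius) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 3L || length(p1) != 3L || anyNA(c(p0, p1)))
    stop("`p0` and `p1` must be RGB triples")
  if (any(c(p0, p1) < 0) || any(c(p0, p1) > 255))
    stop("segment endpoints must lie in [0, 255]^3")
  if (all(p0 == p1)) stop("segment endpoints must differ")
  radius <- as.numeric(radius)
  if (length(radius) != 1L || is.na(radius) || radius <= 0)
    stop("`radius` must be a positive scalar")
  structure(list(label = as.character(label), p0 = p0, p1 = p1, radius = radius),
            class = "linear_color_model")
}

#' @export
print.linear_color_model <- function(x, ...) {
  cat(sprintf("<linear_color_model> %s: (%s) -- (%s), radius %.2f\n",
              x$label, paste(round(x$p0, 1), collapse = ","),
              paste(round(x$p1, 1), collapse = ","), x$radius))
  invisible(x)
}

#' Fit a linear color model to labeled pixels
#'
#' The segment axis is the first principal axis of the pixel cloud
#' through its mean; the endpoints are the orthogonal projections of the
#' extreme pixels onto that axis, clipped to `[0, 255]^3`. The radius is
#' the largest point-to-axis distance among the training pixels, with a
#' floor of 1 RGB unit so that a perfectly collinear cloud still accepts
#' its own pixels after quantization.
#'
#' @param pixels an `N x 3` numeric matrix of RGB training pixels
#'   (`N >= 2`, not all identical).
#' @param label class name for the fitted model.
#' @return a [linear_color_model()].
#' @export
fit_color_model <- function(pixels, label) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || ncol(pixels) != 3L || nrow(pixels) < 2L)
    stop("`pixels` must be an N x 3 numeric matrix with N >= 2")
  mu <- colMeans(pixels)
  centered <- sweep(pixels, 2L, mu)
  if (all(abs(centered) < .Machine$double.eps^0.5))
    stop("degenerate pixel cloud: all training pixels are identical")
  v <- svd(centered, nu = 0L, nv = 1L)$v[, 1L]
  score <- drop(centered %*% v)
  p0 <- pmin(pmax(mu + min(score) * v, 0), 255)
  p1 <- pmin(pmax(mu + max(score) * v, 0), 255)
  perp <- sqrt(pmax(rowSums(centered^2) - score^2, 0))
  linear_color_model(label, p0, p1, radius = max(max(perp), 1))
}

#' Distance from RGB points to a linear color model
#'
#' Euclidean distance to the closed segment `[p0, p1]`: the perpendicular
#' distance where the orthogonal foot falls inside the segment, and the
#' distance to the nearer endpoint otherwise.
#'
#' @param rgb an RGB triple or `N x 3` matrix of triples.
#' @param m a [linear_color_model()].
#' @return a numeric vector of distances in RGB units.
#' @export
distance_to_model <- function(rgb, m) {
  stopifnot(inherits(m, "linear_color_model"))
  rgb <- rgb_matrix(rgb)
  d <- m$p1 - m$p0
  len2 <- sum(d^2)
  t <- pmin(pmax((sweep(rgb, 2L, m$p0) %*% d) / len2, 0), 1)
  foot <- outer(drop(t), d) + rep(m$p0, each = nrow(rgb))
  sqrt(rowSums((rgb - foot)^2))
}

rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(as.numeric(rgb), ncol = 3L)
  storage.mode(rgb) <- "double"
  if (ncol(rgb) != 3L || anyNA(rgb)) stop("`rgb` must be RGB triples")
  rgb
}

#' Sets of linear color models
#'
#' An ordered collection of [linear_color_model()]s covering every object
#' class in the scene, with a designated subset of labels counting as
#' fruit. Modeling every class (not just the fruit) matters: background
#' models compete for pixels near the fruit locus and suppress false
#' positives.
#'
#' @param models a list of [linear_color_model()]s (at least one).
#' @param fruit_labels non-empty character vector; a subset of the model
#'   labels identifying the "red peach" classes.
#' @return an object of class `lcm_set`.
#' @export
model_set <- function(models, fruit_labels) {
  if (length(models) == 0L || !all(vapply(models, inherits, logical(1L), "linear_color_model")))
    stop("`models` must be a non-empty list of linear_color_model objects")
  labels <- vapply(models, `[[`, character(1L), "label")
  fruit_labels <- as.character(fruit_labels)
  if (length(fruit_labels) == 0L || !all(fruit_labels %in% labels))
    stop("`fruit_labels` must be a non-empty subset of the model labels")
  structure(list(models = models, fruit_labels = fruit_labels), class = "lcm_set")
}

#' @export
print.lcm_set <- function(x, ...) {
  cat(sprintf("<lcm_set> %d linear color models (%d fruit classes)\n",
              length(x$models), length(x$fruit_labels)))
  for (m in x$models) {
    fruit <- if (m$label %in% x$fruit_labels) " [fruit]" else ""
    cat(sprintf("  %-16s (%s) -- (%s)  r=%.1f%s\n", m$label,
                paste(round(m$p0), collapse = ","),
                paste(round(m$p1), collapse = ","), m$radius, fruit))
  }
  invisible(x)
}

#' Fit a model set from labeled pixel classes
#'
#' Convenience wrapper fitting one [fit_color_model()] per labeled pixel
#' set. This is the training entry point for the linear-color-model
#' route: hand it per-class pixel samples (e.g. from
#' [generate_training_set()]) and the fruit labels.
#'
#' @param pixel_sets a named list of `N x 3` RGB pixel matrices, one per
#'   class.
#' @param fruit_labels labels (names of `pixel_sets`) counting as fruit.
#' @return an `lcm_set`.
#' @export
fit_lcm <- function(pixel_sets, fruit_labels) {
  if (is.null(names(pixel_sets)) || any(names(pixel_sets) == ""))
    stop("`pixel_sets` must be a named list of pixel matrices")
  models <- lapply(names(pixel_sets), function(lab)
    fit_color_model(pixel_sets[[lab]], lab))
  model_set(models, fruit_labels)
}

#' Classify pixels against a model set
#'
#' Assigns each pixel the label of the model at minimal
#' [distance_to_model()]; ties go to the lowest model index. When
#' `reject = TRUE` (the default) a pixel whose minimal distance exceeds
#' that model's radius receives the reserved label `"unmodeled"`.
#'
#' @param rgb an RGB triple or `N x 3` matrix.
#' @param ms an [model_set()].
#' @param reject reject pixels outside every model's cylinder?
#' @return a character vector of labels.
#' @export
classify_pixel <- function(rgb, ms, reject = TRUE) {
  stopifnot(inherits(ms, "lcm_set"))
  rgb <- rgb_matrix(rgb)
  d <- vapply(ms$models, function(m) distance_to_model(rgb, m),
              numeric(nrow(rgb)))
  d <- matrix(d, nrow = nrow(rgb))
  best <- max.col(-d, ties.method = "first")
  labels <- vapply(ms$models, `[[`, character(1L), "label")[best]
  if (reject) {
    radii <- vapply(ms$models, `[[`, numeric(1L), "radius")[best]
    dist_best <- d[cbind(seq_len(nrow(d)), best)]
    labels[dist_best > radii] <- "unmodeled"
  }
  labels
}

#' Tabulate a model set into a segmentation LUT
#'
#' Classifies the bit-replicated representative RGB point of every RGB565
#' bin (see [expand_rgb565()]) and sets the bin to 1 iff the winning
#' label is one of the set's fruit labels. The per-pixel cost of
#' nearest-segment classification — prohibitive at frame rate — is paid
#' once here; segmentation through the resulting LUT is then exactly
#' equivalent to direct classification of the quantized image.
#'
#' @param ms an [model_set()].
#' @inheritParams segmentation_lut
#' @param reject passed to [classify_pixel()].
#' @return a [segmentation_lut()] with provenance `"lcm"`.
#' @export
build_lcm_lut <- function(ms, layout = c("bitpacked", "byte"), reject = TRUE) {
  stopifnot(inherits(ms, "lcm_set"))
  reps <- expand_rgb565(0:65535)
  labels <- classify_pixel(reps, ms, reject = reject)
  segmentation_lut(labels %in% ms$fruit_labels,
                   layout = match.arg(layout), provenance = "lcm")
}

#' @rdname classify_pixel
#' @param object an `lcm_set`.
#' @param newdata RGB triples, an RGB image array, or a code matrix.
#' @param ... unused.
#' @return `predict.lcm_set()` returns labels for RGB input, or a logical
#'   fruit mask for image input.
#' @export
predict.lcm_set <- function(object, newdata, ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3L) {
    codes <- quantize_image(newdata)
    labels <- classify_pixel(expand_rgb565(as.vector(codes)), object)
    mask <- labels %in% object$fruit_labels
    dim(mask) <- dim(codes)
    return(mask)
  }
  classify_pixel(newdata, object)
}

#' Read and write model sets as JSON
#'
#' The on-disk form is
#' `{"models": [{"label", "p0", "p1", "radius"}, ...], "fruit_labels": [...]}`.
#' Files are validated on load through the [model_set()] constructor.
#'
#' @param ms an [model_set()].
#' @param path a JSON file path.
#' @return `read_model_set()` returns an `lcm_set`.
#' @export
write_model_set <- function(ms, path) {
  stopifnot(inherits(ms, "lcm_set"))
  jsonlite::write_json(
    list(models = lapply(ms$models, function(m)
           list(label = m$label, p0 = m$p0, p1 = m$p1, radius = m$radius)),
         fruit_labels = as.list(ms$fruit_labels)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$models) || is.null(js$fruit_labels))
    stop("model-set JSON must contain `models` and `fruit_labels`")
  models <- lapply(js$models, function(m) {
    if (is.null(m$label) || is.null(m$p0) || is.null(m$p1) || is.null(m$radius))
      stop("each model needs `label`, `p0`, `p1` and `radius`")
    linear_color_model(m$label, unlist(m$p0), unlist(m$p1), m$radius)
  })
  model_set(models, unlist(js$fruit_labels))
}

#' The bundled 11-class demonstration model set
#'
#' Four red-peach skin variants (bright, dark, yellowish, brownish) plus
#' seven background classes (bright/dark foliage, grass, branch, trunk,
#' soil, sky). The endpoints are synthetic — chosen to match the color
#' palette of the synthetic orchard generator — not measurements of real
#' fruit.
#'
#' @return an [model_set()] with 11 models.
#' @export
default_model_set <- function() {
  read_model_set(system.file("extdata", "models_11class_synthetic.json",
                             package = "peachlut", mustWork = TRUE))
}
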