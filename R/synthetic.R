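#' Color palettes of the synthetic orchard
#'
#' Each class is a color locus: a segment from its dark end (`p0`) to its
#' bright end (`p1`) in 8-bit RGB. Peach skin comes in four variants
#' (bright red, dark red, yellowish, brownish); the background mixes
#' foliage, grass, wood, soil and sky. The values are synthetic defaults
#' chosen to look like an orchard under daylight, not measurements of
#' real fruit; the bundled 11-class model set uses the same loci.
#'
#' @return a named list of `list(p0, p1)` color loci.
#' @export
peach_palette <- function() {
  list(
    "bright-peach"    = list(p0 = c(170, 45, 35), p1 = c(255, 120, 95)),
    "dark-peach"      = list(p0 = c(110, 20, 18), p1 = c(185, 55, 45)),
    "yellowish-peach" = list(p0 = c(210, 140, 60), p1 = c(255, 205, 120)),
    "brownish-peach"  = list(p0 = c(130, 60, 35), p1 = c(195, 110, 70)))
}

#' @rdname peach_palette
#' @export
foliage_palette <- function() {
  list(
    "leaf-bright" = list(p0 = c(60, 140, 40), p1 = c(120, 205, 90)),
    "leaf-dark"   = list(p0 = c(18, 60, 15), p1 = c(60, 115, 45)),
    "grass"       = list(p0 = c(90, 130, 50), p1 = c(150, 185, 90)),
    "branch"      = list(p0 = c(70, 50, 30), p1 = c(115, 88, 60)),
    "trunk"       = list(p0 = c(42, 34, 24), p1 = c(82, 62, 46)),
    "soil"        = list(p0 = c(108, 88, 58), p1 = c(162, 132, 96)),
    "sky"         = list(p0 = c(178, 198, 218), p1 = c(240, 246, 255)))
}

#' Parameters of a synthetic orchard scene
#'
#' The generator emulates the imaging conditions of an orchard survey:
#' ellipsoidal red peaches with radial shading along one of four skin
#' color variants, a blocky foliage/wood/sky background, a global
#' multiplicative illumination gain (`bright` = 1.0, `low` = 0.65),
#' per-pixel Gaussian sensor jitter, and opaque leaf-shaped occluders
#' drawn over fruit until each fruit's exact occlusion ratio lands in the
#' requested bin.
#'
#' @param n_fruit number of peaches (0 allowed).
#' @param fruit_radius `(min, max)` semi-major axis in sensor pixels.
#' @param illumination `"bright"` or `"low"`.
#' @param occlusion_bin `"none"`, `"<33%"`, `"33-66%"` or `"66-99%"`.
#' @param noise_sd standard deviation of the per-pixel Gaussian channel
#'   jitter, in 8-bit RGB units.
#' @param illumination_gains named gains applied multiplicatively to the
#'   whole scene.
#' @param seed integer seed; regeneration from the same seed and
#'   parameters is bit-identical.
#' @param scene_id optional identifier carried into evaluation records.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(n_fruit = 3L, fruit_radius = c(26, 55),
                         illumination = c("bright", "low"),
                         occlusion_bin = c("none", "<33%", "33-66%", "66-99%"),
                         noise_sd = 4,
                         illumination_gains = c(bright = 1.0, low = 0.65),
                         seed = 1L, scene_id = NULL) {
  illumination <- match.arg(illumination)
  occlusion_bin <- match.arg(occlusion_bin)
  n_fruit <- as.integer(n_fruit)
  stopifnot(n_fruit >= 0L, length(fruit_radius) == 2L,
            fruit_radius[1L] > 4, fruit_radius[2L] >= fruit_radius[1L],
            noise_sd >= 0, all(illumination_gains > 0))
  structure(list(n_fruit = n_fruit, fruit_radius = as.numeric(fruit_radius),
                 illumination = illumination, occlusion_bin = occlusion_bin,
                 noise_sd = noise_sd, illumination_gains = illumination_gains,
                 seed = as.integer(seed),
                 scene_id = if (is.null(scene_id)) sprintf("scene-%d", seed)
                            else as.character(scene_id)),
            class = "scene_params")
}

# Inner target ranges per occlusion bin, kept clear of the bin edges so
# the exact mask-derived ratio stays inside the requested bin.
OCCLUSION_TARGETS <- list(
  "none"    = c(0, 0),
  "<33%"    = c(0.08, 0.29),
  "33-66%"  = c(0.36, 0.63),
  "66-99%"  = c(0.69, 0.93))

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sample_locus <- function(locus, t) {
  outer(t, locus$p1 - locus$p0) + rep(locus$p0, each = length(t))
}

paint_pixels <- function(img, mask, colors) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- colors[, ch]
    img[, , ch] <- plane
  }
  img
}

ellipse_field <- function(h, w, center, a, b, theta = 0) {
  dr <- matrix(seq_len(h) - 1 - center[1L], h, w)
  dc <- matrix(seq_len(w) - 1 - center[2L], h, w, byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2
}

render_background <- function(h, w, cell = 16L) {
  pal <- foliage_palette()
  weights <- c("leaf-bright" = 0.30, "leaf-dark" = 0.24, "grass" = 0.14,
               "branch" = 0.09, "trunk" = 0.05, "soil" = 0.11, "sky" = 0.07)
  gh <- h %/% cell; gw <- w %/% cell
  ids <- matrix(sample(seq_along(pal), gh * gw, replace = TRUE,
                       prob = weights[names(pal)]), gh, gw)
  tval <- matrix(runif(gh * gw), gh, gw)
  up <- matrix(1, cell, cell)
  labels <- kronecker(ids, up)
  tfull <- kronecker(tval, up)
  img <- array(0, dim = c(h, w, 3L))
  for (k in seq_along(pal)) {
    sel <- labels == k
    if (!any(sel)) next
    img <- paint_pixels(img, sel, sample_locus(pal[[k]], tfull[sel]))
  }
  list(img = img, labels = labels, classes = names(pal))
}

place_fruit <- function(h, w, n, radius_range) {
  placements <- list()
  for (k in seq_len(n)) {
    for (try in 1:80) {
      a <- runif(1L, radius_range[1L], radius_range[2L])
      b <- a * runif(1L, 0.78, 1.05)
      center <- c(runif(1L, a + 8, h - a - 8), runif(1L, b + 8, w - b - 8))
      ok <- TRUE
      for (p in placements) {
        if (sqrt(sum((center - p$center)^2)) < 0.85 * (max(a, b) + max(p$a, p$b))) {
          ok <- FALSE; break
        }
      }
      if (ok) { placements[[k]] <- list(center = center, a = a, b = b); break }
    }
    if (length(placements) < k)
      stop("could not place fruit without heavy overlap; fewer or smaller fruit needed")
  }
  placements
}

occlude_fruit <- function(fruit_mask, placement, target, h, w, forbidden) {
  a <- placement$a; b <- placement$b; center <- placement$center
  fruit_n <- sum(fruit_mask)
  for (restart in 1:20) {
    occ <- matrix(FALSE, h, w)
    ratio <- 0
    for (leaf in 1:40) {
      if (ratio >= target[1L]) break
      ang <- runif(1L, 0, 2 * pi)
      # leaf centered between the fruit rim and its middle, long axis random
      rad <- runif(1L, 0.35, 0.95)
      lc <- center + rad * c(a * sin(ang), b * cos(ang))
      la <- a * runif(1L, 0.40, 0.60)
      lb <- la * runif(1L, 0.38, 0.55)
      leaf_mask <- ellipse_field(h, w, lc, la, lb, runif(1L, 0, pi)) <= 1
      # leaves targeting this fruit stay off the others so every fruit's
      # ratio is controlled independently
      leaf_mask[forbidden] <- FALSE
      occ <- occ | leaf_mask
      ratio <- sum(fruit_mask & occ) / fruit_n
    }
    if (ratio >= target[1L] && ratio <= target[2L]) return(occ)
  }
  stop(sprintf("could not reach occlusion target [%.2f, %.2f] after bounded retries",
               target[1L], target[2L]))
}

#' Generate a synthetic orchard scene with ground truth
#'
#' Renders a 640x480 sensor frame and records, per fruit, the full
#' (pre-occlusion) mask, the visible (post-occlusion) mask, the skin
#' variant and the exact occlusion ratio computed from the masks. The
#' same seed and parameters always reproduce the scene bit-identically,
#' and the generator leaves the caller's RNG state untouched.
#'
#' @param params a [scene_params()].
#' @return an object of class `orchard_scene` with fields `frame`
#'   ([sensor_frame()]), `fruit_masks`, `visible_masks` (lists of
#'   480x640 logical matrices), `occlusion_ratios`, `occluder_mask`,
#'   `background_labels` (integer matrix of background class ids, with
#'   `background_classes` naming them), `fruit_variants`, `illumination`,
#'   `occlusion_bin`, `scene_id` and `seed`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  h <- 480L; w <- 640L
  with_preserved_rng(params$seed, {
    bg <- render_background(h, w)
    img <- bg$img
    placements <- place_fruit(h, w, params$n_fruit, params$fruit_radius)
    pal <- peach_palette()
    variants <- if (params$n_fruit > 0L)
      sample(names(pal), params$n_fruit, replace = TRUE) else character(0L)
    fruit_masks <- vector("list", params$n_fruit)
    for (k in seq_len(params$n_fruit)) {
      p <- placements[[k]]
      e <- ellipse_field(h, w, p$center, p$a, p$b)
      mask <- e <= 1
      fruit_masks[[k]] <- mask
      # radial shading: bright at the center, darker toward the rim
      t <- pmin(pmax(1 - 0.8 * sqrt(e[mask]), 0), 1)
      t <- pmin(pmax(t + rnorm(length(t), 0, 0.04), 0), 1)
      img <- paint_pixels(img, mask, sample_locus(pal[[variants[k]]], t))
    }
    # opaque leaf occluders, per fruit, until the exact ratio hits the bin
    occluder <- matrix(FALSE, h, w)
    target <- OCCLUSION_TARGETS[[params$occlusion_bin]]
    if (params$occlusion_bin != "none" && params$n_fruit > 0L) {
      for (k in seq_len(params$n_fruit)) {
        others <- Reduce(`|`, fruit_masks[-k], matrix(FALSE, h, w))
        occluder <- occluder |
          occlude_fruit(fruit_masks[[k]], placements[[k]], target, h, w, others)
      }
    }
    if (any(occluder)) {
      lp <- foliage_palette()
      which_leaf <- sample(c("leaf-bright", "leaf-dark"), 1L)
      img <- paint_pixels(img, occluder,
                          sample_locus(lp[[which_leaf]], runif(sum(occluder))))
    }
    gain <- params$illumination_gains[[params$illumination]]
    img <- img * gain
    if (params$noise_sd > 0)
      img <- img + rnorm(length(img), 0, params$noise_sd)
    img <- array(as.integer(pmin(pmax(round(img), 0), 255)), dim = dim(img))

    visible_masks <- lapply(fruit_masks, function(m) m & !occluder)
    ratios <- vapply(seq_len(params$n_fruit), function(k)
      sum(fruit_masks[[k]] & occluder) / sum(fruit_masks[[k]]), numeric(1L))
    fruit_any <- Reduce(`|`, fruit_masks, matrix(FALSE, h, w))
    background_labels <- bg$labels
    background_labels[fruit_any | occluder] <- 0L

    structure(list(frame = sensor_frame(img),
                   fruit_masks = fruit_masks, visible_masks = visible_masks,
                   occlusion_ratios = ratios, occluder_mask = occluder,
                   background_labels = background_labels,
                   background_classes = bg$classes,
                   fruit_variants = variants,
                   illumination = params$illumination,
                   occlusion_bin = params$occlusion_bin,
                   scene_id = params$scene_id, seed = params$seed),
              class = "orchard_scene")
  })
}

#' @export
print.orchard_scene <- function(x, ...) {
  cat(sprintf("<orchard_scene> %s: %d fruit, %s illumination, occlusion %s\n",
              x$scene_id, length(x$fruit_masks), x$illumination, x$occlusion_bin))
  if (length(x$occlusion_ratios))
    cat("  occlusion ratios:",
        paste(sprintf("%.2f", x$occlusion_ratios), collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth fruit mask of a scene
#'
#' Union of the per-fruit masks, either the full pre-occlusion extent or
#' only the visible pixels, in sensor (640x480) or normal-mode QVGA
#' (320x240, 2x-subsampled) resolution.
#'
#' @param scene an `orchard_scene`.
#' @param which `"full"` or `"visible"`.
#' @param resolution `"sensor"` or `"qvga"`.
#' @return a logical matrix.
#' @export
scene_gt_mask <- function(scene, which = c("full", "visible"),
                          resolution = c("qvga", "sensor")) {
  stopifnot(inherits(scene, "orchard_scene"))
  which <- match.arg(which); resolution <- match.arg(resolution)
  masks <- if (which == "full") scene$fruit_masks else scene$visible_masks
  m <- Reduce(`|`, masks, matrix(FALSE, 480L, 640L))
  if (resolution == "qvga") m <- m[seq.int(1L, 480L, 2L), seq.int(1L, 640L, 2L)]
  m
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 1000003) %% 2147483629)
}

#' Generate a batch of scenes with split seeds
#'
#' Each scene gets its own seed derived from the batch seed, so any
#' scene is independently reproducible.
#'
#' @param n_scenes number of scenes.
#' @param seed batch seed.
#' @param ... passed to [scene_params()] (everything but `seed` /
#'   `scene_id`).
#' @param id_prefix prefix for scene identifiers.
#' @return a list of `orchard_scene` objects.
#' @export
generate_scenes <- function(n_scenes, seed = 1L, ..., id_prefix = "scene") {
  lapply(seq_len(n_scenes), function(i) {
    generate_scene(scene_params(..., seed = derive_seed(seed, i),
                                scene_id = sprintf("%s-%03d", id_prefix, i)))
  })
}

#' Generate a labeled training set for both LUT-building routes
#'
#' Emulates the manual labeling step: QVGA normal-mode images with
#' visible-fruit masks (for histogram accumulation) and per-class pixel
#' sets (for fitting linear color models) — the four peach skin variants
#' plus the seven background classes, eleven classes in all. Fruit and
#' background labels never overlap; occluded fruit pixels are excluded
#' from both.
#'
#' @param n_scenes number of training scenes.
#' @param seed batch seed.
#' @param max_pixels_per_class cap on sampled pixels per class for the
#'   model-fitting sets.
#' @param ... passed to [scene_params()].
#' @return a list with `scenes`, `images` (QVGA RGB arrays),
#'   `fruit_masks` and `background_masks` (QVGA logical), and
#'   `pixel_sets` (named list of `N x 3` RGB matrices, one per class).
#' @export
generate_training_set <- function(n_scenes, seed = 1L,
                                  max_pixels_per_class = 4000L, ...) {
  stopifnot(n_scenes >= 1L)
  scenes <- generate_scenes(n_scenes, seed = seed, ..., id_prefix = "train")
  sub_r <- seq.int(1L, 480L, 2L); sub_c <- seq.int(1L, 640L, 2L)
  images <- lapply(scenes, function(s) acquire_normal(s$frame))
  fruit_masks <- lapply(scenes, scene_gt_mask, which = "visible")
  background_masks <- lapply(scenes, function(s)
    s$background_labels[sub_r, sub_c] > 0L)

  pixel_sets <- list()
  add_pixels <- function(label, img, sel) {
    if (!any(sel)) return(invisible(NULL))
    px <- cbind(img[, , 1L][sel], img[, , 2L][sel], img[, , 3L][sel])
    pixel_sets[[label]] <<- rbind(pixel_sets[[label]], px)
    invisible(NULL)
  }
  for (i in seq_along(scenes)) {
    s <- scenes[[i]]; img <- images[[i]]
    for (k in seq_along(s$fruit_masks)) {
      add_pixels(s$fruit_variants[k], img, s$visible_masks[[k]][sub_r, sub_c])
    }
    bg <- s$background_labels[sub_r, sub_c]
    for (ci in seq_along(s$background_classes)) {
      add_pixels(s$background_classes[ci], img, bg == ci)
    }
  }
  pixel_sets <- lapply(pixel_sets, function(px) {
    if (nrow(px) > max_pixels_per_class)
      px <- px[seq.int(1L, nrow(px), length.out = max_pixels_per_class), , drop = FALSE]
    px
  })
  list(scenes = scenes, images = images, fruit_masks = fruit_masks,
       background_masks = background_masks, pixel_sets = pixel_sets)
}
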