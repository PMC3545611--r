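#' Segmentation quality metrics against a labeled ground truth
#'
#' Two complementary percentages compare an automatic segmentation
#' `pred` with a reference fruit mask `gt`:
#'
#' * **area relative error** — `100 * |area(pred) - area(gt)| / area(gt)`,
#'   the absolute mismatch between the segmented fruit area and the
#'   labeled area, in percent of the labeled area;
#' * **noise fraction** — `100 * area(pred \ gt) / area(gt)`, the
#'   false-positive ("noisy") pixels outside the labeled fruit relative
#'   to the labeled area.
#'
#' Both default to the labeled fruit area as denominator
#' (`denom = "gt"`); `denom = "frame"` normalizes by the full frame
#' instead. An empty ground truth leaves the metric undefined and is an
#' error.
#'
#' @param pred,gt logical masks of identical dimensions; `gt` non-empty.
#' @param denom `"gt"` or `"frame"`.
#' @return a percentage (numeric scalar).
#' @export
area_relative_error <- function(pred, gt, denom = c("gt", "frame")) {
  check_mask_pair(pred, gt)
  d <- switch(match.arg(denom), gt = sum(gt), frame = length(gt))
  100 * abs(sum(pred) - sum(gt)) / d
}

#' @rdname area_relative_error
#' @export
noise_fraction <- function(pred, gt, denom = c("gt", "frame")) {
  check_mask_pair(pred, gt)
  d <- switch(match.arg(denom), gt = sum(gt), frame = length(gt))
  100 * sum(pred & !gt) / d
}

check_mask_pair <- function(pred, gt) {
  if (!is.logical(pred) || !is.logical(gt) || !identical(dim(pred), dim(gt)))
    stop("`pred` and `gt` must be logical masks of identical dimensions")
  if (sum(gt) == 0L)
    stop("empty ground truth: metric undefined")
  invisible(NULL)
}

#' Run the two-LUT comparison protocol over a scene batch
#'
#' For each scene: acquire the normal-mode QVGA image, quantize it, and
#' segment it once per method; then score each segmentation against the
#' scene's labeled fruit mask. Scene condition tags (illumination,
#' occlusion bin) ride along so results can be stratified.
#'
#' @param scenes list of [generate_scene()] results (class
#'   `orchard_scene`).
#' @param luts named list of [segmentation_lut()]s, e.g.
#'   `list(lcm_lut = ..., histogram_lut = ...)`.
#' @param gt which ground truth to score against: `"full"` (the complete
#'   fruit extent, including pixels hidden by occluders) or `"visible"`
#'   (only unoccluded fruit pixels).
#' @return a data.frame with one row per scene x method: `scene_id`,
#'   `method`, `illumination`, `occlusion_bin`, `area_rel_error_pct`,
#'   `noise_fraction_pct`.
#' @export
run_comparison <- function(scenes, luts, gt = c("full", "visible")) {
  gt <- match.arg(gt)
  if (is.null(names(luts)) || any(names(luts) == ""))
    stop("`luts` must be a named list of segmentation LUTs")
  rows <- list()
  for (s in scenes) {
    stopifnot(inherits(s, "orchard_scene"))
    codes <- quantize_image(acquire_normal(s$frame))
    gt_mask <- scene_gt_mask(s, which = gt, resolution = "qvga")
    for (method in names(luts)) {
      pred <- segment_image(codes, luts[[method]])
      rows[[length(rows) + 1L]] <- data.frame(
        scene_id = s$scene_id, method = method,
        illumination = s$illumination, occlusion_bin = s$occlusion_bin,
        area_rel_error_pct = area_relative_error(pred, gt_mask),
        noise_fraction_pct = noise_fraction(pred, gt_mask),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate comparison records into stratified mean tables
#'
#' Unweighted per-scene means of both metrics for every method x stratum
#' cell, where the stratum is either the illumination tag or the
#' occlusion bin. Strata with no scenes are reported as missing (`NA`),
#' never as zero.
#'
#' @param records the data.frame from [run_comparison()].
#' @param by `"illumination"` or `"occlusion_bin"`.
#' @return a data.frame of per-stratum means with columns `method`,
#'   the stratum, `n_scenes`, `area_rel_error_pct`, `noise_fraction_pct`.
#' @export
summarize_comparison <- function(records, by = c("illumination", "occlusion_bin")) {
  by <- match.arg(by)
  strata <- if (by == "illumination") c("bright", "low")
            else c("none", "<33%", "33-66%", "66-99%")
  methods <- unique(records$method)
  grid <- expand.grid(method = methods, stratum = strata,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- records$method == grid$method[i] & records[[by]] == grid$stratum[i]
    n <- sum(sel)
    data.frame(method = grid$method[i], stratum = grid$stratum[i], n_scenes = n,
               area_rel_error_pct = if (n) mean(records$area_rel_error_pct[sel]) else NA_real_,
               noise_fraction_pct = if (n) mean(records$noise_fraction_pct[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "stratum"] <- by
  out
}

#' Render the four-table comparison layout as markdown
#'
#' Emits the standard report: area relative error by illumination, area
#' relative error by occlusion, noise fraction by illumination, noise
#' fraction by occlusion — one markdown table each, methods as columns.
#' Empty strata print as `n/a`.
#'
#' @param records the data.frame from [run_comparison()].
#' @return a character vector of markdown lines (invisibly printed with
#'   `cat` if `print = TRUE`).
#' @param print print the tables to the console?
#' @export
format_comparison_tables <- function(records, print = FALSE) {
  methods <- unique(records$method)
  fmt_cell <- function(v) ifelse(is.na(v), "n/a", sprintf("%.2f%%", v))
  one_table <- function(title, by, metric) {
    s <- summarize_comparison(records, by = by)
    strata <- unique(s[[by]])
    lines <- c(paste0("**", title, "**"), "",
               paste0("| ", if (by == "illumination") "Light Conditions" else "Occlusion Conditions",
                      " | ", paste(methods, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(methods) + 1L), collapse = "|"), "|"))
    for (st in strata) {
      vals <- vapply(methods, function(m)
        fmt_cell(s[[metric]][s$method == m & s[[by]] == st]), character(1L))
      lines <- c(lines, paste0("| ", st, " | ", paste(vals, collapse = " | "), " |"))
    }
    c(lines, "")
  }
  out <- c(
    one_table("Average relative error in the area estimate, by illumination",
              "illumination", "area_rel_error_pct"),
    one_table("Average relative error in the area estimate, by occlusion",
              "occlusion_bin", "area_rel_error_pct"),
    one_table("Average noisy pixels, by illumination",
              "illumination", "noise_fraction_pct"),
    one_table("Average noisy pixels, by occlusion",
              "occlusion_bin", "noise_fraction_pct"))
  if (print) cat(out, sep = "\n")
  invisible(out)
}
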