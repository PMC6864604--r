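#' Pipeline configuration
#'
#' Collects every tunable parameter of the readout pipeline in one place so
#' that a report can be regenerated from its logged configuration.
#'
#' @param flipped control line taken from the lower band of the center cell
#'   instead of the upper one (strip framed the other way up).
#' @param otsu_levels class count for [otsu_threshold()] (default 2: a
#'   single mask threshold).
#' @param apply_full_image evaluate the mask over the whole image rather
#'   than only the control/test rectangles (diagnostic; the sums only ever
#'   read the two line regions).
#' @param reference_quantity_fg reference analyte mass defining x = 0 on the
#'   calibration axis, in femtograms (default 10 fg, the lowest assayed
#'   class, so the five classes map to x = 0..4).
#' @param svm_cost soft-margin penalty C for the linear SVM.
#' @param folds cross-validation fold count.
#' @param seed top-level RNG seed; all randomness (fold shuffling, synthetic
#'   noise) flows from it.
#' @param sample_volume_ul applied sample volume in microliters, used to
#'   convert analyte mass to concentration (default 10 uL).
#' @param molecular_weight analyte molecular weight in Da for molarity
#'   conversion (default 66500, human serum albumin).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(flipped = FALSE, otsu_levels = 2L,
                            apply_full_image = FALSE,
                            reference_quantity_fg = 10,
                            svm_cost = 1, folds = 5L, seed = 1L,
                            sample_volume_ul = 10,
                            molecular_weight = 66500) {
  stopifnot(otsu_levels >= 2L, reference_quantity_fg > 0,
            svm_cost > 0, folds >= 2L, sample_volume_ul > 0)
  structure(list(flipped = isTRUE(flipped),
                 otsu_levels = as.integer(otsu_levels),
                 apply_full_image = isTRUE(apply_full_image),
                 reference_quantity_fg = reference_quantity_fg,
                 svm_cost = svm_cost, folds = as.integer(folds),
                 seed = as.integer(seed),
                 sample_volume_ul = sample_volume_ul,
                 molecular_weight = molecular_weight),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   [write_pipeline_config()] returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Weighted red-intensity sum over a masked region
#'
#' The band signal is the sum of red-channel intensities over the pixels of
#' a region that the mask admits; each pixel is weighted by its own red
#' intensity, so the statistic grows with both band area and band depth.
#'
#' @param img an [rgb_image()].
#' @param mask an `lfa_mask` of the same dimensions (from [build_mask()]).
#' @param region the [rect()] to sum over.
#' @return Integer-valued sum of red intensities.
#' @export
weighted_sum <- function(img, mask, region) {
  stopifnot(inherits(img, "rgb_image"), inherits(mask, "lfa_mask"),
            inherits(region, "rect"))
  if (!identical(dim(mask$values), dim(img$red))) {
    stop("mask and image dimensions disagree", call. = FALSE)
  }
  rows <- rect_rows(region); cols <- rect_cols(region)
  sum(img$red[rows, cols][mask$values[rows, cols] == 1L])
}

#' Test-to-control signal ratio
#'
#' The T/C ratio divides the test-band red sum by the control-band red sum.
#' Because a global illumination change rescales both sums alike, the ratio
#' is the pipeline's lighting-robust quantification feature. A zero control
#' sum means the control line never developed, i.e. the assay did not run.
#'
#' @param s_test,s_control weighted red sums from [weighted_sum()].
#' @return `s_test / s_control` at full precision.
#' @export
tc_ratio <- function(s_test, s_control) {
  if (s_control <= 0) {
    stop(paste("invalid strip: control-line signal is zero, the assay did",
               "not run"), call. = FALSE)
  }
  s_test / s_control
}

#' Analyze one strip image
#'
#' Deterministic composition of the full readout: center grid cell ->
#' control/test rectangles -> red/green ratio image -> Otsu mask learned on
#' the control region -> weighted red sums -> T/C ratio.
#'
#' @param img an [rgb_image()] framed per the 3x3 grid convention.
#' @param config a [pipeline_config()].
#' @return An object of class `intensity_summary`: `s_control`, `s_test`,
#'   `tc_ratio`, `masked_pixels` (per-region counts), `th_mask`, and the
#'   `center`, `control`, `test` rectangles.
#' @export
analyze_strip <- function(img, config = pipeline_config()) {
  stopifnot(inherits(img, "rgb_image"), inherits(config, "pipeline_config"))
  cb <- center_box(img$width, img$height)
  regions <- line_regions(cb, flipped = config$flipped)
  r <- ratio_image(img)
  targets <- if (config$apply_full_image) {
    rect(0, 0, img$width, img$height)
  } else {
    list(regions$control, regions$test)
  }
  mask <- build_mask(r, regions$control, targets, levels = config$otsu_levels)
  s_control <- weighted_sum(img, mask, regions$control)
  s_test <- weighted_sum(img, mask, regions$test)
  count_in <- function(region) {
    sum(mask$values[rect_rows(region), rect_cols(region)])
  }
  structure(list(
    s_control = s_control,
    s_test = s_test,
    tc_ratio = tc_ratio(s_test, s_control),
    masked_pixels = c(control = count_in(regions$control),
                      test = count_in(regions$test)),
    th_mask = mask$threshold,
    center = cb, control = regions$control, test = regions$test
  ), class = "intensity_summary")
}

#' @export
print.intensity_summary <- function(x, ...) {
  cat(sprintf(
    "<intensity_summary> S_control = %d, S_test = %d, T/C = %.4f (TH_mask = %.4f)\n",
    x$s_control, x$s_test, x$tc_ratio, x$th_mask))
  cat(sprintf("  masked pixels: control %d, test %d\n",
              x$masked_pixels["control"], x$masked_pixels["test"]))
  invisible(x)
}
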