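#' Run the full readout-calibration-classification pipeline
#'
#' Orchestrates the end-to-end analysis: strip images (if given) are read
#' and reduced to T/C readings with [analyze_strip()]; the calibration line
#' is fitted on the readings; per-class statistics are computed; readings
#' are mapped to calibrated log-quantity features; and a stratified k-fold
#' cross-validated one-vs-one linear SVM produces a confusion matrix and
#' accuracy. Every stage's parameters are echoed in the report so a report
#' is fully regenerable from its configuration and seed.
#'
#' @param images optional data frame with columns `path` and `quantity_fg`
#'   describing labelled strip images to analyze.
#' @param readings optional readings data frame (as from
#'   [load_fixture_readings()] or [read_readings()]); image-derived readings
#'   are appended to it.
#' @param config a [pipeline_config()].
#' @return An object of class `lfa_report`: `readings`, `calibration`,
#'   `class_stats`, `features`, `confusion`, `accuracy`, `config`.
#' @export
run_end_to_end <- function(images = NULL, readings = NULL,
                           config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(images) && is.null(readings)) {
    stop("usage error: supply strip images and/or a readings table",
         call. = FALSE)
  }
  if (!is.null(images)) {
    stopifnot(is.data.frame(images),
              all(c("path", "quantity_fg") %in% names(images)))
    if (nrow(images) == 0L) {
      stop("usage error: empty image list", call. = FALSE)
    }
    img_readings <- do.call(rbind, lapply(seq_len(nrow(images)), function(i) {
      summ <- analyze_strip(read_image(images$path[i]), config)
      data.frame(set_id = "images", quantity_fg = images$quantity_fg[i],
                 reading_index = i, tc_ratio = summ$tc_ratio)
    }))
    keep <- c("set_id", "quantity_fg", "reading_index", "tc_ratio")
    readings <- rbind(if (!is.null(readings)) readings[, keep] else NULL,
                      img_readings)
  }
  readings <- check_readings(readings)
  model <- fit_calibration(readings,
                           reference_fg = config$reference_quantity_fg)
  stats <- class_stats(readings)
  features <- (readings$tc_ratio - model$intercept) / model$slope
  cm <- cross_validate(features, readings$quantity_fg,
                       k = config$folds, cost = config$svm_cost,
                       seed = config$seed)
  structure(list(readings = readings, calibration = model,
                 class_stats = stats, features = features,
                 confusion = cm, accuracy = accuracy(cm),
                 config = config),
            class = "lfa_report")
}

#' @export
print.lfa_report <- function(x, ...) {
  cat(sprintf("<lfa_report> %d readings, %d classes\n",
              nrow(x$readings), nrow(x$class_stats)))
  print(x$calibration)
  cat(sprintf("  cross-validated accuracy: %.1f%%\n", x$accuracy))
  invisible(x)
}

#' Serialize a report, calibration model or summary to JSON
#'
#' @param x an `lfa_report`, `lfa_calibration`, `intensity_summary` or any
#'   list-like result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  out <- report_payload(x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "lfa_report")) {
    list(
      calibration = report_payload(x$calibration),
      class_stats = x$class_stats,
      confusion = list(labels = rownames(x$confusion),
                       counts = unclass(x$confusion)),
      accuracy_pct = x$accuracy,
      config = unclass(x$config)
    )
  } else if (inherits(x, "lfa_calibration")) {
    list(slope = x$slope, intercept = x$intercept,
         reference_fg = x$reference_fg, sigma = x$sigma,
         r_squared = x$r_squared, lob = x$lob, lod = x$lod, loq = x$loq,
         n = x$n)
  } else if (inherits(x, "intensity_summary")) {
    list(s_control = x$s_control, s_test = x$s_test, tc_ratio = x$tc_ratio,
         th_mask = x$th_mask,
         masked_pixels = as.list(x$masked_pixels),
         center = unclass(x$center), control = unclass(x$control),
         test = unclass(x$test))
  } else if (inherits(x, "strip_ground_truth")) {
    list(control_rect = unclass(x$control_rect),
         test_rect = unclass(x$test_rect),
         spec = unclass(x$spec))
  } else {
    x
  }
}

#' Load a serialized calibration model
#'
#' Reads a JSON file written by [write_report_json()] for an
#' `lfa_calibration` (or the `calibration` field of a report).
#'
#' @param path JSON file.
#' @return An `lfa_calibration`.
#' @export
read_calibration_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(v$calibration)) v <- v$calibration
  calibration_model(slope = v$slope, intercept = v$intercept,
                    reference_fg = v$reference_fg,
                    sigma = if (is.null(v$sigma)) NA_real_ else v$sigma,
                    r_squared = if (is.null(v$r_squared)) NA_real_ else v$r_squared,
                    lob = if (is.null(v$lob)) 0 else v$lob)
}
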