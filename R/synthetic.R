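#' Specification of a synthetic LFA strip image
#'
#' Describes an idealised strip photograph with known ground truth: a bright
#' background, a control band and (optionally) a test band inside the center
#' grid cell, a global illumination factor, and additive pixel noise. Band
#' strength in \[0, 1\] controls how developed a band is, under one of two
#' forward models:
#'
#' * `"coverage"` (default): the band is painted at full band colour over a
#'   centred sub-stretch of the line whose length is `strength` times the
#'   line width. This emulates a line whose developed (conjugate-capturing)
#'   extent grows with analyte load, keeps the control region cleanly
#'   bimodal for Otsu thresholding, and makes the masked red sum -- hence
#'   T/C -- increase essentially linearly with strength.
#' * `"flat"`: the full band rectangle is painted by amplitude blending,
#'   `pixel = (1 - strength) * background + strength * band_colour`. Useful
#'   for closed-form checks (masked sum = pixel count x band red).
#'
#' `strength = 0` paints nothing in either model.
#'
#' @param width,height image size in pixels.
#' @param background background colour, length-3 (R, G, B) in \[0, 255\].
#' @param band_color band colour, length-3 (R, G, B) in \[0, 255\]; shared by
#'   both lines, as both develop the same gold-nanoparticle red.
#' @param control_strength,test_strength band strengths in \[0, 1\].
#' @param band_thickness band height as a fraction of the center-cell
#'   height; must fit inside one third of the cell.
#' @param profile `"coverage"` or `"flat"` (see above).
#' @param illumination global multiplicative factor k > 0 applied to all
#'   channels after painting (clipped at 255).
#' @param noise_sd standard deviation of additive per-pixel, per-channel
#'   Gaussian noise (default 2 intensity levels, a typical smartphone-sensor
#'   noise floor).
#' @param seed RNG seed for the noise; identical specs give byte-identical
#'   images.
#' @return An object of class `synthetic_strip_spec`.
#' @export
synthetic_strip_spec <- function(width = 600L, height = 600L,
                                 background = c(200, 200, 200),
                                 band_color = c(160, 130, 130),
                                 control_strength = 1, test_strength = 0.5,
                                 band_thickness = 0.18,
                                 profile = c("coverage", "flat"),
                                 illumination = 1, noise_sd = 2,
                                 seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(length(background) == 3, length(band_color) == 3,
            all(background >= 0 & background <= 255),
            all(band_color >= 0 & band_color <= 255))
  if (control_strength < 0 || control_strength > 1 ||
      test_strength < 0 || test_strength > 1) {
    stop("band strengths must lie in [0, 1]", call. = FALSE)
  }
  if (illumination <= 0) stop("illumination factor must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (band_thickness <= 0) stop("band_thickness must be > 0", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background, band_color = band_color,
                 control_strength = control_strength,
                 test_strength = test_strength,
                 band_thickness = band_thickness, profile = profile,
                 illumination = illumination,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_strip_spec")
}

#' Generate a synthetic strip image with ground truth
#'
#' Paints the control band (upper third of the center cell) and the test
#' band (middle third) according to the spec's profile and strengths, then
#' applies the illumination factor, adds seeded Gaussian noise, and
#' rounds/clips to 8-bit. Identical specs (including seed) give
#' byte-identical images.
#'
#' @param spec a [synthetic_strip_spec()].
#' @return A list with `image` (an [rgb_image()]) and `truth` (class
#'   `strip_ground_truth`): `control_rect` and `test_rect`, the painted
#'   extents (`NULL` for an unpainted band), and an echo of `spec`.
#' @export
generate_strip <- function(spec) {
  stopifnot(inherits(spec, "synthetic_strip_spec"))
  cb <- center_box(spec$width, spec$height)
  regions <- line_regions(cb, flipped = FALSE)

  thick <- round(spec$band_thickness * rect_height(cb))
  if (thick < 1L) stop("band thickness below one pixel", call. = FALSE)

  # painted extent of one band, or NULL when nothing is painted
  band_rect <- function(region, strength) {
    if (thick > rect_height(region)) {
      stop(sprintf(
        "geometry error: band thickness %d px exceeds line-region height %d px",
        thick, rect_height(region)), call. = FALSE)
    }
    if (strength == 0) return(NULL)
    pad <- (rect_height(region) - thick) %/% 2L
    if (spec$profile == "coverage") {
      cols <- round(strength * rect_width(region))
      if (cols < 1L) return(NULL)
      xpad <- (rect_width(region) - cols) %/% 2L
      rect(region$x0 + xpad, region$y0 + pad,
           region$x0 + xpad + cols, region$y0 + pad + thick)
    } else {
      rect(region$x0, region$y0 + pad, region$x1, region$y0 + pad + thick)
    }
  }
  control_rect <- band_rect(regions$control, spec$control_strength)
  test_rect <- band_rect(regions$test, spec$test_strength)

  planes <- lapply(spec$background, function(v) {
    matrix(v, spec$height, spec$width)
  })
  paint <- function(planes, band, strength) {
    if (is.null(band)) return(planes)
    amp <- if (spec$profile == "coverage") 1 else strength
    rows <- rect_rows(band); cols <- rect_cols(band)
    for (i in 1:3) {
      planes[[i]][rows, cols] <-
        (1 - amp) * planes[[i]][rows, cols] + amp * spec$band_color[i]
    }
    planes
  }
  planes <- paint(planes, control_rect, spec$control_strength)
  planes <- paint(planes, test_rect, spec$test_strength)

  planes <- lapply(planes, function(p) p * spec$illumination)
  if (spec$noise_sd > 0) {
    planes <- with_local_seed(spec$seed, {
      lapply(planes, function(p) {
        p + rnorm(length(p), sd = spec$noise_sd)
      })
    })
  }
  planes <- lapply(planes, function(p) {
    matrix(pmin(pmax(round(p), 0), 255), spec$height, spec$width)
  })

  img <- rgb_image(planes[[1]], planes[[2]], planes[[3]])
  truth <- structure(list(control_rect = control_rect, test_rect = test_rect,
                          spec = spec),
                     class = "strip_ground_truth")
  list(image = img, truth = truth)
}

# T/C ratio as a function of test-band strength for a given noiseless
# geometry; cached, since it is reused for every inversion.
tc_lookup <- function(spec, grid = seq(0, 1, by = 0.01)) {
  base <- spec
  base$test_strength <- 0
  base$noise_sd <- 0
  base$illumination <- 1
  key <- paste(
    c(base$width, base$height, base$background, base$band_color,
      base$control_strength, base$band_thickness, base$profile,
      format(grid[1]), format(grid[length(grid)]), length(grid)),
    collapse = "|")
  if (!is.null(.lfa_cache[[key]])) return(.lfa_cache[[key]])
  tc <- vapply(grid, function(s) {
    sp <- base
    sp$test_strength <- s
    analyze_strip(generate_strip(sp)$image)$tc_ratio
  }, numeric(1))
  out <- list(strength = grid, tc = tc)
  .lfa_cache[[key]] <- out
  out
}

#' Band strength reproducing a calibrated T/C value
#'
#' Inverts the calibration line: the target T/C for a given analyte mass is
#' `m * log10(quantity / reference) + b`, and the returned test-band
#' strength is the one whose noiseless default-geometry pipeline T/C best
#' matches that target, read off a lookup table built by running the
#' pipeline over a strength grid. With the default geometry the match is
#' within about +/- 0.05 of the target (column-rounding granularity).
#'
#' @param quantity_fg analyte mass in femtograms (> 0), vectorised.
#' @param model a calibration model (see [calibration_model()] or
#'   [fit_calibration()]) with slope >= 0; a zero slope maps every quantity
#'   to the intercept's strength.
#' @param spec geometry to calibrate against (test strength, illumination
#'   and noise are overridden); default [synthetic_strip_spec()].
#' @return Test-band strength(s) in \[0, 1\].
#' @export
strength_for_quantity <- function(quantity_fg, model,
                                  spec = synthetic_strip_spec()) {
  stopifnot(inherits(model, "lfa_calibration"))
  if (any(quantity_fg <= 0)) stop("quantity must be > 0", call. = FALSE)
  if (model$slope < 0) stop("model slope must be >= 0", call. = FALSE)
  target <- if (model$slope == 0) {
    rep(model$intercept, length(quantity_fg))
  } else {
    model$slope * log10(quantity_fg / model$reference_fg) + model$intercept
  }
  lut <- tc_lookup(spec)
  if (any(target < 0) || any(target > max(lut$tc))) {
    stop(sprintf(
      "target T/C outside achievable range [0, %.3f] for this geometry",
      max(lut$tc)), call. = FALSE)
  }
  # invert the (non-decreasing) lookup; keep the smallest strength per T/C
  keep <- !duplicated(lut$tc)
  approx(lut$tc[keep], lut$strength[keep], xout = target,
         ties = "ordered", rule = 2)$y
}

#' Simulate a set of strips for known quantities
#'
#' Convenience wrapper producing one synthetic reading set: for each
#' quantity and replicate, a strip whose test-band strength is chosen by
#' [strength_for_quantity()] and whose illumination is drawn from
#' `illumination_range`, analyzed back into a T/C reading.
#'
#' @param quantities_fg vector of analyte masses in fg.
#' @param n_replicates strips per quantity.
#' @param model calibration model mapping quantity to target T/C.
#' @param spec base [synthetic_strip_spec()]; per-strip strength, seed and
#'   illumination are filled in.
#' @param seed top-level seed for illumination draws and per-strip noise.
#' @param illumination_range length-2 range of illumination factors.
#' @return A data frame of readings: `set_id`, `quantity_fg`,
#'   `reading_index`, `tc_ratio`, plus the realised `strength` and
#'   `illumination`.
#' @export
simulate_strip_set <- function(quantities_fg, n_replicates = 5L, model,
                               spec = synthetic_strip_spec(), seed = 1L,
                               illumination_range = c(0.85, 1)) {
  stopifnot(n_replicates >= 1L, length(illumination_range) == 2L)
  strengths <- strength_for_quantity(quantities_fg, model, spec)
  ks <- with_local_seed(seed, {
    matrix(runif(length(quantities_fg) * n_replicates,
                 illumination_range[1], illumination_range[2]),
           nrow = length(quantities_fg))
  })
  rows <- list()
  for (i in seq_along(quantities_fg)) {
    for (j in seq_len(n_replicates)) {
      sp <- spec
      sp$test_strength <- strengths[i]
      sp$illumination <- ks[i, j]
      sp$seed <- as.integer((seed * 1009L + i * 101L + j) %% .Machine$integer.max)
      summ <- analyze_strip(generate_strip(sp)$image)
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = "synthetic", quantity_fg = quantities_fg[i],
        reading_index = j, tc_ratio = summ$tc_ratio,
        strength = strengths[i], illumination = ks[i, j])
    }
  }
  do.call(rbind, rows)
}
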