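#' Red/green channel-ratio image
#'
#' On an LFA photograph the red-to-green intensity ratio is close to one
#' everywhere except over the reddish test and control bands, which makes it
#' a lighting-robust segmentation feature: a global change in illumination
#' scales both channels and cancels in the ratio. Pixels with zero green are
#' flagged invalid rather than clamped, so infinite ratios never enter the
#' threshold histogram or the mask.
#'
#' @param img an [rgb_image()].
#' @return An object of class `ratio_image` with fields `ratio` (numeric
#'   matrix, `NA` where invalid) and `valid` (logical matrix).
#' @export
ratio_image <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  valid <- img$green > 0L
  r <- matrix(NA_real_, img$height, img$width)
  r[valid] <- img$red[valid] / img$green[valid]
  structure(list(ratio = r, valid = valid,
                 width = img$width, height = img$height),
            class = "ratio_image")
}

#' Otsu threshold(s) on a set of ratio values
#'
#' Generalisation of Otsu's method to non-integer data: the values are
#' binned into a uniform histogram spanning their observed range, and the
#' cut point(s) minimising the total (weight-summed) intra-class variance
#' are found by exhaustive search over bin boundaries. With `levels = 2`
#' (the pipeline default, since the mask rule uses a single threshold) this
#' is classical bilevel Otsu; higher level counts return `levels - 1`
#' ascending thresholds. Ties are broken toward the smallest threshold(s).
#'
#' @param values numeric vector with at least two distinct finite values.
#' @param levels number of classes (>= 2); `levels - 1` thresholds returned.
#' @param bins histogram resolution (default 256, mirroring 8-bit practice).
#' @return Numeric vector of `levels - 1` ascending threshold values, each
#'   the upper edge of the last bin of its class.
#' @export
otsu_threshold <- function(values, levels = 2L, bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || levels < 2L) {
    stop("need at least two values and levels >= 2", call. = FALSE)
  }
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    stop("degenerate input: all values identical, no threshold exists",
         call. = FALSE)
  }
  idx <- pmin(floor((values - lo) / (hi - lo) * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  mids <- lo + (seq_len(bins) - 0.5) * (hi - lo) / bins
  edge <- function(cut) lo + cut * (hi - lo) / bins

  if (levels == 2L) {
    # vectorised over all cuts: intra-class variance of {bins <= t} and rest
    w <- cumsum(counts)
    s1 <- cumsum(counts * mids)
    s2 <- cumsum(counts * mids^2)
    n <- w[bins]; S1 <- s1[bins]; S2 <- s2[bins]
    cuts <- seq_len(bins - 1L)
    wL <- w[cuts]; wR <- n - wL
    varL <- ifelse(wL > 0, s2[cuts] - s1[cuts]^2 / wL, 0)
    varR <- ifelse(wR > 0, (S2 - s2[cuts]) - (S1 - s1[cuts])^2 / wR, 0)
    intra <- varL + varR
    ok <- wL > 0 & wR > 0
    intra[!ok] <- Inf
    return(edge(cuts[which.min(intra)]))
  }

  if (levels > 3L) {
    stop("exhaustive multilevel search supports at most 3 levels",
         call. = FALSE)
  }
  w <- c(0, cumsum(counts))
  s1 <- c(0, cumsum(counts * mids))
  s2 <- c(0, cumsum(counts * mids^2))
  class_ss <- function(a, b) {     # bins a..b (1-based, inclusive)
    n <- w[b + 1L] - w[a]
    if (n == 0) return(NA_real_)
    m1 <- s1[b + 1L] - s1[a]
    (s2[b + 1L] - s2[a]) - m1^2 / n
  }
  combos <- combn(bins - 1L, levels - 1L)
  best <- Inf; best_cuts <- NULL
  for (j in seq_len(ncol(combos))) {
    cuts <- combos[, j]
    bounds <- c(0L, cuts, bins)
    tot <- 0
    ok <- TRUE
    for (k in seq_len(levels)) {
      ss <- class_ss(bounds[k] + 1L, bounds[k + 1L])
      if (is.na(ss)) { ok <- FALSE; break }
      tot <- tot + ss
    }
    if (ok && tot < best) { best <- tot; best_cuts <- cuts }
  }
  if (is.null(best_cuts)) {
    stop("degenerate input: cannot form the requested number of classes",
         call. = FALSE)
  }
  edge(best_cuts)
}

#' Build the binary band mask
#'
#' The threshold is learned on the control-line region -- the one band
#' guaranteed to be present on a valid strip -- by Otsu's method on its
#' ratio values, and then applied over the requested rectangles: a pixel
#' enters the mask iff it is valid and its red/green ratio is strictly
#' greater than the threshold. Invalid pixels are always 0.
#'
#' @param r a [ratio_image()].
#' @param region_for_threshold [rect()] whose ratios define the threshold
#'   (normally the control-line region).
#' @param apply_to a [rect()] or list of [rect()]s over which the mask is
#'   evaluated; pass the full-image rect to mask everywhere.
#' @param levels passed to [otsu_threshold()]; the top threshold is used.
#' @return An object of class `lfa_mask`: `values` (integer 0/1 matrix of
#'   the full image size) and `threshold`.
#' @export
build_mask <- function(r, region_for_threshold, apply_to, levels = 2L) {
  stopifnot(inherits(r, "ratio_image"), inherits(region_for_threshold, "rect"))
  if (inherits(apply_to, "rect")) apply_to <- list(apply_to)
  sub <- r$ratio[rect_rows(region_for_threshold),
                 rect_cols(region_for_threshold)]
  vals <- sub[is.finite(sub)]
  if (length(unique(vals)) < 2L) {
    stop(paste("degenerate input: thresholding region has fewer than two",
               "distinct valid ratio values"), call. = FALSE)
  }
  th <- otsu_threshold(vals, levels = levels)
  th <- th[length(th)]
  m <- matrix(0L, r$height, r$width)
  for (rc in apply_to) {
    rows <- rect_rows(rc); cols <- rect_cols(rc)
    block <- r$ratio[rows, cols, drop = FALSE]
    m[rows, cols] <- as.integer(!is.na(block) & block > th)
  }
  structure(list(values = m, threshold = th), class = "lfa_mask")
}

#' Export a mask as a black-and-white PNG
#'
#' Mask value 1 maps to white (255), 0 to black, for visual inspection of
#' the segmentation.
#'
#' @param mask an `lfa_mask` from [build_mask()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "lfa_mask"))
  png::writePNG(mask$values * 1.0, path)
  invisible(path)
}
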