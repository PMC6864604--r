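#' Pixel rectangle
#'
#' Rectangles use the package-wide coordinate convention: x = column,
#' y = row, 0-based, origin at the top-left corner, half-open on both axes
#' (`[x0, x1) x [y0, y1)`).
#'
#' @param x0,y0,x1,y1 integer pixel coordinates with `x0 < x1`, `y0 < y1`.
#' @return An object of class `rect`.
#' @export
rect <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(v != round(v))) stop("rect coordinates must be integers", call. = FALSE)
  if (x0 >= x1 || y0 >= y1) {
    stop("rect must satisfy x0 < x1 and y0 < y1", call. = FALSE)
  }
  structure(as.list(as.integer(v)), names = names(v), class = "rect")
}

#' @export
print.rect <- function(x, ...) {
  cat(sprintf("<rect> [%d, %d) x [%d, %d)  (%d x %d px)\n",
              x$x0, x$x1, x$y0, x$y1, rect_width(x), rect_height(x)))
  invisible(x)
}

rect_width <- function(r) r$x1 - r$x0
rect_height <- function(r) r$y1 - r$y0

# 1-based matrix index ranges for a 0-based half-open rect
rect_rows <- function(r) (r$y0 + 1L):r$y1
rect_cols <- function(r) (r$x0 + 1L):r$x1

#' Center cell of the 3x3 framing grid
#'
#' The acquisition protocol frames the strip so that the test/control region
#' sits exactly in the center box of the camera's 3x3 grid; the region of
#' interest is therefore the middle ninth of the image, computed with floor
#' division (remainder rows/columns fall outside the lower/upper cut).
#'
#' @param width,height image dimensions in pixels (both at least 3).
#' @return A [rect()] covering `[floor(w/3), floor(2w/3)) x
#'   [floor(h/3), floor(2h/3))`.
#' @export
center_box <- function(width, height) {
  if (width < 3 || height < 3) {
    stop("image must be at least 3 x 3 pixels to have a center grid cell",
         call. = FALSE)
  }
  rect(floor(width / 3), floor(height / 3),
       floor(2 * width / 3), floor(2 * height / 3))
}

#' Control- and test-line rectangles within the center cell
#'
#' The center cell is split into three equal horizontal bands on an inner
#' 0..3 y-lattice spanning the full cell width. The test line occupies the
#' middle band; the control line occupies the band above it by default
#' (`flipped = TRUE` places it below instead, for strips framed the other
#' way up). Floor splits assign remainder rows to the last band.
#'
#' @param center the center-cell [rect()], at least 3 pixels tall.
#' @param flipped if `TRUE`, the control line is taken from the lower band.
#' @return A list of class `region_pair` with [rect()]s `control` and `test`.
#' @export
line_regions <- function(center, flipped = FALSE) {
  stopifnot(inherits(center, "rect"))
  h <- rect_height(center)
  if (h < 3) stop("center box must be at least 3 pixels tall", call. = FALSE)
  ys <- center$y0 + floor(h * 0:3 / 3)
  test <- rect(center$x0, ys[2], center$x1, ys[3])
  control <- if (flipped) {
    rect(center$x0, ys[3], center$x1, ys[4])
  } else {
    rect(center$x0, ys[1], center$x1, ys[2])
  }
  structure(list(control = control, test = test), class = "region_pair")
}
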