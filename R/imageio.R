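#' 8-bit ARGB raster image
#'
#' Container for the four channel planes of a strip photograph. Each plane is
#' an integer-valued matrix (rows = y, columns = x) with intensities in
#' \[0, 255\]. The red and green planes carry all the signal the pipeline
#' uses; alpha is kept so that packed 32-bit pixels round-trip losslessly.
#'
#' @param red,green,blue numeric matrices of identical dimension, integer
#'   values in \[0, 255\].
#' @param alpha optional alpha plane; defaults to fully opaque (255).
#' @return An object of class `rgb_image` with fields `alpha`, `red`,
#'   `green`, `blue`, `width`, `height`.
#' @export
rgb_image <- function(red, green, blue, alpha = NULL) {
  red <- check_plane(red, "red")
  green <- check_plane(green, "green")
  blue <- check_plane(blue, "blue")
  if (is.null(alpha)) {
    alpha <- matrix(255L, nrow(red), ncol(red))
  } else {
    alpha <- check_plane(alpha, "alpha")
  }
  dims <- lapply(list(alpha, red, green, blue), dim)
  if (length(unique(dims)) != 1L) {
    stop("all channel planes must share the same dimensions", call. = FALSE)
  }
  structure(
    list(alpha = alpha, red = red, green = green, blue = blue,
         width = ncol(red), height = nrow(red)),
    class = "rgb_image"
  )
}

check_plane <- function(m, name) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("'%s' plane must be a numeric matrix", name), call. = FALSE)
  }
  if (anyNA(m) || any(m < 0) || any(m > 255) || any(m != round(m))) {
    stop(sprintf("'%s' plane must hold integers in [0, 255]", name),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d pixels (width x height), 8-bit ARGB\n",
              x$width, x$height))
  invisible(x)
}

#' Read a strip photograph
#'
#' Decodes an 8-bit PNG, TIFF or JPEG file into an [rgb_image()]. Images
#' without an alpha channel get an opaque alpha plane. Bit depths other than
#' 8 bits per channel are rejected rather than rescaled so that weighted
#' red-intensity sums stay comparable across images.
#'
#' @param path path to a PNG, TIFF or JPEG file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: '%s' does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    hdr <- readBin(path, "raw", n = 25L)
    if (length(hdr) >= 25L && as.integer(hdr[25L]) != 8L) {
      stop(sprintf("unsupported format: PNG bit depth %d (only 8 supported)",
                   as.integer(hdr[25L])), call. = FALSE)
    }
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- suppressWarnings(tiff::readTIFF(path, info = TRUE))
    bits <- attr(arr, "bits.per.sample")
    if (!is.null(bits) && any(bits != 8L)) {
      stop(sprintf("unsupported format: TIFF bit depth %s (only 8 supported)",
                   paste(bits, collapse = "/")), call. = FALSE)
    }
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    }
    eb <- EBImage::readImage(path)
    arr <- aperm(EBImage::imageData(eb), c(2, 1, 3)[seq_along(dim(eb))])
  } else {
    stop(sprintf("unsupported image extension '%s'", ext), call. = FALSE)
  }
  array_to_image(arr)
}

array_to_image <- function(arr) {
  if (is.matrix(arr)) {           # greyscale
    g <- round_plane(arr)
    return(rgb_image(g, g, g))
  }
  nch <- dim(arr)[3]
  planes <- lapply(seq_len(nch), function(i) round_plane(arr[, , i]))
  if (nch == 1L) {
    rgb_image(planes[[1]], planes[[1]], planes[[1]])
  } else if (nch == 2L) {         # grey + alpha
    rgb_image(planes[[1]], planes[[1]], planes[[1]], alpha = planes[[2]])
  } else if (nch == 3L) {
    rgb_image(planes[[1]], planes[[2]], planes[[3]])
  } else {
    rgb_image(planes[[1]], planes[[2]], planes[[3]], alpha = planes[[4]])
  }
}

round_plane <- function(m) {
  out <- round(m * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an image to PNG or TIFF
#'
#' Both formats are lossless for 8-bit data, so
#' `read_image(write_image(img, path))` reproduces `img` exactly.
#'
#' @param img an [rgb_image()].
#' @param path destination path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  arr <- array(0, dim = c(img$height, img$width, 4L))
  arr[, , 1] <- img$red / 255
  arr[, , 2] <- img$green / 255
  arr[, , 3] <- img$blue / 255
  arr[, , 4] <- img$alpha / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    stop(sprintf("unsupported output extension '%s' (use png or tiff)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Unpack a 32-bit ARGB pixel
#'
#' A camera pixel is one unsigned 32-bit word: bits 31-24 alpha, 23-16 red,
#' 15-8 green, 7-0 blue. Values are handled as doubles because R integers
#' are signed 32-bit.
#'
#' @param value unsigned 32-bit pixel value(s), in \[0, 2^32).
#' @return A named list with numeric vectors `alpha`, `red`, `green`, `blue`.
#' @export
unpack_argb <- function(value) {
  if (any(value < 0) || any(value >= 2^32) || any(value != round(value))) {
    stop("pixel values must be integers in [0, 2^32)", call. = FALSE)
  }
  list(
    alpha = value %/% 2^24 %% 256,
    red   = value %/% 2^16 %% 256,
    green = value %/% 2^8 %% 256,
    blue  = value %% 256
  )
}

#' Pack channel intensities into a 32-bit ARGB pixel
#'
#' Inverse of [unpack_argb()].
#'
#' @param alpha,red,green,blue intensities in \[0, 255\].
#' @return Numeric vector of packed pixel values.
#' @export
pack_argb <- function(alpha, red, green, blue) {
  ch <- cbind(alpha, red, green, blue)
  if (any(ch < 0) || any(ch > 255) || any(ch != round(ch))) {
    stop("channel intensities must be integers in [0, 255]", call. = FALSE)
  }
  alpha * 2^24 + red * 2^16 + green * 2^8 + blue
}
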