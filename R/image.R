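#' Ultrasound image container
#'
#' An `us_image` is an integer matrix of 8-bit gray levels (rows = image rows,
#' columns = image columns) with an optional physical pixel spacing in mm.
#' All feature extraction in this package operates on this container.
#'
#' @param pixels integer or numeric matrix with values in \[0, 255\].
#' @param pixel_spacing_mm optional positive numeric of length 1 (isotropic)
#'   or 2 (`c(row, col)` spacing). When present, geometric outputs are in mm.
#' @return An object of class `us_image`: an integer matrix with a
#'   `pixel_spacing_mm` attribute.
#' @examples
#' img <- us_image(matrix(0:255, 16, 16))
#' dim(img)
#' @export
us_image <- function(pixels, pixel_spacing_mm = NULL) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2x2")
  if (anyNA(pixels)) stop("image contains missing values")
  if (any(pixels < 0 | pixels > 255))
    stop("pixel values must lie in [0, 255]")
  if (any(pixels != round(pixels)))
    stop("pixel values must be integers (8-bit gray levels)")
  storage.mode(pixels) <- "integer"
  if (!is.null(pixel_spacing_mm)) {
    if (!is.numeric(pixel_spacing_mm) ||
        !length(pixel_spacing_mm) %in% c(1L, 2L) ||
        any(pixel_spacing_mm <= 0))
      stop("`pixel_spacing_mm` must be 1 or 2 positive numbers")
    if (length(pixel_spacing_mm) == 1L)
      pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  }
  structure(pixels, pixel_spacing_mm = pixel_spacing_mm,
            class = c("us_image", class(pixels)))
}

#' @export
print.us_image <- function(x, ...) {
  sp <- attr(x, "pixel_spacing_mm")
  cat(sprintf("<us_image> %d x %d, range [%d, %d]%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (is.null(sp)) "" else
                sprintf(", spacing %.4g x %.4g mm", sp[1], sp[2])))
  invisible(x)
}

# BT.601 luma weights, fixed so multi-channel fixtures are deterministic
.LUMA <- c(0.299, 0.587, 0.114)

#' Read a B-mode ultrasound image from a PNG file
#'
#' Reads an 8-bit PNG and returns a grayscale [us_image()]. Multi-channel
#' images are converted with fixed BT.601 luma weights (0.299 R + 0.587 G +
#' 0.114 B); an alpha channel, if any, is ignored. The conversion is
#' deterministic, but single-channel grayscale PNG is the documented contract.
#'
#' @param path path to a PNG file.
#' @param pixel_spacing_mm optional pixel spacing forwarded to [us_image()].
#' @return An [us_image()].
#' @export
read_image <- function(path, pixel_spacing_mm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- png::readPNG(path)
  if (length(a) == 0L) stop("zero-size image: ", path)
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    a <- if (nch >= 3L) {
      .LUMA[1] * a[, , 1] + .LUMA[2] * a[, , 2] + .LUMA[3] * a[, , 3]
    } else {
      a[, , 1]  # gray + alpha
    }
  }
  us_image(round(a * 255), pixel_spacing_mm = pixel_spacing_mm)
}

#' Write an ultrasound image to an 8-bit grayscale PNG
#'
#' @param img an [us_image()] or integer matrix in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (!inherits(img, "us_image")) img <- us_image(img)
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

# Extract the pixels of a rectangular ROI (half-open convention).
# Returns a plain integer matrix of size height x width.
roi_pixels <- function(img, rect) {
  stopifnot(inherits(rect, "rect_roi"))
  m <- unclass(img)
  m[(rect$y0 + 1L):(rect$y0 + rect$height),
    (rect$x0 + 1L):(rect$x0 + rect$width), drop = FALSE]
}
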