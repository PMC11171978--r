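#' Regions of interest
#'
#' Feature extraction uses five named regions per image: four rectangles
#' (`quality`, `upper_edge`, `lower_edge`, `bone`) and one polygon
#' (`morphology`) outlining the tendon body. Coordinates are 0-based with
#' x = column and y = row; rectangles are half-open,
#' `[x0, x0 + width) x [y0, y0 + height)`, so a w x h rectangle covers
#' exactly `w * h` pixels.
#'
#' @param x0,y0 integer top-left corner (0-based).
#' @param width,height positive integers, both at least 4 (texture matrices
#'   need pixel pairs in every direction).
#' @param name one of `"quality"`, `"upper_edge"`, `"lower_edge"`, `"bone"`.
#' @return `rect_roi()` returns a `rect_roi` object; `poly_roi()` a
#'   `poly_roi`; `roi_set()` a `roi_set`.
#' @name rois
NULL

RECT_NAMES <- c("quality", "upper_edge", "lower_edge", "bone")

#' @rdname rois
#' @export
rect_roi <- function(x0, y0, width, height, name) {
  name <- match.arg(name, RECT_NAMES)
  v <- c(x0 = x0, y0 = y0, width = width, height = height)
  if (any(v != round(v))) stop("rectangle coordinates must be integers")
  if (x0 < 0 || y0 < 0) stop("rectangle corner must be non-negative")
  if (width < 4 || height < 4)
    stop("rectangle must be at least 4x4 (got ", width, "x", height, ")")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height),
                 name = name),
            class = "rect_roi")
}

#' @rdname rois
#' @param vertices numeric matrix with columns (x, y): at least 4 vertices of
#'   a simple (non-self-intersecting) closed polygon, in drawing order; the
#'   closing edge from last back to first vertex is implicit.
#' @export
poly_roi <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("`vertices` must be an n x 2 matrix (x, y)")
  if (nrow(vertices) < 4L) stop("polygon needs at least 4 vertices")
  if (anyNA(vertices)) stop("polygon vertices contain missing values")
  if (!polygon_is_simple(vertices)) stop("polygon is self-intersecting")
  if (abs(shoelace_area(vertices)) <= 0) stop("polygon has zero area")
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(vertices = vertices, name = "morphology"),
            class = "poly_roi")
}

#' @rdname rois
#' @param rects named list of `rect_roi` objects (names must match their
#'   `name` fields).
#' @param poly optional `poly_roi`.
#' @param image_id identifier linking the set to an image.
#' @export
roi_set <- function(rects = list(), poly = NULL, image_id = "image") {
  stopifnot(is.list(rects))
  nm <- vapply(rects, function(r) r$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate ROI names")
  names(rects) <- nm
  if (!is.null(poly)) stopifnot(inherits(poly, "poly_roi"))
  structure(list(image_id = image_id, rects = rects, poly = poly),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> image '%s': %d rectangle(s) [%s]%s\n",
              x$image_id, length(x$rects),
              paste(names(x$rects), collapse = ", "),
              if (is.null(x$poly)) "" else " + morphology polygon"))
  invisible(x)
}

# Signed polygon area by the shoelace formula (positive if counter-clockwise
# in a y-down raster frame is irrelevant; callers take abs()).
shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Proper-crossing test for two closed segments p1-p2 and p3-p4, excluding
# shared endpoints (adjacent polygon edges always share one).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    d(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  ident <- function(a, b) all(a == b)
  # collinear overlap / touching interior counts as non-simple unless it is
  # exactly a shared endpoint
  for (p in list(p3, p4)) {
    if (on_seg(p1, p2, p) && !ident(p, p1) && !ident(p, p2)) return(TRUE)
  }
  for (p in list(p1, p2)) {
    if (on_seg(p3, p4, p) && !ident(p, p3) && !ident(p, p4)) return(TRUE)
  }
  FALSE
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    a1 <- v[i, ]; a2 <- v[i %% n + 1L, ]
    for (j in seq_len(n)) {
      if (j <= i) next
      adjacent <- (j == i %% n + 1L) || (i == j %% n + 1L)
      if (adjacent) next
      b1 <- v[j, ]; b2 <- v[j %% n + 1L, ]
      if (segments_cross(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

#' Read a region-of-interest set from JSON
#'
#' The JSON object maps ROI names to geometry: rectangles as
#' `[x0, y0, width, height]` (0-based, half-open) under the keys `quality`,
#' `upper_edge`, `lower_edge`, `bone`, and the tendon outline as an n x 2
#' vertex array under `morphology`. ROIs are validated against the image:
#' out-of-bounds rectangles, degenerate polygons and unknown names are
#' rejected, never repaired.
#'
#' @param path path to the JSON file.
#' @param img the [us_image()] the ROIs refer to (for bounds checking).
#' @param image_id identifier stored in the returned set.
#' @return A [roi_set()].
#' @export
read_roiset <- function(path, img, image_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  roiset_from_list(spec, img, image_id = image_id)
}

#' @rdname read_roiset
#' @param spec a named list as produced by parsing the JSON described above.
#' @export
roiset_from_list <- function(spec, img, image_id = "image") {
  if (is.null(names(spec)) || any(names(spec) == ""))
    stop("ROI entries must be named")
  unknown <- setdiff(names(spec), c(RECT_NAMES, "morphology"))
  if (length(unknown))
    stop("unknown ROI name(s): ", paste(unknown, collapse = ", "))
  rects <- list()
  poly <- NULL
  for (nm in names(spec)) {
    g <- spec[[nm]]
    if (nm == "morphology") {
      poly <- poly_roi(g)
      if (any(poly$vertices[, 1] < 0) || any(poly$vertices[, 2] < 0) ||
          any(poly$vertices[, 1] > ncol(img)) ||
          any(poly$vertices[, 2] > nrow(img)))
        stop("morphology polygon escapes image bounds")
    } else {
      if (length(g) != 4L) stop("rectangle '", nm, "' must be [x0,y0,w,h]")
      r <- rect_roi(g[1], g[2], g[3], g[4], name = nm)
      if (r$x0 + r$width > ncol(img) || r$y0 + r$height > nrow(img))
        stop("rectangle '", nm, "' exceeds image bounds (",
             nrow(img), "x", ncol(img), ")")
      rects[[nm]] <- r
    }
  }
  roi_set(rects = rects, poly = poly, image_id = image_id)
}

#' Write a region-of-interest set to JSON
#'
#' Inverse of [read_roiset()].
#'
#' @param rois a [roi_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roiset <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  out <- lapply(rois$rects, function(r) c(r$x0, r$y0, r$width, r$height))
  if (!is.null(rois$poly)) out$morphology <- unname(rois$poly$vertices)
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
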