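#' Split a tendon outline into upper and lower border chains
#'
#' The morphology polygon outlines the tendon body in a longitudinal view:
#' two roughly horizontal borders joined at the ends. The vertex cycle is cut
#' at the leftmost and the rightmost vertex (ties broken by smaller y) into
#' two open chains; the chain with the smaller mean y is the upper border.
#' Each chain must be x-monotone — a chain that doubles back in x has no
#' single-valued border function and is rejected.
#'
#' @param poly a [poly_roi()].
#' @return List with `upper` and `lower`, each an n x 2 matrix of (x, y)
#'   vertices ordered by increasing x.
#' @export
split_chains <- function(poly) {
  stopifnot(inherits(poly, "poly_roi"))
  v <- poly$vertices
  n <- nrow(v)
  if (diff(range(v[, 1])) < 2)
    stop("polygon x-extent must be at least 2 pixels")
  i_left <- order(v[, 1], v[, 2])[1]
  i_right <- order(-v[, 1], v[, 2])[1]     # ties: smaller y on both ends
  idx_fwd <- function(a, b) {        # walk a -> b in vertex-cycle order
    if (a <= b) a:b else c(a:n, 1:b)
  }
  c1 <- v[idx_fwd(i_left, i_right), , drop = FALSE]
  c2 <- v[rev(idx_fwd(i_right, i_left)), , drop = FALSE]
  # vertical cap edges at the left/right ends belong to neither border:
  # shed them so e.g. a rectangle splits into its two horizontal edges
  trim_caps <- function(ch) {
    while (nrow(ch) > 2L && ch[1, 1] == ch[2, 1]) ch <- ch[-1, , drop = FALSE]
    n <- nrow(ch)
    while (n > 2L && ch[n, 1] == ch[n - 1L, 1]) {
      ch <- ch[-n, , drop = FALSE]; n <- nrow(ch)
    }
    ch
  }
  c1 <- trim_caps(c1); c2 <- trim_caps(c2)
  for (ch in list(c1, c2)) {
    if (nrow(ch) < 2L) stop("degenerate border chain")
    if (any(diff(ch[, 1]) < 0)) stop("border chain doubles back in x")
    if (any(diff(ch[, 1]) == 0)) stop("border chain has a vertical interior segment")
  }
  if (mean(c1[, 2]) <= mean(c2[, 2])) list(upper = c1, lower = c2)
  else list(upper = c2, lower = c1)
}

#' Tendon width profile
#'
#' Samples the vertical distance between the two border chains at
#' `n_stations` equally spaced x positions across their common x-range,
#' linearly interpolating each chain. Widths are in pixels, or in mm when
#' the image's column pixel spacing is supplied.
#'
#' @param chains result of [split_chains()].
#' @param n_stations number of sampling stations, at least 2; default 100
#'   bounds the discretization error of the summary statistics below 1\% for
#'   smooth borders.
#' @param spacing_mm optional `c(row, col)` pixel spacing; widths (vertical
#'   distances) scale by the row spacing.
#' @return List with `stations` (x positions) and `widths`.
#' @export
width_profile <- function(chains, n_stations = 100L, spacing_mm = NULL) {
  if (n_stations < 2L) stop("`n_stations` must be at least 2")
  up <- chains$upper; lo <- chains$lower
  x0 <- max(min(up[, 1]), min(lo[, 1]))
  x1 <- min(max(up[, 1]), max(lo[, 1]))
  if (x1 <= x0) stop("chains share no x-range")
  xs <- seq(x0, x1, length.out = n_stations)
  yu <- stats::approx(up[, 1], up[, 2], xout = xs, ties = mean)$y
  yl <- stats::approx(lo[, 1], lo[, 2], xout = xs, ties = mean)$y
  w <- abs(yl - yu)
  if (!is.null(spacing_mm)) w <- w * spacing_mm[1]
  list(stations = xs, widths = w)
}

#' Convex hull area of a point set
#'
#' @param pts n x 2 matrix.
#' @return Area of the convex hull (shoelace formula on the hull vertices).
#' @keywords internal
convex_hull_area <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) return(0)
  abs(shoelace_area(pts[h, , drop = FALSE]))
}

MORPH_FEATURE_NAMES <- c("morph_max_width", "morph_min_width",
                         "morph_mean_width", "morph_parallelism_sd",
                         "morph_width_ratio")

#' The 5-variable tendon morphology descriptor
#'
#' From the width profile of the polygonal tendon outline: maximum, minimum
#' and mean width, parallelism (the population standard deviation of the
#' widths — 0 for perfectly parallel borders), and the max/min width ratio.
#' The auxiliary convexity (polygon area over convex-hull area, 1 for a
#' convex outline) is returned separately from the canonical five.
#'
#' @param poly a [poly_roi()].
#' @param n_stations sampling stations for the width profile.
#' @param spacing_mm optional pixel spacing `c(row, col)`; widths in mm.
#' @return List with `features` (named numeric of the 5 canonical
#'   variables; `morph_width_ratio` is `NA` flagged undefined if the minimum
#'   width is 0), `convexity` (auxiliary), and `profile`.
#' @export
morphology_features <- function(poly, n_stations = 100L, spacing_mm = NULL) {
  chains <- split_chains(poly)
  prof <- width_profile(chains, n_stations = n_stations,
                        spacing_mm = spacing_mm)
  w <- prof$widths
  ratio <- if (min(w) <= 0) NA_real_ else max(w) / min(w)
  area <- abs(shoelace_area(poly$vertices))
  hull <- convex_hull_area(poly$vertices)
  list(features = c(morph_max_width = max(w),
                    morph_min_width = min(w),
                    morph_mean_width = mean(w),
                    morph_parallelism_sd = sqrt(mean((w - mean(w))^2)),
                    morph_width_ratio = ratio),
       convexity = area / hull,
       profile = prof)
}
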