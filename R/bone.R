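#' Otsu threshold of an 8-bit region
#'
#' Exhaustive search over the 256-bin histogram for the threshold t that
#' maximizes the between-class variance of the split `{v < t}` vs
#' `{v >= t}`. Returns `NA` (degenerate) when the region holds a single
#' gray level.
#'
#' @param region integer matrix of 8-bit values.
#' @return Integer threshold in `1..255`, or `NA_integer_` if degenerate.
#' @export
otsu_threshold <- function(region) {
  v <- as.vector(unclass(region))
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  if (sum(h > 0) < 2L) return(NA_integer_)
  lev <- 0:255
  w0 <- cumsum(h)[1:255]                  # pixels < t for t = 1..255
  s0 <- cumsum(h * lev)[1:255]
  w1 <- n - w0
  mu_tot <- sum(h * lev) / n
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (sum(h * lev) - s0[valid]) / w1[valid]
  bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  # the criterion plateaus across empty histogram stretches; take the
  # plateau midpoint (as ImageJ does) rather than its left edge
  as.integer(round(mean(which(bcv == max(bcv)))))   # foreground is v >= t
}

# 8-connected component labeling by iterative minimum-label propagation.
# Returns an integer matrix: 0 background, 1..K compact component labels.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- mask != 0
  if (!any(fg)) return(matrix(0L, nr, nc))
  lab <- matrix(Inf, nr + 2L, nc + 2L)
  core <- cbind(rep(2:(nr + 1L), nc), rep(2:(nc + 1L), each = nr))
  lab[2:(nr + 1L), 2:(nc + 1L)][fg] <- which(fg)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  repeat {
    cur <- lab[ri, ci, drop = FALSE]
    new <- cur
    for (k in seq_len(nrow(shifts))) {
      new <- pmin(new, lab[ri + shifts$dr[k], ci + shifts$dc[k], drop = FALSE])
    }
    new[!fg] <- Inf
    if (identical(new, cur)) break
    lab[ri, ci] <- new
  }
  out <- matrix(0L, nr, nc)
  ids <- lab[ri, ci, drop = FALSE][fg]
  out[fg] <- as.integer(factor(ids, levels = sort(unique(ids))))
  out
}

#' Segment the bright bone interface by thresholding
#'
#' Bone reflects strongly in B-mode imaging, so the bone surface inside the
#' bone ROI is delineated by intensity thresholding: pixels at or above the
#' threshold are foreground. Components are 8-connected; components smaller
#' than `min_fragment_px` are removed as speckle before counting fragments.
#'
#' @param region integer matrix of raw 8-bit values (the bone ROI).
#' @param threshold_method `"otsu"` (default, parameter-free) or `"fixed"`.
#' @param threshold integer cutoff, required for `"fixed"`.
#' @param min_fragment_px smallest component kept, default 5 pixels.
#' @return A `bone_segmentation`: list with `mask` (0/1 matrix), `labels`
#'   (component label matrix), `n_fragments`, `threshold_used` (`NA` when
#'   Otsu is degenerate on a single-gray-level region — then 0 fragments),
#'   and `min_fragment_px`.
#' @export
segment_bone <- function(region, threshold_method = c("otsu", "fixed"),
                         threshold = NULL, min_fragment_px = 5L) {
  threshold_method <- match.arg(threshold_method)
  if (min_fragment_px < 1L) stop("`min_fragment_px` must be >= 1")
  region <- unclass(region)
  thr <- if (threshold_method == "fixed") {
    if (is.null(threshold)) stop("`threshold` required for method 'fixed'")
    as.integer(threshold)
  } else {
    otsu_threshold(region)
  }
  if (is.na(thr)) {
    empty <- matrix(0L, nrow(region), ncol(region))
    return(structure(list(mask = empty, labels = empty, n_fragments = 0L,
                          threshold_used = NA_integer_,
                          min_fragment_px = as.integer(min_fragment_px)),
                     class = "bone_segmentation"))
  }
  mask <- (region >= thr) * 1L
  labels <- label_components(mask)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes >= min_fragment_px)
    labels[!(labels %in% keep)] <- 0L
    labels[labels > 0L] <- as.integer(factor(labels[labels > 0L],
                                             levels = keep))
  }
  structure(list(mask = (labels > 0L) * 1L, labels = labels,
                 n_fragments = max(labels),
                 threshold_used = thr,
                 min_fragment_px = as.integer(min_fragment_px)),
            class = "bone_segmentation")
}

# Moore-neighbor contour tracing of one component (8-connected outer
# boundary through pixel centers). Returns the closed contour arc length
# with diagonal steps weighted sqrt(2). A single isolated pixel has length 0.
trace_perimeter <- function(comp_mask) {
  nr <- nrow(comp_mask); nc <- ncol(comp_mask)
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- comp_mask != 0
  # clockwise Moore neighborhood starting West (dr, dc)
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  hit <- which(m, arr.ind = TRUE)
  start <- hit[order(hit[, 1], hit[, 2])[1], ]      # topmost, then leftmost
  p <- start
  enter <- 1L            # scan starts at the backtrack position, initially W
  path_len <- 0
  first_move <- NULL
  step <- 0L
  max_steps <- 8L * sum(m) + 8L
  repeat {
    move <- 0L
    for (k in 0:7) {
      d <- (enter - 1L + k) %% 8L + 1L
      q <- p + dirs[d, ]
      if (m[q[1], q[2]]) { move <- d; break }
    }
    if (move == 0L) return(0)                       # isolated pixel
    if (all(p == start)) {
      if (is.null(first_move)) first_move <- move
      else if (move == first_move) break            # Jacob's criterion
    }
    path_len <- path_len + sqrt(sum(dirs[move, ]^2))
    p <- p + dirs[move, ]
    # new scan starts at the last background checked, two clockwise steps
    # back from the move direction, seen from the new pixel
    enter <- (move - 1L + 6L) %% 8L + 1L
    step <- step + 1L
    if (step > max_steps) stop("contour tracing failed to terminate")
  }
  path_len
}

BONE_FEATURE_NAMES <- c("bone_n_fragments", "bone_area", "bone_perimeter",
                        "bone_convexity", "bone_glcm_homogeneity",
                        "bone_glcm_contrast", "bone_glcm_correlation")

#' The 7-variable bone descriptor
#'
#' Counts and measures the thresholded bone fragments and describes the
#' echotexture of the raw bone ROI:
#' \itemize{
#'   \item `bone_n_fragments`: connected components after speckle removal
#'   \item `bone_area`: total foreground pixel count (mm^2 with spacing)
#'   \item `bone_perimeter`: summed outer-contour arc length over fragments,
#'     diagonal steps weighted `sqrt(2)`
#'   \item `bone_convexity`: foreground area over the convex-hull area of
#'     the union of foreground pixels (pixels taken as unit squares);
#'     `NA` flagged undefined when there is no fragment
#'   \item `bone_glcm_homogeneity`: `sum(p / (1 + |i - j|))` — deliberately
#'     distinct from the texture ROIs' inverse difference moment
#'   \item `bone_glcm_contrast`, `bone_glcm_correlation`: as in
#'     [glcm_features()], computed on the raw (not thresholded) ROI so they
#'     describe the echotexture of the bone region
#' }
#'
#' @param seg a [segment_bone()] result.
#' @param region the raw 8-bit ROI the segmentation came from.
#' @param config a [tq_config()] (quantization / GLCM settings).
#' @param spacing_mm optional pixel spacing `c(row, col)`: area scales by
#'   `row * col`, perimeter by the mean spacing.
#' @return Named numeric vector of the 7 bone features.
#' @export
bone_features <- function(seg, region, config = tq_config(),
                          spacing_mm = NULL) {
  stopifnot(inherits(seg, "bone_segmentation"))
  n <- seg$n_fragments
  if (n == 0L) {
    area <- 0; perim <- 0; convex <- NA_real_
  } else {
    area <- sum(seg$mask)
    perim <- sum(vapply(seq_len(n), function(k) {
      trace_perimeter(seg$labels == k)
    }, numeric(1)))
    px <- which(seg$mask != 0, arr.ind = TRUE)
    # pixel (r, c) covers the unit square [c-1, c] x [r-1, r]
    corners <- rbind(cbind(px[, 2] - 1, px[, 1] - 1),
                     cbind(px[, 2],     px[, 1] - 1),
                     cbind(px[, 2] - 1, px[, 1]),
                     cbind(px[, 2],     px[, 1]))
    convex <- area / convex_hull_area(corners)
    if (!is.null(spacing_mm)) {
      area <- area * spacing_mm[1] * spacing_mm[2]
      perim <- perim * mean(spacing_mm)
    }
  }
  qr <- quantize(region, config$levels)
  g <- glcm(qr, levels = config$levels, distance = config$glcm_distance,
            angles = config$glcm_angles)
  gf <- glcm_features(g)
  lev <- 0:(config$levels - 1)
  I <- matrix(lev, config$levels, config$levels)
  J <- t(I)
  c(bone_n_fragments = as.numeric(n),
    bone_area = area,
    bone_perimeter = perim,
    bone_convexity = convex,
    bone_glcm_homogeneity = sum(g$p / (1 + abs(I - J))),
    bone_glcm_contrast = unname(gf["glcm_contrast"]),
    bone_glcm_correlation = unname(gf["glcm_correlation"]))
}
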