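#' Gray-level quantization
#'
#' Maps 8-bit pixel values onto `levels` equal-width gray bins:
#' `floor(v * levels / 256)`, giving values in `0 .. levels - 1`.
#' Co-occurrence and difference statistics are computed on this reduced
#' alphabet; 32 levels (the package default) stabilizes the estimates on the
#' small regions typical of tendon ROIs.
#'
#' @param region integer matrix of 8-bit values.
#' @param levels number of gray levels, between 2 and 256.
#' @return Integer matrix of the same shape with values in `0 .. levels - 1`.
#' @export
quantize <- function(region, levels = 32L) {
  if (levels < 2L || levels > 256L) stop("`levels` must be in [2, 256]")
  m <- floor(unclass(region) * levels / 256)
  storage.mode(m) <- "integer"
  m
}

# angle (degrees) -> (row, col) offset at unit distance; y grows downwards
.GLCM_OFFSETS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                      `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(v(x), v(x + offset))` at the given distance
#' for each requested orientation, symmetrizes each count matrix by adding
#' its transpose, normalizes to probabilities, and averages over the
#' orientations. The result is a symmetric `levels x levels` probability
#' matrix summing to 1.
#'
#' Orientations with no valid pairs (region smaller than the offset) are
#' dropped from the average; it is an error if no orientation yields a pair.
#'
#' @param region quantized integer matrix (values `0 .. levels - 1`).
#' @param levels number of gray levels of the quantized region.
#' @param distance pair offset length in pixels, default 1.
#' @param angles orientations in degrees, subset of `c(0, 45, 90, 135)`.
#' @return A `glcm` object: list with elements `p` (probability matrix),
#'   `levels`, `distance`, `angles`.
#' @export
glcm <- function(region, levels = 32L, distance = 1L,
                 angles = c(0, 45, 90, 135)) {
  region <- unclass(region)
  if (any(region < 0 | region >= levels))
    stop("region values must lie in [0, levels)")
  if (distance < 1L) stop("`distance` must be a positive integer")
  if (!all(angles %in% c(0, 45, 90, 135)))
    stop("`angles` must be a subset of {0, 45, 90, 135}")
  nr <- nrow(region); nc <- ncol(region)
  acc <- matrix(0, levels, levels)
  used <- 0L
  for (a in angles) {
    off <- .GLCM_OFFSETS[[as.character(a)]] * distance
    rows <- seq_len(nr)[seq_len(nr) + off[1] >= 1 & seq_len(nr) + off[1] <= nr]
    cols <- seq_len(nc)[seq_len(nc) + off[2] >= 1 & seq_len(nc) + off[2] <= nc]
    if (!length(rows) || !length(cols)) next
    i <- region[rows, cols, drop = FALSE]
    j <- region[rows + off[1], cols + off[2], drop = FALSE]
    counts <- matrix(tabulate(i * levels + j + 1L, nbins = levels * levels),
                     levels, levels, byrow = TRUE)
    counts <- counts + t(counts)
    acc <- acc + counts / sum(counts)
    used <- used + 1L
  }
  if (used == 0L) stop("no valid pixel pairs for the requested offsets")
  structure(list(p = acc / used, levels = levels,
                 distance = distance, angles = angles),
            class = "glcm")
}

#' Haralick features of a co-occurrence matrix
#'
#' The six GLCM descriptors used for the texture ROIs, with gray levels
#' indexed `0 .. Ng - 1`:
#' \itemize{
#'   \item contrast: sum of `(i - j)^2 p(i, j)`
#'   \item sum average: mean of the gray-level-sum distribution `p_{x+y}`
#'   \item sum-of-squares variance: `sum((i - mu)^2 p(i, j))`, `mu` the
#'     marginal mean
#'   \item difference variance: variance of the gray-level-difference
#'     distribution `p_{x-y}`
#'   \item correlation: `(sum(i j p(i, j)) - mu_x mu_y) / (sigma_x sigma_y)`;
#'     `NA` (flagged undefined) on a constant region where a marginal
#'     standard deviation vanishes
#'   \item inverse difference moment: sum of `p(i, j) / (1 + (i - j)^2)`
#' }
#'
#' @param m a [glcm()] object.
#' @return Named numeric vector `glcm_contrast`, `glcm_sum_average`,
#'   `glcm_ssq_variance`, `glcm_difference_variance`, `glcm_correlation`,
#'   `glcm_idm`.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  p <- m$p
  ng <- m$levels
  lev <- 0:(ng - 1)
  I <- matrix(lev, ng, ng)         # row index value
  J <- matrix(lev, ng, ng, byrow = TRUE)
  px <- rowSums(p)                  # symmetric: px == py
  mu <- sum(lev * px)
  sigma <- sqrt(sum((lev - mu)^2 * px))
  # gray-level sum and absolute-difference distributions
  psum <- tapply(p, I + J, sum)
  ks <- as.numeric(names(psum))
  pdiff <- tapply(p, abs(I - J), sum)
  kd <- as.numeric(names(pdiff))
  mud <- sum(kd * pdiff)
  corr <- if (sigma < 1e-12) NA_real_ else
    (sum(I * J * p) - mu * mu) / (sigma * sigma)
  c(glcm_contrast = sum((I - J)^2 * p),
    glcm_sum_average = sum(ks * psum),
    glcm_ssq_variance = sum((I - mu)^2 * p),
    glcm_difference_variance = sum((kd - mud)^2 * pdiff),
    glcm_correlation = corr,
    glcm_idm = sum(p / (1 + (I - J)^2)))
}

# default GLDS displacement set: the four canonical unit offsets, (row, col)
.GLDS_DISPLACEMENTS <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

#' Gray-level difference statistics histogram
#'
#' Histogram of absolute gray-level differences `|v(x) - v(x + d)|` pooled
#' over all valid pixel pairs of all requested displacements, normalized to
#' probabilities over `k = 0 .. levels - 1`. Pooling the pair set (rather
#' than averaging per-displacement feature values) keeps the estimate
#' sample-efficient on small ROIs.
#'
#' @param region quantized integer matrix (values `0 .. levels - 1`).
#' @param levels number of gray levels.
#' @param displacements list of `(row, col)` integer offsets.
#' @return A `glds` object: list with `q` (probability vector of length
#'   `levels`), `levels`, `displacements`.
#' @export
glds <- function(region, levels = 32L, displacements = .GLDS_DISPLACEMENTS) {
  region <- unclass(region)
  if (any(region < 0 | region >= levels))
    stop("region values must lie in [0, levels)")
  nr <- nrow(region); nc <- ncol(region)
  counts <- numeric(levels)
  for (off in displacements) {
    rows <- seq_len(nr)[seq_len(nr) + off[1] >= 1 & seq_len(nr) + off[1] <= nr]
    cols <- seq_len(nc)[seq_len(nc) + off[2] >= 1 & seq_len(nc) + off[2] <= nc]
    if (!length(rows) || !length(cols)) next
    d <- abs(region[rows, cols, drop = FALSE] -
               region[rows + off[1], cols + off[2], drop = FALSE])
    counts <- counts + tabulate(d + 1L, nbins = levels)
  }
  if (sum(counts) == 0) stop("no valid pixel pairs for the displacements")
  structure(list(q = counts / sum(counts), levels = levels,
                 displacements = displacements),
            class = "glds")
}

#' Features of a gray-level difference histogram
#'
#' With `q(k)` the probability of absolute difference `k`:
#' homogeneity `sum(q / (1 + k^2))`, contrast `sum(k^2 q)`, angular second
#' moment `sum(q^2)`, entropy `-sum(q log q)` over nonzero bins (natural
#' log), and mean `sum(k q)`.
#'
#' @param h a [glds()] object.
#' @return Named numeric vector `glds_homogeneity`, `glds_contrast`,
#'   `glds_asm`, `glds_entropy`, `glds_mean`.
#' @export
glds_features <- function(h) {
  stopifnot(inherits(h, "glds"))
  q <- h$q
  k <- seq_along(q) - 1
  qn <- q[q > 0]
  c(glds_homogeneity = sum(q / (1 + k^2)),
    glds_contrast = sum(k^2 * q),
    glds_asm = sum(q^2),
    glds_entropy = -sum(qn * log(qn)),
    glds_mean = sum(k * q))
}

# One-level 2D Haar decomposition by 2x2 block filtering (orthonormal
# normalization, divisor 2). Odd trailing row/column truncated, not padded:
# padding would invent gradients at the border.
haar_decompose <- function(region) {
  x <- unclass(region)
  nr <- nrow(x) - nrow(x) %% 2L
  nc <- ncol(x) - ncol(x) %% 2L
  if (nr < 2L || nc < 2L) stop("region must be at least 2x2")
  a <- x[seq(1L, nr, 2L), seq(1L, nc, 2L), drop = FALSE]
  b <- x[seq(1L, nr, 2L), seq(2L, nc, 2L), drop = FALSE]
  cc <- x[seq(2L, nr, 2L), seq(1L, nc, 2L), drop = FALSE]
  d <- x[seq(2L, nr, 2L), seq(2L, nc, 2L), drop = FALSE]
  list(approx = (a + b + cc + d) / 2,
       horiz = (a - b + cc - d) / 2,   # column differences: vertical edges
       vert  = (a + b - cc - d) / 2,   # row differences: horizontal edges
       diag  = (a - b - cc + d) / 2)
}

#' Haar wavelet sub-band statistics
#'
#' One-level 2D Haar transform of the raw 8-bit region (2x2 block averages
#' and differences, orthonormal scaling). The three detail sub-bands
#' (horizontal, vertical, diagonal) carry the local intensity gradients; the
#' returned statistics are the mean and the population variance of the
#' pooled absolute detail coefficients. The approximation band is excluded —
#' its statistics would duplicate plain mean intensity.
#'
#' @param region integer matrix of raw 8-bit values, at least 2x2; an odd
#'   trailing row/column is truncated.
#' @return Named numeric vector `haar_mean`, `haar_variance`.
#' @export
haar_features <- function(region) {
  dec <- haar_decompose(region)
  v <- abs(c(dec$horiz, dec$vert, dec$diag))
  c(haar_mean = mean(v), haar_variance = mean((v - mean(v))^2))
}

TEXTURE_FEATURE_NAMES <- c(
  "glcm_contrast", "glcm_sum_average", "glcm_ssq_variance",
  "glcm_difference_variance", "glcm_correlation", "glcm_idm",
  "glds_homogeneity", "glds_contrast", "glds_asm", "glds_entropy",
  "glds_mean", "haar_mean", "haar_variance")

#' The 13-variable texture descriptor of a rectangular ROI
#'
#' Quantizes the ROI, computes the six GLCM and five GLDS features on the
#' quantized alphabet, and the two Haar sub-band statistics on the raw 8-bit
#' pixels (difference statistics need the reduced alphabet; gradient
#' statistics do not). Used for the tissue-quality and the two
#' tendon-border ROIs.
#'
#' @param img an [us_image()].
#' @param rect a [rect_roi()] inside the image.
#' @param config a [tq_config()]; controls quantization levels, GLCM
#'   distance/angles and GLDS displacements.
#' @return Named numeric vector of the 13 texture features;
#'   `glcm_correlation` is `NA` (flagged undefined) on a constant region.
#' @export
texture_vector <- function(img, rect, config = tq_config()) {
  region <- roi_pixels(img, rect)
  qr <- quantize(region, config$levels)
  g <- glcm(qr, levels = config$levels, distance = config$glcm_distance,
            angles = config$glcm_angles)
  h <- glds(qr, levels = config$levels,
            displacements = config$glds_displacements)
  out <- c(glcm_features(g), glds_features(h), haar_features(region))
  out[TEXTURE_FEATURE_NAMES]
}
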