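# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
# Keeps all generators pure functions of their spec.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# unit-mean Rayleigh speckle envelope (first-order B-mode speckle model)
rayleigh_envelope <- function(n, scale = sqrt(2 / pi)) {
  scale * sqrt(-2 * log(stats::runif(n)))
}

# fraction of diffuse (speckle) backscatter inside the organized tendon
# band; the remainder is the coherent fibrillar component
.FIBRIL_COHERENCE <- 0.45

#' Generate a speckled tendon phantom with ground truth
#'
#' A deterministic stand-in for a longitudinal B-mode view of the patellar
#' tendon: a fibrillar (horizontally striped) echogenic tendon band over a
#' dim background, multiplicative Rayleigh speckle throughout, optional dark
#' circular lesions emulating hypoechoic tendinopathic defects, and a bright
#' bone band broken by `n_gaps` anechoic gaps (ground truth for the
#' fragment count). The function also returns the matching ROI set
#' (quality, upper edge, lower edge, bone rectangles and the tendon-body
#' polygon) and the generating truth, so every feature module can be tested
#' end to end without clinical images. Same spec (seed included) gives a
#' bit-identical image.
#'
#' @param rows,cols image size, default 128 x 192.
#' @param speckle_scale Rayleigh scale of the speckle envelope; the default
#'   `sqrt(2 / pi)` gives a unit-mean envelope (full developed speckle,
#'   coefficient of variation about 0.52).
#' @param band_period,band_contrast fibrillar stripe period (px) and
#'   relative amplitude.
#' @param lesion_count,lesion_radius,lesion_darkening number, radius (px)
#'   and relative darkening of tendinopathic lesions inside the tendon
#'   band. A lesion loses the coherent fibrillar backscatter (its speckle
#'   becomes fully developed, hence locally rougher) and is mildly
#'   hypoechoic.
#' @param bone_y,bone_thickness,bone_brightness bone band top row (0-based),
#'   thickness and mean gray level; defaults place it under the tendon.
#' @param n_gaps number of gaps splitting the bone band into `n_gaps + 1`
#'   fragments.
#' @param gap_width gap width in pixels.
#' @param seed RNG seed; fixed seed implies a bit-identical phantom.
#' @return List with `image` ([us_image()]), `rois` ([roi_set()]), and
#'   `truth` (list: `n_fragments`, `bone_threshold` — a fixed threshold
#'   guaranteed to separate bone from background —, `lesion_centers`,
#'   `tendon_rows`, `polygon`).
#' @export
generate_phantom <- function(rows = 128L, cols = 192L,
                             speckle_scale = sqrt(2 / pi),
                             band_period = 6, band_contrast = 0.35,
                             lesion_count = 0L, lesion_radius = 6,
                             lesion_darkening = 0.35,
                             bone_y = round(0.78 * rows),
                             bone_thickness = 8L,
                             bone_brightness = 235,
                             n_gaps = 0L, gap_width = 6L,
                             seed = 1L) {
  stopifnot(rows >= 64, cols >= 64, bone_y + bone_thickness <= rows,
            n_gaps >= 0, lesion_count >= 0)
  tendon_top <- round(0.18 * rows)
  tendon_bottom <- round(0.60 * rows)
  gen <- with_seed(seed, {
    yy <- matrix(seq_len(rows), rows, cols)
    mu <- matrix(28, rows, cols)
    band <- yy >= tendon_top & yy < tendon_bottom
    mu[band] <- 115 * (1 + band_contrast * sin(2 * pi * yy[band] / band_period))
    lesion_centers <- NULL
    if (lesion_count > 0L) {
      cy <- round(stats::runif(lesion_count, tendon_top + lesion_radius + 2,
                               tendon_bottom - lesion_radius - 2))
      cx <- round(stats::runif(lesion_count, lesion_radius + 2,
                               cols - lesion_radius - 2))
      lesion_centers <- cbind(x = cx, y = cy)
      xx <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
      lesion_hits <- list()
      for (k in seq_len(lesion_count)) {
        d2 <- (xx - cx[k])^2 + (yy - cy[k])^2
        lesion_hits[[k]] <- which(d2 <= lesion_radius^2 & band)
      }
    }
    # healthy tendon scatters partly coherently (organized fibrils): the
    # band gets a damped speckle envelope; elsewhere speckle is fully
    # developed
    E <- matrix(rayleigh_envelope(rows * cols, speckle_scale), rows, cols)
    E[band] <- (1 - .FIBRIL_COHERENCE) + .FIBRIL_COHERENCE * E[band]
    img <- mu * E
    if (lesion_count > 0L) {
      # tendinopathic degeneration: loss of the coherent fibrillar
      # component (fully developed speckle again) plus mild
      # hypoechogenicity - locally rougher, not merely dimmer
      for (hit in lesion_hits) {
        img[hit] <- mu[hit] * (1 - lesion_darkening) *
          rayleigh_envelope(length(hit), speckle_scale)
      }
    }
    # bright bone band, mildly noisy, broken by anechoic gaps
    bone_rows <- (bone_y + 1L):(bone_y + bone_thickness)
    img[bone_rows, ] <- bone_brightness +
      stats::rnorm(length(bone_rows) * cols, 0, 6)
    if (n_gaps > 0L) {
      centers <- round(seq(0, cols, length.out = n_gaps + 2L))[2:(n_gaps + 1L)]
      for (g in centers) {
        c0 <- max(1L, g - floor(gap_width / 2))
        c1 <- min(cols, c0 + gap_width - 1L)
        img[bone_rows, c0:c1] <- 15 + abs(stats::rnorm(
          length(bone_rows) * (c1 - c0 + 1L), 0, 5))
      }
    }
    list(image = us_image(pmin(pmax(round(img), 0), 255)),
         lesion_centers = lesion_centers)
  })
  mid <- round((tendon_top + tendon_bottom) / 2)
  qh <- max(16L, round((tendon_bottom - tendon_top) * 0.5))
  rects <- list(
    quality = rect_roi(round(cols * 0.2), mid - round(qh / 2),
                       round(cols * 0.6), qh, "quality"),
    upper_edge = rect_roi(round(cols * 0.2), tendon_top - 5,
                          round(cols * 0.6), 10, "upper_edge"),
    lower_edge = rect_roi(round(cols * 0.2), tendon_bottom - 5,
                          round(cols * 0.6), 10, "lower_edge"),
    bone = rect_roi(4, bone_y - 4, cols - 8, bone_thickness + 8, "bone"))
  polygon <- rbind(c(4, tendon_top), c(cols - 4, tendon_top),
                   c(cols - 4, tendon_bottom), c(4, tendon_bottom))
  rois <- roi_set(rects = rects, poly = poly_roi(polygon),
                  image_id = sprintf("phantom_seed%d", seed))
  truth <- list(n_fragments = n_gaps + 1L,
                bone_threshold = 128L,
                lesion_centers = gen$lesion_centers,
                tendon_rows = c(top = tendon_top, bottom = tendon_bottom),
                polygon = polygon)
  list(image = gen$image, rois = rois, truth = truth)
}

#' Simulate a longitudinal dataset from the random-intercept logistic model
#'
#' Generates data from the model the prediction stage fits:
#' `u_j ~ N(0, sigma^2)` per subject, `x_ij ~ N(x_mean, x_sd^2)` per
#' observation, `Y_ij ~ Bernoulli(plogis(beta0 + beta1 x_ij + u_j))`.
#' Ordinal 0-3 grades are also emitted by cutting the linear predictor at
#' its 40/70/90 percent quantiles, giving all four grades non-trivial
#' frequency for dichotomization tests (including the severe-grade guard).
#'
#' @param n_subjects,obs_per_subject design size.
#' @param beta0,beta1,sigma generative intercept, slope and random-intercept
#'   standard deviation.
#' @param x_mean,x_sd covariate distribution.
#' @param seed RNG seed.
#' @return Data frame: `subject_id`, `obs`, `x`, `u`, `eta`, `y`, `grade`.
#' @export
generate_glmm_dataset <- function(n_subjects = 200L, obs_per_subject = 4L,
                                  beta0 = -1, beta1 = 1.5, sigma = 1,
                                  x_mean = 0, x_sd = 1, seed = 1L) {
  stopifnot(n_subjects >= 2L, obs_per_subject >= 1L, sigma >= 0)
  with_seed(seed, {
    n <- n_subjects * obs_per_subject
    subject <- rep(seq_len(n_subjects), each = obs_per_subject)
    u <- stats::rnorm(n_subjects, 0, sigma)[subject]
    x <- stats::rnorm(n, x_mean, x_sd)
    eta <- beta0 + beta1 * x + u
    y <- stats::rbinom(n, 1L, stats::plogis(eta))
    # rank-based quantile cut: robust to ties / a degenerate constant eta
    q <- rank(eta, ties.method = "first") / n
    grade <- as.integer(cut(q, breaks = c(0, 0.4, 0.7, 0.9, 1),
                            include.lowest = TRUE)) - 1L
    data.frame(subject_id = sprintf("S%03d", subject),
               obs = rep(seq_len(obs_per_subject), n_subjects),
               x = x, u = u, eta = eta, y = y, grade = grade,
               stringsAsFactors = FALSE)
  })
}

#' Simulate paired ordinal ratings with tunable agreement
#'
#' Session 1 grades are uniform over 0-3; session 2 repeats session 1 with
#' probability `agreement_level` and is otherwise redrawn uniformly from
#' the three other grades. Marginals stay uniform, agreement 0.25
#' reproduces exact independence, and the expected quadratic-weighted kappa
#' has the closed form `1 - (4 / 3) (1 - agreement_level)`.
#'
#' @param n number of rated subjects.
#' @param agreement_level probability in \[0, 1\] of repeating the grade.
#' @param seed RNG seed.
#' @return Data frame: `subject_id`, `session1`, `session2`.
#' @export
generate_rating_pairs <- function(n, agreement_level, seed = 1L) {
  stopifnot(agreement_level >= 0, agreement_level <= 1, n >= 2)
  with_seed(seed, {
    s1 <- sample(0:3, n, replace = TRUE)
    keep <- stats::runif(n) < agreement_level
    shift <- sample(1:3, n, replace = TRUE)    # uniform over other grades
    s2 <- ifelse(keep, s1, (s1 + shift) %% 4L)
    data.frame(subject_id = sprintf("S%05d", seq_len(n)),
               session1 = s1, session2 = s2, stringsAsFactors = FALSE)
  })
}

#' Simulate paired quantitative measurements for ICC checks
#'
#' Subject true values are `N(0, sigma_b^2)`; each session adds independent
#' `N(0, sigma_e^2)` error. The two-way consistency ICC of this model is
#' `sigma_b^2 / (sigma_b^2 + sigma_e^2)`.
#'
#' @param n subjects.
#' @param sigma_b,sigma_e between-subject and within-subject (session error)
#'   standard deviations.
#' @param seed RNG seed.
#' @return Data frame: `subject_id`, `session1`, `session2`.
#' @export
generate_paired_measurements <- function(n, sigma_b = 1, sigma_e = 1,
                                         seed = 1L) {
  with_seed(seed, {
    b <- stats::rnorm(n, 0, sigma_b)
    data.frame(subject_id = sprintf("S%05d", seq_len(n)),
               session1 = b + stats::rnorm(n, 0, sigma_e),
               session2 = b + stats::rnorm(n, 0, sigma_e),
               stringsAsFactors = FALSE)
  })
}
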