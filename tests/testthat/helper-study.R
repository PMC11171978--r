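# A small two-session study in the layout the pipeline consumes: latent
# per-subject severity drives both the expert grades and a handful of
# canonical quantitative variables. One variable is pure noise so the ICC
# screen has something to reject.

make_synthetic_study <- function(n_subjects = 20, seed = 1,
                                 grade_cap = 3L,
                                 rois = c("bone", "quality", "thickness")) {
  set.seed(seed)
  z <- rnorm(n_subjects)                      # latent severity
  subj <- sprintf("P%02d", seq_len(n_subjects))
  grade_of <- function(zz) {
    g <- as.integer(cut(zz, c(-Inf, -0.5, 0.5, 1.3, Inf))) - 1L
    pmin(g, grade_cap)
  }
  ratings <- do.call(rbind, lapply(rois, function(rn) {
    do.call(rbind, lapply(1:2, function(s) {
      data.frame(subject_id = subj, session = s, roi_name = rn,
                 grade = grade_of(z + rnorm(n_subjects, 0, 0.3)),
                 stringsAsFactors = FALSE)
    }))
  }))
  informative <- function(slope, noise_sd = 0.3)
    slope * rep(z, 2) + rnorm(2 * n_subjects, 0, noise_sd)
  features <- data.frame(
    subject_id = rep(subj, 2),
    session = rep(1:2, each = n_subjects),
    bone_glcm_contrast = informative(1.2),
    bone_area = informative(0.8),
    quality_glds_homogeneity = informative(-1.0),
    morph_mean_width = informative(1.0),
    quality_glds_mean = rnorm(2 * n_subjects),   # unreliable: pure noise
    stringsAsFactors = FALSE)
  list(features = features, ratings = ratings, z = z)
}
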