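#' Extraction and analysis configuration
#'
#' One object collects every tunable of the pipeline so each run can record
#' its full provenance. Defaults: 32 gray levels, GLCM distance 1 averaged
#' over the four canonical orientations, GLDS pooled over the four unit
#' displacements, 100 morphology stations, Otsu bone threshold with a
#' 5-pixel speckle floor, two-way absolute-agreement ICC screening at 0.75,
#' Laplace GLMM integration.
#'
#' @param levels gray levels for quantization (2-256).
#' @param glcm_distance,glcm_angles co-occurrence offset and orientations.
#' @param glds_displacements list of (row, col) difference offsets.
#' @param n_stations morphology width-profile sampling stations.
#' @param bone_threshold_method `"otsu"` or `"fixed"`.
#' @param bone_threshold fixed cutoff (used when method is `"fixed"`).
#' @param min_fragment_px smallest bone fragment kept.
#' @param icc_form ICC used for screening: `"agreement"`, `"consistency"`
#'   or `"oneway"`.
#' @param icc_threshold screening cutoff.
#' @param nagq GLMM integration points (1 = Laplace).
#' @return A `tq_config` list.
#' @export
tq_config <- function(levels = 32L, glcm_distance = 1L,
                      glcm_angles = c(0, 45, 90, 135),
                      glds_displacements = .GLDS_DISPLACEMENTS,
                      n_stations = 100L,
                      bone_threshold_method = "otsu",
                      bone_threshold = NULL,
                      min_fragment_px = 5L,
                      icc_form = "agreement",
                      icc_threshold = 0.75,
                      nagq = 1L) {
  if (levels < 2L || levels > 256L) stop("`levels` must be in [2, 256]")
  if (icc_threshold < 0 || icc_threshold > 1)
    stop("`icc_threshold` must be in [0, 1]")
  structure(list(levels = as.integer(levels),
                 glcm_distance = as.integer(glcm_distance),
                 glcm_angles = glcm_angles,
                 glds_displacements = glds_displacements,
                 n_stations = as.integer(n_stations),
                 bone_threshold_method = bone_threshold_method,
                 bone_threshold = bone_threshold,
                 min_fragment_px = as.integer(min_fragment_px),
                 icc_form = icc_form,
                 icc_threshold = icc_threshold,
                 nagq = as.integer(nagq)),
            class = "tq_config")
}

# canonical order of the 51-variable quantitative descriptor
feature_block <- function(prefix) paste0(prefix, "_", TEXTURE_FEATURE_NAMES)

#' Canonical names of the 51-variable descriptor
#'
#' 13 texture variables for each of the quality, upper-edge and lower-edge
#' ROIs, 5 morphology variables, 7 bone variables — in the fixed order used
#' by every writer and reader in the package.
#'
#' @return Character vector of length 51.
#' @export
feature_names <- function() {
  c(feature_block("quality"), feature_block("upper_edge"),
    feature_block("lower_edge"), MORPH_FEATURE_NAMES, BONE_FEATURE_NAMES)
}

#' Extract the full 51-variable descriptor of one image
#'
#' Runs all four analysis modules on their ROIs: texture (GLCM + GLDS +
#' Haar) on the quality and the two edge rectangles, width/parallelism
#' morphology on the tendon polygon, and threshold-based bone analysis on
#' the bone rectangle. Missing ROIs yield a flagged-missing block (`NA`
#' values listed in the `flags` attribute), never a silently shorter
#' vector.
#'
#' @param img an [us_image()].
#' @param rois a [roi_set()].
#' @param config a [tq_config()].
#' @return A `feature_vector`: named numeric of length 51 in canonical
#'   order, with attributes `image_id`, `aux` (named numeric, currently the
#'   auxiliary `morph_convexity`) and `flags` (named character: variables
#'   undefined or from missing ROIs, with reasons).
#' @export
extract_all <- function(img, rois, config = tq_config()) {
  stopifnot(inherits(img, "us_image"), inherits(rois, "roi_set"))
  vals <- stats::setNames(rep(NA_real_, 51L), feature_names())
  flags <- character(0)
  spacing <- attr(img, "pixel_spacing_mm")
  for (rn in c("quality", "upper_edge", "lower_edge")) {
    if (is.null(rois$rects[[rn]])) {
      flags[feature_block(rn)] <- "missing ROI"
      next
    }
    tv <- texture_vector(img, rois$rects[[rn]], config)
    vals[feature_block(rn)] <- unname(tv)
    if (is.na(tv["glcm_correlation"]))
      flags[paste0(rn, "_glcm_correlation")] <- "undefined on constant region"
  }
  aux <- c(morph_convexity = NA_real_)
  if (is.null(rois$poly)) {
    flags[MORPH_FEATURE_NAMES] <- "missing ROI"
  } else {
    mf <- morphology_features(rois$poly, n_stations = config$n_stations,
                              spacing_mm = spacing)
    vals[MORPH_FEATURE_NAMES] <- unname(mf$features)
    aux["morph_convexity"] <- mf$convexity
    if (is.na(mf$features["morph_width_ratio"]))
      flags["morph_width_ratio"] <- "zero minimum width"
  }
  if (is.null(rois$rects$bone)) {
    flags[BONE_FEATURE_NAMES] <- "missing ROI"
  } else {
    region <- roi_pixels(img, rois$rects$bone)
    seg <- segment_bone(region,
                        threshold_method = config$bone_threshold_method,
                        threshold = config$bone_threshold,
                        min_fragment_px = config$min_fragment_px)
    bf <- bone_features(seg, region, config, spacing_mm = spacing)
    vals[BONE_FEATURE_NAMES] <- unname(bf)
    if (is.na(bf["bone_convexity"]))
      flags["bone_convexity"] <- "no bone fragment"
    if (is.na(bf["bone_glcm_correlation"]))
      flags["bone_glcm_correlation"] <- "undefined on constant region"
  }
  structure(vals, image_id = rois$image_id, aux = aux, flags = flags,
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> image '%s': %d variables, %d flagged\n",
              attr(x, "image_id"), length(x), length(attr(x, "flags"))))
  invisible(x)
}

#' Write feature vectors to CSV
#'
#' One row per image: `image_id` followed by the 51 variables in canonical
#' order (52 columns). With `include_aux = TRUE` the auxiliary
#' `morph_convexity` column is appended after the canonical block.
#'
#' @param fvs a `feature_vector` or list of them.
#' @param path output CSV path.
#' @param include_aux append auxiliary columns, default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_features <- function(fvs, path, include_aux = FALSE) {
  if (inherits(fvs, "feature_vector")) fvs <- list(fvs)
  cols <- feature_names()
  rows <- lapply(fvs, function(fv) {
    stopifnot(inherits(fv, "feature_vector"),
              identical(names(fv), cols))
    d <- data.frame(image_id = attr(fv, "image_id"), stringsAsFactors = FALSE)
    d[cols] <- as.numeric(fv)
    if (include_aux) d[names(attr(fv, "aux"))] <- as.numeric(attr(fv, "aux"))
    d
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    cbind(data.frame(image_id = character(0), stringsAsFactors = FALSE),
          as.data.frame(matrix(numeric(0), 0, length(cols),
                               dimnames = list(NULL, cols))))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [write_features()]
#'
#' @param path CSV path.
#' @return Data frame with `image_id` and the 51 canonical columns.
#' @export
read_features <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_names(), names(d))
  if (length(missing))
    stop("feature CSV lacks columns: ", paste(missing, collapse = ", "))
  d
}

# roi_name of the rating scale -> feature-column prefix of the descriptor
.ROI_PREFIX <- c(bone = "bone", quality = "quality", thickness = "morph",
                 upper_edge = "upper_edge", lower_edge = "lower_edge")

#' Run the complete reliability-and-validity analysis
#'
#' The statistical pipeline applied to a two-session study: (1) per-ROI
#' rating reliability (quadratic-weighted kappa, Kendall's W); (2) per
#' quantitative variable, the three ICC forms and Kendall's W, with
#' ICC-based screening (variables below the threshold are discarded as
#' candidate predictors); (3) per rated ROI and response rule (Y1 = any
#' change, Y3 = severe change), a single-covariate random-intercept
#' logistic GLMM for every retained variable of that ROI, leave-one-
#' subject-out cross-validation, the cross-validated ROC/AUC, and selection
#' of the highest-AUC model. Responses observed in a single class are
#' reported as "model not created".
#'
#' Both sessions of each subject enter the prediction data as repeated
#' observations of that subject, with the rating of the same session as the
#' response.
#'
#' @param features data frame: `subject_id`, `session` (1/2) and the
#'   quantitative variable columns (canonical names).
#' @param ratings data frame: `subject_id`, `session`, `roi_name`
#'   (`bone`, `quality`, `thickness`, `upper_edge`, `lower_edge`), `grade`
#'   (0-3).
#' @param config a [tq_config()].
#' @return A `validation_report`: list with `rating_reliability`,
#'   `feature_reliability`, `retained`, `models` (per ROI x response ranked
#'   data frames), and `config`.
#' @export
run_validation <- function(features, ratings, config = tq_config()) {
  rel_ratings <- rating_reliability(ratings)
  vars <- intersect(feature_names(), names(features))
  if (!length(vars)) stop("no canonical feature columns in `features`")
  rel_feat <- reliability_table(features, variables = vars,
                                icc_form = config$icc_form,
                                threshold = config$icc_threshold)
  retained <- screen_variables(rel_feat)
  models <- list()
  for (rn in intersect(names(.ROI_PREFIX), unique(ratings$roi_name))) {
    roi_vars <- retained[startsWith(retained,
                                    paste0(.ROI_PREFIX[[rn]], "_"))]
    r <- ratings[ratings$roi_name == rn, c("subject_id", "session", "grade")]
    merged <- merge(features, r, by = c("subject_id", "session"))
    for (rule in c("Y1", "Y3")) {
      key <- paste(rn, rule, sep = ".")
      if (!length(roi_vars)) {
        models[[key]] <- data.frame()
        next
      }
      res <- validity_analysis(merged, roi_vars, rule = rule,
                               nagq = config$nagq)
      models[[key]] <- select_best(res)
    }
  }
  structure(list(rating_reliability = rel_ratings,
                 feature_reliability = rel_feat,
                 retained = retained,
                 models = models,
                 config = config),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  %d variables screened, %d retained (ICC %s >= %.2f)\n",
              nrow(x$feature_reliability), length(x$retained),
              x$config$icc_form, x$config$icc_threshold))
  for (key in names(x$models)) {
    m <- x$models[[key]]
    if (!nrow(m)) {
      cat(sprintf("  %-18s no candidate variables\n", key))
    } else if (all(m$status != "ok")) {
      cat(sprintf("  %-18s model not created (%s)\n", key,
                  "single-class response"))
    } else {
      best <- m[which(m$selected)[1], ]
      cat(sprintf("  %-18s best %s: AUC %.3f (beta1 %.3g)\n", key,
                  best$variable, best$auc, best$beta1))
    }
  }
  invisible(x)
}

#' Write a validation report to a directory of CSV/JSON files
#'
#' Writes `rating_reliability.csv`, `feature_reliability.csv`, one
#' `models_<roi>_<rule>.csv` per analysis, and `report.json` with the
#' resolved configuration and the retained-variable list.
#'
#' @param report a [run_validation()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$rating_reliability,
                   file.path(dir, "rating_reliability.csv"),
                   row.names = FALSE)
  utils::write.csv(report$feature_reliability,
                   file.path(dir, "feature_reliability.csv"),
                   row.names = FALSE)
  for (key in names(report$models)) {
    m <- report$models[[key]]
    if (nrow(m))
      utils::write.csv(m, file.path(dir, sprintf("models_%s.csv",
                                                 gsub("\\.", "_", key))),
                       row.names = FALSE)
  }
  cfg <- report$config
  cfg$glds_displacements <- lapply(cfg$glds_displacements, as.integer)
  jsonlite::write_json(
    list(config = unclass(cfg), retained = report$retained,
         models = names(report$models)),
    file.path(dir, "report.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(dir)
}
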