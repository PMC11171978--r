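#' Quadratic-weighted Cohen's kappa for two sessions of ordinal grades
#'
#' Chance-corrected agreement with squared disagreement weights
#' `w_ij = ((i - j) / (k - 1))^2`:
#' `kappa_w = 1 - sum(w * o) / sum(w * e)`, where `o` is the observed joint
#' proportion matrix of the two sessions and `e` the product of its
#' marginals. Undefined (returns `NA`) when the expected weighted
#' disagreement is zero, i.e. both sessions are constant.
#'
#' @param session1,session2 integer grades in `0 .. n_categories - 1`.
#' @param n_categories number of ordinal categories, default 4 (grades 0-3).
#' @return The weighted kappa, or `NA_real_` if undefined.
#' @export
weighted_kappa <- function(session1, session2, n_categories = 4L) {
  stopifnot(length(session1) == length(session2), length(session1) >= 2)
  k <- n_categories
  if (any(c(session1, session2) < 0 | c(session1, session2) >= k))
    stop("grades must lie in [0, n_categories)")
  o <- table(factor(session1, levels = 0:(k - 1)),
             factor(session2, levels = 0:(k - 1))) / length(session1)
  e <- outer(rowSums(o), colSums(o))
  w <- outer(0:(k - 1), 0:(k - 1), function(i, j) ((i - j) / (k - 1))^2)
  denom <- sum(w * e)
  if (denom <= 0) return(NA_real_)
  1 - sum(w * o) / denom
}

#' Intraclass correlation coefficients for two-session measurements
#'
#' Single-measure ICCs from the two-way subject x session mean-squares
#' decomposition (n subjects, k = 2 sessions): with `MSR` the
#' between-subject, `MSC` the between-session, `MSE` the residual and `MSW`
#' the within-subject mean square,
#' \itemize{
#'   \item one-way consistency, ICC(1):
#'     `(MSR - MSW) / (MSR + (k - 1) MSW)`
#'   \item two-way absolute agreement, ICC(A,1):
#'     `(MSR - MSE) / (MSR + (k - 1) MSE + k / n (MSC - MSE))`
#'   \item two-way consistency, ICC(C,1): `(MSR - MSE) / (MSR + (k - 1) MSE)`
#' }
#' Pairs with a missing value in either session are dropped
#' (pairwise-complete); at least 3 complete pairs are required. All three
#' forms are returned so any screening choice can be audited; the screening
#' default in this package is absolute agreement.
#'
#' @param session1,session2 numeric measurements, one value per subject.
#' @return List with `icc_1`, `icc_a`, `icc_c`, and `n_used`; coefficients
#'   are `NA` when the total variance is zero.
#' @export
icc_pair <- function(session1, session2) {
  stopifnot(length(session1) == length(session2))
  ok <- is.finite(session1) & is.finite(session2)
  x <- cbind(session1[ok], session2[ok])
  n <- nrow(x)
  if (n < 3L)
    return(list(icc_1 = NA_real_, icc_a = NA_real_, icc_c = NA_real_,
                n_used = n))
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  ssw <- sst - ssr
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  msw <- ssw / (n * (k - 1))
  if (sst <= 0)
    return(list(icc_1 = NA_real_, icc_a = NA_real_, icc_c = NA_real_,
                n_used = n))
  list(icc_1 = (msr - msw) / (msr + (k - 1) * msw),
       icc_a = (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)),
       icc_c = (msr - mse) / (msr + (k - 1) * mse),
       n_used = n)
}

#' Kendall's coefficient of concordance (W) with tie correction
#'
#' Agreement of m rankings of n subjects using midranks for ties:
#' `W = (12 S - 3 m^2 n (n + 1)^2) / (m^2 n (n^2 - 1) - m T)`, with `S` the
#' sum of squared rank sums and `T = sum(t^3 - t)` over tie groups of every
#' ranking. Undefined (`NA`) when every ranking is completely tied.
#'
#' @param x n x m numeric matrix: n subjects ranked by m sessions/raters.
#' @return Kendall's W in `[0, 1]`, or `NA_real_` if undefined.
#' @export
kendall_w <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  stopifnot(n >= 2, m >= 2)
  ranks <- apply(x, 2, rank, ties.method = "average")
  rs <- rowSums(ranks)
  s <- sum(rs^2)
  tie_t <- sum(apply(x, 2, function(col) {
    t <- table(col); sum(t^3 - t)
  }))
  denom <- m^2 * n * (n^2 - 1) - m * tie_t
  if (denom <= 0) return(NA_real_)
  (12 * s - 3 * m^2 * n * (n + 1)^2) / denom
}

#' Reliability table for a two-session feature data set
#'
#' Computes, per quantitative variable, the three single-measure ICC forms
#' and Kendall's W across the two sessions, and applies the screening rule:
#' variables whose screening ICC is below the threshold (or undefined) are
#' rejected as candidate predictors.
#'
#' @param features data frame with columns `subject_id`, `session` (1 or 2)
#'   and one numeric column per variable.
#' @param variables character vector of variable columns; default all
#'   numeric columns except `subject_id`/`session`.
#' @param icc_form which ICC drives screening: `"agreement"` (ICC(A,1),
#'   default), `"consistency"` (ICC(C,1)) or `"oneway"` (ICC(1)).
#' @param threshold screening cutoff, default 0.75: variables with a
#'   screening ICC below it are rejected.
#' @return Data frame with one row per variable: `variable`, `icc_1`,
#'   `icc_a`, `icc_c`, `kcc`, `n_used`, `icc_screen`, `retained`, `reason`.
#' @export
reliability_table <- function(features, variables = NULL,
                              icc_form = c("agreement", "consistency",
                                           "oneway"),
                              threshold = 0.75) {
  icc_form <- match.arg(icc_form)
  stopifnot(all(c("subject_id", "session") %in% names(features)))
  if (is.null(variables)) {
    variables <- setdiff(names(features)[vapply(features, is.numeric,
                                                logical(1))],
                         c("subject_id", "session"))
  }
  s1 <- features[features$session == 1, , drop = FALSE]
  s2 <- features[features$session == 2, , drop = FALSE]
  s2 <- s2[match(s1$subject_id, s2$subject_id), , drop = FALSE]
  if (anyNA(s2$subject_id)) stop("every subject needs both sessions")
  pick <- c(agreement = "icc_a", consistency = "icc_c", oneway = "icc_1")
  rows <- lapply(variables, function(v) {
    ic <- icc_pair(s1[[v]], s2[[v]])
    ok <- is.finite(s1[[v]]) & is.finite(s2[[v]])
    kcc <- if (sum(ok) >= 2) kendall_w(cbind(s1[[v]][ok], s2[[v]][ok]))
           else NA_real_
    screen <- ic[[pick[[icc_form]]]]
    retained <- !is.na(screen) && screen >= threshold
    reason <- if (retained) "" else if (is.na(screen)) "undefined ICC"
              else sprintf("ICC %.3f < %.2f", screen, threshold)
    data.frame(variable = v, icc_1 = ic$icc_1, icc_a = ic$icc_a,
               icc_c = ic$icc_c, kcc = kcc, n_used = ic$n_used,
               icc_screen = screen, retained = retained, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply the ICC screening rule
#'
#' @param rel a [reliability_table()] result.
#' @return Character vector of retained variable names.
#' @export
screen_variables <- function(rel) rel$variable[rel$retained]

#' Reliability of ordinal clinical ratings
#'
#' Per rated ROI: quadratic-weighted kappa and tie-corrected Kendall's W of
#' the two rating sessions.
#'
#' @param ratings data frame with columns `subject_id`, `session`,
#'   `roi_name`, `grade` (0-3).
#' @return Data frame with one row per ROI: `roi_name`, `kappa`, `kcc`, `n`.
#' @export
rating_reliability <- function(ratings) {
  stopifnot(all(c("subject_id", "session", "roi_name", "grade")
                %in% names(ratings)))
  rois <- unique(ratings$roi_name)
  rows <- lapply(rois, function(rn) {
    r <- ratings[ratings$roi_name == rn, ]
    s1 <- r[r$session == 1, ]
    s2 <- r[r$session == 2, ]
    s2 <- s2[match(s1$subject_id, s2$subject_id), ]
    data.frame(roi_name = rn,
               kappa = weighted_kappa(s1$grade, s2$grade),
               kcc = kendall_w(cbind(s1$grade, s2$grade)),
               n = nrow(s1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
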