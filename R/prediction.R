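#' Dichotomize ordinal tendon grades
#'
#' Two binary readings of the 0-3 structural-change grade: `Y1` flags any
#' structural change (grade above 0), `Y3` flags severe change (grade equal
#' to 3).
#'
#' @param grades integer vector of grades in 0-3.
#' @param rule `"Y1"` or `"Y3"`.
#' @return Integer 0/1 vector.
#' @export
dichotomize <- function(grades, rule = c("Y1", "Y3")) {
  rule <- match.arg(rule)
  if (any(!grades %in% 0:3)) stop("grades must be integers in 0..3")
  if (rule == "Y1") as.integer(grades > 0) else as.integer(grades == 3)
}

#' Fit a random-intercept logistic mixed model
#'
#' The single-covariate logistic GLMM
#' `logit P(Y_ij = 1 | x_ij, u_j) = beta0 + beta1 x_ij + u_j`,
#' `u_j ~ N(0, sigma^2)` a per-subject random intercept, fitted by maximum
#' marginal likelihood with `lme4::glmer` (Laplace approximation by
#' default; adaptive Gauss-Hermite via `nagq`). Single-term fixed effects
#' only — the pilot-scale designs this targets cannot support more.
#'
#' A response observed in only one class yields status `"not_created"`
#' (no model is fitted); convergence failures and complete-separation
#' symptoms are returned as a non-converged fit, never silently.
#'
#' @param data data frame with columns `subject_id`, `x`, `y` (0/1).
#' @param nagq integration points: 1 = Laplace (default), more = adaptive
#'   Gauss-Hermite.
#' @return A `glmm_fit`: list with `beta0`, `beta1`, `se_beta1`, `sigma2`,
#'   `loglik`, `converged`, `status` (`"ok"` or `"not_created"`),
#'   `messages`, `n_obs`, `n_subjects`.
#' @export
fit_glmm <- function(data, nagq = 1L) {
  stopifnot(all(c("subject_id", "x", "y") %in% names(data)))
  data <- data[is.finite(data$x), , drop = FALSE]
  if (length(unique(data$y)) < 2L) {
    return(structure(list(beta0 = NA_real_, beta1 = NA_real_,
                          se_beta1 = NA_real_, sigma2 = NA_real_,
                          loglik = NA_real_, converged = FALSE,
                          status = "not_created",
                          messages = "response has a single class",
                          n_obs = nrow(data),
                          n_subjects = length(unique(data$subject_id))),
                     class = "glmm_fit"))
  }
  if (length(unique(data$subject_id)) < 2L) stop("need at least 2 subjects")
  if (stats::var(data$x) == 0) {
    # uninformative covariate: the model collapses to intercept-only
    fit0 <- lme4::glmer(y ~ 1 + (1 | subject_id), data = data,
                        family = binomial)
    vc0 <- lme4::VarCorr(fit0)
    return(structure(list(beta0 = unname(lme4::fixef(fit0)[1]), beta1 = 0,
                          se_beta1 = NA_real_,
                          sigma2 = unname(vc0$subject_id[1, 1]),
                          loglik = as.numeric(stats::logLik(fit0)),
                          converged = TRUE, status = "ok",
                          messages = "constant covariate: intercept-only fit",
                          n_obs = nrow(data),
                          n_subjects = length(unique(data$subject_id))),
                     class = "glmm_fit"))
  }
  msgs <- character(0)
  fit <- tryCatch(
    withCallingHandlers(
      lme4::glmer(y ~ x + (1 | subject_id), data = data, family = binomial,
                  nAGQ = nagq),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      }),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # optimizer blow-ups (e.g. under complete separation) are reported as a
    # flagged failed fit, never raised
    return(structure(list(beta0 = NA_real_, beta1 = NA_real_,
                          se_beta1 = NA_real_, sigma2 = NA_real_,
                          loglik = NA_real_, converged = FALSE,
                          status = "failed",
                          messages = c(msgs, conditionMessage(fit)),
                          n_obs = nrow(data),
                          n_subjects = length(unique(data$subject_id))),
                     class = "glmm_fit"))
  }
  # vcov() can itself emit Hessian diagnostics; keep them with the rest
  beta <- lme4::fixef(fit)
  se <- withCallingHandlers(
    sqrt(diag(as.matrix(stats::vcov(fit)))),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  vc <- lme4::VarCorr(fit)
  separation <- abs(beta[2]) > 50 || se[2] > 1e3
  if (separation) msgs <- c(msgs, "possible complete separation")
  structure(list(beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 se_beta1 = unname(se[2]),
                 sigma2 = unname(vc$subject_id[1, 1]),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = length(msgs) == 0L,
                 status = "ok", messages = msgs,
                 n_obs = nrow(data),
                 n_subjects = length(unique(data$subject_id))),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  if (x$status != "ok") {
    cat("<glmm_fit> model not created:", x$messages, "\n")
  } else {
    cat(sprintf(
      "<glmm_fit> beta0 %.4g, beta1 %.4g (se %.3g), sigma2 %.4g%s\n",
      x$beta0, x$beta1, x$se_beta1, x$sigma2,
      if (x$converged) "" else "  [not converged]"))
  }
  invisible(x)
}

#' Leave-one-subject-out cross-validated predictions
#'
#' For each subject j, the model is refitted on all other subjects and j's
#' observations are predicted with the fixed effects only — the random
#' effect of an unseen subject is its prior mean 0, so
#' `p = plogis(beta0 + beta1 x)`. No information from the held-out subject
#' (covariates or labels) enters the training fold. A training fold that
#' loses one response class entirely falls back to the fold's prevalence as
#' the predicted probability and is flagged.
#'
#' @param data data frame with columns `subject_id`, `x`, `y`.
#' @param nagq forwarded to [fit_glmm()].
#' @return A `cv_prediction`: list with `prob` (one probability per row of
#'   `data`, in row order), `fold` (left-out subject per row), `y`,
#'   `degenerate_folds` (subjects whose training fold was single-class),
#'   `fallback_folds` (folds whose mixed-model fit failed and fell back to
#'   the fixed-effects logistic fit), `status`.
#' @export
lolo_cv <- function(data, nagq = 1L) {
  stopifnot(all(c("subject_id", "x", "y") %in% names(data)))
  subjects <- unique(data$subject_id)
  if (length(subjects) < 3L) stop("need at least 3 subjects for LOLO-CV")
  if (length(unique(data$y)) < 2L) {
    return(structure(list(prob = rep(NA_real_, nrow(data)),
                          fold = data$subject_id, y = data$y,
                          degenerate_folds = character(0),
                          status = "not_created"),
                     class = "cv_prediction"))
  }
  prob <- rep(NA_real_, nrow(data))
  degenerate <- character(0)
  fallback <- character(0)
  for (s in subjects) {
    hold <- data$subject_id == s
    train <- data[!hold, , drop = FALSE]
    if (length(unique(train$y)) < 2L) {
      degenerate <- c(degenerate, as.character(s))
      prob[hold] <- mean(train$y)
      next
    }
    f <- fit_glmm(train, nagq = nagq)
    if (f$status == "ok" && is.finite(f$beta0) && is.finite(f$beta1)) {
      prob[hold] <- stats::plogis(f$beta0 + f$beta1 * data$x[hold])
    } else {
      # mixed-model optimizer failed on this fold (e.g. separation): fall
      # back to the fixed-effects-only logistic fit, flagged
      fallback <- c(fallback, as.character(s))
      g <- suppressWarnings(stats::glm(y ~ x, data = train,
                                       family = binomial))
      prob[hold] <- stats::plogis(stats::coef(g)[1] +
                                    stats::coef(g)[2] * data$x[hold])
    }
  }
  structure(list(prob = prob, fold = data$subject_id, y = data$y,
                 degenerate_folds = degenerate, fallback_folds = fallback,
                 status = "ok"),
            class = "cv_prediction")
}

#' ROC curve and AUC of prediction scores
#'
#' The AUC is the midrank Mann-Whitney concordance: the probability that a
#' random positive scores above a random negative, ties counted 1/2. The
#' curve enumerates all distinct scores as thresholds (predict positive if
#' `score >= t`).
#'
#' @param scores numeric prediction scores (e.g., cross-validated
#'   probabilities).
#' @param labels 0/1 vector, both classes present.
#' @return A `roc_result`: list with `auc`, `thresholds`, `sensitivity`,
#'   `specificity`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & is.finite(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ROC curve")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n0,
                 numeric(1))
  structure(list(auc = auc, thresholds = thr, sensitivity = sens,
                 specificity = spec),
            class = "roc_result")
}

#' Validity analysis of one ROI: per-variable GLMM, LOLO-CV, AUC
#'
#' For one rated ROI and one binary response rule, runs the full validity
#' chain for every candidate variable: random-intercept logistic GLMM on all
#' data (reported coefficients), leave-one-subject-out cross-validation, and
#' the cross-validated AUC. Variables whose response is single-class are
#' reported with status `"not_created"`.
#'
#' @param data data frame with columns `subject_id`, `grade`, and the
#'   candidate variable columns; one row per observation (subject x
#'   session).
#' @param variables character vector of candidate variable names (normally
#'   the ICC-retained ones).
#' @param rule `"Y1"` or `"Y3"`.
#' @param nagq forwarded to [fit_glmm()].
#' @return Data frame, one row per variable: `variable`, `response`,
#'   `beta0`, `beta1`, `se_beta1`, `sigma2`, `converged`, `auc`, `status`,
#'   plus attribute `"cv"` holding the per-variable `cv_prediction`s.
#' @export
validity_analysis <- function(data, variables, rule = c("Y1", "Y3"),
                              nagq = 1L) {
  rule <- match.arg(rule)
  y <- dichotomize(data$grade, rule)
  cvs <- list()
  rows <- lapply(variables, function(v) {
    d <- data.frame(subject_id = data$subject_id, x = data[[v]], y = y)
    d <- d[is.finite(d$x), , drop = FALSE]
    fit <- fit_glmm(d, nagq = nagq)
    if (fit$status != "ok") {
      return(data.frame(variable = v, response = rule, beta0 = NA_real_,
                        beta1 = NA_real_, se_beta1 = NA_real_,
                        sigma2 = NA_real_, converged = FALSE, auc = NA_real_,
                        status = fit$status, stringsAsFactors = FALSE))
    }
    cv <- lolo_cv(d, nagq = nagq)
    roc <- roc_auc(cv$prob, cv$y)
    cvs[[v]] <<- cv
    data.frame(variable = v, response = rule, beta0 = fit$beta0,
               beta1 = fit$beta1, se_beta1 = fit$se_beta1,
               sigma2 = fit$sigma2, converged = fit$converged,
               auc = roc$auc, status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cv") <- cvs
  out
}

#' Rank fitted models and select the best by cross-validated AUC
#'
#' Successful models are ranked by decreasing AUC; ties are broken by the
#' larger Wald ratio `|beta1| / se`, then variable name, so the selection is
#' deterministic. Models that were not created remain listed with their
#' status.
#'
#' @param results a [validity_analysis()] data frame.
#' @return The same data frame ordered by rank, with columns `rank` (NA for
#'   models not created) and `selected` (TRUE on the top model).
#' @export
select_best <- function(results) {
  ok <- results$status == "ok"
  wald <- ifelse(ok & results$se_beta1 > 0,
                 abs(results$beta1) / results$se_beta1, 0)
  ord <- order(!ok, -ifelse(ok, results$auc, -Inf), -wald, results$variable)
  out <- results[ord, , drop = FALSE]
  out$rank <- NA_integer_
  out$rank[out$status == "ok"] <- seq_len(sum(ok))
  out$selected <- FALSE
  if (any(ok)) out$selected[1] <- TRUE
  rownames(out) <- NULL
  out
}
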