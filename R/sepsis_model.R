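# Advanced-sepsis detection models: a univariate variance-explained screen,
# ridge regression on the 0/1 outcome (linear-probability scores; the
# coefficients minimise ||y - b0 - X b||^2 + lambda ||b||^2 with an
# unpenalised intercept and z-scored features), iterated k-fold
# cross-validation with patient-grouped folds, ROC/AUC, thresholding at a
# matched false-positive rate, and one-sample t-tests of metric draws against
# the clinician reference value.

#' Model specification
#'
#' @param name model label (`"A"`, `"B"`, `"C"`, or anything descriptive).
#' @param feature_names feature columns used by the model.
#' @param lambda_grid ridge penalty grid for inner selection (non-negative;
#'   log-spaced by default).
#' @param r2_min univariate screen threshold: minimum fraction of outcome
#'   variation a feature must explain (default 0.04, inclusive).
#' @param k_folds outer folds (default 5).
#' @param n_iterations cross-validation repetitions (default 1000).
#' @param seed master seed; per-iteration seeds are derived from it.
#' @param group_by_patient if TRUE (default) folds are drawn over patients so
#'   no patient contributes to both train and test of a fold.
#' @param target_fpr false-positive rate at which the classification
#'   threshold is matched (the clinician documentation FPR in the intended
#'   use; default 0.25).
#' @param inner_folds folds for the inner lambda selection.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(name = "A", feature_names, lambda_grid = 10^seq(-3, 3, 1),
                       r2_min = 0.04, k_folds = 5L, n_iterations = 1000L,
                       seed = 1L, group_by_patient = TRUE, target_fpr = 0.25,
                       inner_folds = 5L) {
  if (!is.character(feature_names) || length(feature_names) == 0L)
    stop("invalid configuration field 'feature_names': need at least one feature")
  if (length(lambda_grid) == 0L || any(lambda_grid < 0))
    stop("invalid configuration field 'lambda_grid': non-negative values required")
  check_prob(r2_min, "r2_min")
  check_number(k_folds, "k_folds", lower = 2)
  check_number(n_iterations, "n_iterations", lower = 1)
  check_number(seed, "seed", 0, 2^31 - 1)
  check_flag(group_by_patient, "group_by_patient")
  check_prob(target_fpr, "target_fpr")
  check_number(inner_folds, "inner_folds", lower = 2)
  structure(list(name = name, feature_names = feature_names,
                 lambda_grid = lambda_grid, r2_min = r2_min,
                 k_folds = as.integer(k_folds),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), group_by_patient = group_by_patient,
                 target_fpr = target_fpr, inner_folds = as.integer(inner_folds)),
            class = "model_spec")
}

#' Univariate feature screen
#'
#' Selects the features whose squared product-moment correlation with the 0/1
#' outcome is at least `r2_min` (i.e. features explaining at least that
#' fraction of the outcome variation). Constant features are excluded.
#'
#' @param features data frame or matrix of candidate features.
#' @param outcomes 0/1 (or logical) outcome vector.
#' @param r2_min inclusive threshold, default 0.04.
#' @return character vector of selected names with attribute `r2` (named
#'   vector of all computed r-squared values); empty with a warning when every
#'   feature is constant.
#' @export
univariate_screen <- function(features, outcomes, r2_min = 0.04) {
  X <- as.matrix(features)
  y <- as.numeric(outcomes)
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("need at least 2 distinct outcome values")
  r2 <- vapply(colnames(X), function(nm) {
    x <- X[, nm]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])^2
  }, numeric(1))
  sel <- names(r2)[!is.na(r2) & r2 >= r2_min]
  if (length(sel) == 0L)
    warning("no feature passed the variance-explained screen")
  attr(sel, "r2") <- r2
  sel
}

#' Fit a ridge regression model
#'
#' Features are z-scored by their training mean and SD; zero-variance
#' features are dropped (and recorded in the fit). Slope coefficients
#' minimise the penalised least-squares objective with an unpenalised
#' intercept; the fit is computed by QR on the sqrt(lambda)-augmented design,
#' which is numerically stabler than forming the normal equations. Scores
#' from [predict()] are the linear predictor.
#'
#' @param X numeric matrix or data frame of features.
#' @param y numeric (0/1) outcome.
#' @param lambda ridge penalty, `>= 0` (`0` gives ordinary least squares).
#' @return object of class `"ridge_model"` with the standardisation
#'   statistics, intercept, coefficients (standardised scale) and
#'   `lambda_used`.
#' @export
fit_ridge <- function(X, y, lambda) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least 2 rows to fit")
  if (anyNA(X) || anyNA(y)) stop("missing values must be removed before fitting")
  if (!is_number(lambda) || lambda < 0) stop("lambda must be >= 0")
  mu <- colMeans(X)
  sdev <- apply(X, 2L, sd)
  keep <- sdev > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdev[keep], "/")
  yc <- y - mean(y)
  p <- ncol(Xs)
  beta <- if (p == 0L) numeric(0) else {
    Xa <- rbind(Xs, diag(sqrt(lambda), p))
    fit <- stats::lm.fit(Xa, c(yc, numeric(p)))
    fit$coefficients
  }
  structure(list(feature_names = colnames(X)[keep],
                 dropped = colnames(X)[!keep],
                 center = mu[keep], scale = sdev[keep],
                 intercept = mean(y),
                 coefficients = unname(beta),
                 lambda_used = lambda), class = "ridge_model")
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  drop(object$intercept + Xs %*% object$coefficients)
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("Ridge model: %d features, lambda = %g, intercept = %.4f\n",
              length(x$feature_names), x$lambda_used, x$intercept))
  if (length(x$dropped))
    cat("  dropped (zero variance):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

# inner lambda selection: k-fold CV mean squared error over the grid
select_lambda <- function(X, y, grid, inner_folds) {
  if (length(grid) == 1L) return(grid)
  n <- nrow(X)
  kf <- min(inner_folds, n)
  fold <- sample(rep_len(seq_len(kf), n))
  mse <- sapply(grid, function(lam) {
    err <- 0
    for (f in seq_len(kf)) {
      tr <- fold != f
      if (sum(tr) < 2L) next
      fit <- fit_ridge(X[tr, , drop = FALSE], y[tr], lam)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      err <- err + sum((y[!tr] - pred)^2)
    }
    err / n
  })
  grid[which.min(mse)]
}

#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) identity: the probability that a
#' random positive outscores a random negative, with ties counted one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  lab <- as.logical(labels)
  if (anyNA(scores) || anyNA(lab)) stop("scores and labels must be complete")
  n1 <- sum(lab)
  n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)                      # midranks handle ties as 1/2
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification threshold matched to a target false-positive rate
#'
#' Returns the smallest threshold (classification rule: `score >= threshold`)
#' whose achieved FPR does not exceed the target. Candidates are the observed
#' score values; if even the largest negative score must be excluded, a value
#' just above it is returned.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 labels (at least one negative required).
#' @param target_fpr target false-positive rate in \[0, 1\].
#' @return the threshold.
#' @export
threshold_at_fpr <- function(scores, labels, target_fpr) {
  if (!is_number(target_fpr) || target_fpr < 0 || target_fpr > 1)
    stop("target_fpr must lie in [0, 1]")
  lab <- as.logical(labels)
  neg <- scores[!lab]
  if (length(neg) == 0L) stop("need at least one negative to match an FPR")
  for (t in sort(unique(scores)))
    if (mean(neg >= t) <= target_fpr) return(t)
  max(neg) + max(1e-8, diff(range(scores)) * 1e-8)
}

#' Confusion-matrix classification metrics
#'
#' @param predicted logical (or 0/1) predictions.
#' @param labels logical (or 0/1) reference labels; both classes must be
#'   present.
#' @return list with `sensitivity`, `specificity`, `accuracy`, `f1`, `fpr`.
#'   With no predicted positives the F1 score is defined as 0.
#' @export
classification_metrics <- function(predicted, labels) {
  pred <- as.logical(predicted)
  lab <- as.logical(labels)
  if (all(lab) || !any(lab))
    stop("labels must contain both classes")
  tp <- sum(pred & lab)
  fp <- sum(pred & !lab)
  fn <- sum(!pred & lab)
  tn <- sum(!pred & !lab)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(lab),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
       fpr = fp / (fp + tn))
}

#' One-sample t-test of metric draws against the clinician value
#'
#' Two-sided one-sample t-test of the cross-validation metric draws against
#' the clinician scalar. Degenerate draws all equal to the reference return
#' t = 0, p = 1; zero-variance draws away from it are an error.
#'
#' @param draws numeric vector of per-iteration metric values (length >= 2).
#' @param clinician_value reference scalar.
#' @return list with `t_statistic`, `p_value`, `df`, `mean_draws`.
#' @export
compare_metric_draws <- function(draws, clinician_value) {
  n <- length(draws)
  if (n < 2L) stop("need at least 2 draws")
  s <- sd(draws)
  m <- mean(draws)
  if (s == 0) {
    if (isTRUE(all.equal(m, clinician_value)))
      return(list(t_statistic = 0, p_value = 1, df = n - 1, mean_draws = m))
    stop("zero-variance draws: t-test degenerate")
  }
  t_stat <- (m - clinician_value) / (s / sqrt(n))
  list(t_statistic = t_stat, p_value = 2 * pt(-abs(t_stat), df = n - 1),
       df = n - 1, mean_draws = m)
}

# ROC step curve of pooled scores, evaluated on an FPR grid by taking the
# maximal TPR achieved at or below each grid FPR
roc_tpr_at <- function(scores, labels, fpr_grid) {
  lab <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tp <- cumsum(lab[ord])
  fp <- cumsum(!lab[ord])
  keep <- c(s[-1L] != s[-length(s)], TRUE)   # collapse tied scores
  fpr <- c(0, fp[keep] / sum(!lab))
  tpr <- c(0, tp[keep] / sum(lab))
  approx(fpr, tpr, xout = fpr_grid, method = "constant", f = 0,
         ties = max, rule = 2)$y
}

#' Iterated cross-validated evaluation of a ridge model
#'
#' Repeats k-fold cross-validation `n_iterations` times, reshuffling the
#' folds each iteration with a seed derived from the master seed. Within an
#' iteration every record appears in exactly one test fold; with
#' `group_by_patient` folds are drawn over patients. Per outer training fold
#' the ridge penalty is chosen by inner cross-validation over `lambda_grid`,
#' and the classification threshold is matched to `target_fpr` on the
#' training-fold scores (never on test data). AUC per iteration uses the
#' pooled test-fold scores; the mean ROC curve is vertically averaged on a
#' fixed 101-point FPR grid.
#'
#' @param features data frame holding at least `spec$feature_names`.
#' @param outcomes 0/1 or logical outcome; rows with missing outcome or
#'   missing features are dropped.
#' @param spec a [model_spec()].
#' @param patient_ids patient identifier per row (required when
#'   `spec$group_by_patient`).
#' @param return_assignments if TRUE, also return the fold-assignment matrix
#'   (records x iterations) for audit.
#' @return object of class `"cv_result"`: `auc` (per-iteration draws),
#'   `mean_auc`, `sd_auc`, `metrics` (per-iteration sensitivity, specificity,
#'   accuracy, F1, FPR at the matched threshold), `roc` (FPR grid, mean and
#'   SD of TPR), and bookkeeping fields.
#' @export
cross_validate <- function(features, outcomes, spec, patient_ids = NULL,
                           return_assignments = FALSE) {
  X <- as.matrix(as.data.frame(features)[, spec$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(outcomes)
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- nrow(X)
  if (n < spec$k_folds) stop("fewer records than folds")
  if (spec$group_by_patient && is.null(patient_ids))
    stop("patient_ids are required when group_by_patient = TRUE")
  groups <- if (spec$group_by_patient) as.character(patient_ids[ok]) else
    as.character(seq_len(n))
  ug <- unique(groups)
  if (length(ug) < spec$k_folds)
    stop("fewer patients than folds")
  set.seed(spec$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_iterations)
  fpr_grid <- seq(0, 1, length.out = 101L)
  auc <- numeric(spec$n_iterations)
  met <- matrix(NA_real_, spec$n_iterations, 5L,
                dimnames = list(NULL, c("sensitivity", "specificity",
                                        "accuracy", "f1", "fpr")))
  tprs <- matrix(NA_real_, spec$n_iterations, length(fpr_grid))
  assign_mat <- if (return_assignments)
    matrix(NA_integer_, n, spec$n_iterations)
  for (it in seq_len(spec$n_iterations)) {
    set.seed(iter_seeds[it])
    fold_of <- sample(rep_len(seq_len(spec$k_folds), length(ug)))
    names(fold_of) <- ug
    fold <- unname(fold_of[groups])
    scores <- numeric(n)
    pred <- logical(n)
    for (f in seq_len(spec$k_folds)) {
      tr <- fold != f
      if (!any(!tr)) next
      lam <- select_lambda(X[tr, , drop = FALSE], y[tr], spec$lambda_grid,
                           spec$inner_folds)
      fit <- fit_ridge(X[tr, , drop = FALSE], y[tr], lam)
      # pooled scores use the centred linear predictor (intercept removed):
      # the intercept is the fold's training base rate and would otherwise
      # distort the pooled cross-fold ranking without adding any
      # within-fold discrimination
      train_scores <- predict(fit, X[tr, , drop = FALSE]) - fit$intercept
      thr <- threshold_at_fpr(train_scores, y[tr], spec$target_fpr)
      scores[!tr] <- predict(fit, X[!tr, , drop = FALSE]) - fit$intercept
      pred[!tr] <- scores[!tr] >= thr
    }
    auc[it] <- roc_auc(scores, y)
    m <- classification_metrics(pred, y == 1)
    met[it, ] <- c(m$sensitivity, m$specificity, m$accuracy, m$f1, m$fpr)
    tprs[it, ] <- roc_tpr_at(scores, y, fpr_grid)
    if (return_assignments) assign_mat[, it] <- fold
  }
  structure(list(
    name = spec$name, auc = auc, mean_auc = mean(auc), sd_auc = sd(auc),
    metrics = as.data.frame(met),
    roc = data.frame(fpr = fpr_grid, tpr_mean = colMeans(tprs),
                     tpr_sd = apply(tprs, 2L, sd)),
    n_records = n, n_patients = length(ug), spec = spec,
    assignments = assign_mat, groups = groups), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Model %s: %d records, %d patients, %d x %d-fold CV\n",
              x$name, x$n_records, x$n_patients, x$spec$n_iterations,
              x$spec$k_folds))
  cat(sprintf("  AUC %.3f (SD %.3f); at FPR %.2f: sens %.3f, spec %.3f, F1 %.3f\n",
              x$mean_auc, x$sd_auc, x$spec$target_fpr,
              mean(x$metrics$sensitivity), mean(x$metrics$specificity),
              mean(x$metrics$f1)))
  invisible(x)
}

#' Candidate feature sets for models A, B and C
#'
#' Model A uses every candidate feature (wearable-derived plus manual);
#' Model B the features explaining at least `r2_min` of the outcome
#' variation among all of Model A's candidates; Model C the screened features
#' drawn from the wearable device alone.
#'
#' @param features feature data frame from [build_feature_matrix()].
#' @param outcomes 0/1 outcome per row.
#' @param r2_min screen threshold, default 0.04.
#' @return named list of character vectors `A`, `B`, `C`.
#' @export
model_feature_sets <- function(features, outcomes, r2_min = 0.04) {
  all_feats <- intersect(c(wearable_feature_names(), manual_feature_names()),
                         names(features))
  wear <- intersect(wearable_feature_names(), names(features))
  list(A = all_feats,
       B = as.character(univariate_screen(features[all_feats], outcomes, r2_min)),
       C = as.character(univariate_screen(features[wear], outcomes, r2_min)))
}

#' Mean ROC curve plot in the iterated-CV style
#'
#' Mean ROC with +/- 1 SD vertical bars, optionally overlaying a reference
#' operating point (e.g. the clinicians').
#'
#' @param cv a `"cv_result"`.
#' @param reference_point optional `c(fpr, tpr)` to mark.
#' @param ... passed to [plot()].
#' @export
plot_roc <- function(cv, reference_point = NULL, ...) {
  r <- cv$roc
  plot(r$fpr, r$tpr_mean, type = "l", lwd = 2, xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("Model %s (AUC %.2f)", cv$name, cv$mean_auc), ...)
  idx <- seq(1L, nrow(r), by = 5L)
  arrows_ok <- r$tpr_sd[idx] > 0
  suppressWarnings(graphics::arrows(
    r$fpr[idx][arrows_ok], (r$tpr_mean - r$tpr_sd)[idx][arrows_ok],
    r$fpr[idx][arrows_ok], (r$tpr_mean + r$tpr_sd)[idx][arrows_ok],
    angle = 90, code = 3, length = 0.02, col = "grey60"))
  abline(0, 1, lty = 3)
  if (!is.null(reference_point))
    points(reference_point[1L], reference_point[2L], pch = 19, col = "darkorange")
  invisible(cv)
}
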