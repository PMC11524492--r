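# ridge models, screening, CV machinery, ROC/threshold/metrics, t-tests

test_that("the univariate screen is inclusive at the threshold and drops constants", {
  set.seed(20)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  strong <- y + rnorm(n, 0, 0.1)
  noise <- rnorm(n)
  flat <- rep(2, n)
  X <- data.frame(strong = strong, noise = noise, flat = flat)
  sel <- univariate_screen(X, y, 0.04)
  expect_true("strong" %in% sel)
  expect_false("flat" %in% sel)
  r2 <- attr(sel, "r2")
  expect_true(is.na(r2["flat"]))
  # inclusive boundary: threshold set to a feature's exact computed r-squared
  sel_at <- univariate_screen(X["noise"], y, r2_min = unname(r2["noise"]))
  expect_true("noise" %in% sel_at)
  expect_error(univariate_screen(X, rep(1, n)), "distinct outcome")
  expect_warning(univariate_screen(X["flat"], y), "no feature")
})

test_that("an independent noise feature rarely passes the 4% screen", {
  set.seed(21)
  n <- 10000
  y <- rbinom(n, 1, 0.3)
  expect_warning(sel <- univariate_screen(data.frame(noise = rnorm(n)), y, 0.04),
                 "no feature")
  expect_equal(length(sel), 0)
})

test_that("lambda = 0 reproduces least squares and huge lambda shrinks to the mean", {
  set.seed(22)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- rnorm(20)
  fit0 <- fit_ridge(X, y, 0)
  Xs <- scale(X)
  ols <- coef(lm(y ~ Xs))
  expect_equal(fit0$coefficients, unname(ols[-1]), tolerance = 1e-10)
  expect_equal(fit0$intercept, mean(y))

  fit_inf <- fit_ridge(X, y, 1e8)
  expect_true(all(abs(fit_inf$coefficients) < 1e-5))
  expect_equal(unname(predict(fit_inf, X)[1]), mean(y), tolerance = 1e-4)
})

test_that("ridge coefficients match the closed-form normal-equation oracle", {
  set.seed(23)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- rnorm(20)
  fit <- fit_ridge(X, y, 1)
  Xs <- scale(X)
  oracle <- solve(crossprod(Xs) + diag(1, 3), crossprod(Xs, y - mean(y)))
  expect_lt(max(abs(fit$coefficients - drop(oracle))), 1e-8)
})

test_that("coefficient norms shrink monotonically in lambda", {
  set.seed(24)
  X <- matrix(rnorm(150), 30, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(30)
  norms <- vapply(c(0, 0.1, 1, 10, 100, 1000), function(l)
    sqrt(sum(fit_ridge(X, y, l)$coefficients^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("zero-variance features are dropped from the fit and recorded", {
  set.seed(25)
  X <- cbind(x1 = rnorm(20), dead = rep(3, 20))
  y <- rnorm(20)
  fit <- fit_ridge(X, y, 1)
  expect_equal(fit$dropped, "dead")
  expect_equal(length(fit$coefficients), 1)
  expect_equal(length(predict(fit, X)), 20)
})

test_that("AUC equals pairwise concordance with ties counted one half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(0, 0, 1)), 0)
  expect_equal(roc_auc(c(0.9, 0.3, 0.5, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)       # tie
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(26)
  s <- rnorm(50)
  lab <- rbinom(50, 1, 0.5)
  if (sum(lab) %in% c(0, 50)) lab[1] <- 1 - lab[1]
  a <- roc_auc(s, lab)
  expect_equal(roc_auc(exp(s), lab), a)
  expect_equal(roc_auc(s^3 + 5 * s, lab), a)
  expect_equal(roc_auc(rank(s), lab), a)
})

test_that("FPR-matched thresholds achieve the target exactly by enumeration", {
  scores <- c(0.1, 0.2, 0.5, 0.8, 0.9, 0.95)
  labels <- c(0, 0, 0, 0, 1, 1)
  t0 <- threshold_at_fpr(scores, labels, 0)
  expect_gt(t0, 0.8)
  expect_equal(mean(scores[labels == 0] >= t0), 0)

  t1 <- threshold_at_fpr(scores, labels, 1)
  expect_lte(t1, min(scores))

  tq <- threshold_at_fpr(scores, labels, 0.25)
  expect_true(tq > 0.5 && tq <= 0.8)
  expect_equal(sum(scores[labels == 0] >= tq), 1)
  expect_error(threshold_at_fpr(scores, labels, 1.5), "\\[0, 1\\]")
})

test_that("classification metrics follow the confusion-matrix definitions", {
  # TP=3, FP=1, FN=1, TN=3
  pred <- c(rep(TRUE, 4), rep(FALSE, 4))
  lab <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  m <- classification_metrics(pred, lab)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$fpr, 0.25)

  perfect <- classification_metrics(lab, lab)
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "accuracy", "f1")]) == 1))

  none <- classification_metrics(rep(FALSE, 8), lab)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_equal(none$f1, 0)
})

test_that("metric draws are compared with a correct one-sample t-test", {
  same <- compare_metric_draws(rep(0.85, 5), 0.85)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  sym <- compare_metric_draws(c(0.8, 0.9), 0.85)
  expect_equal(sym$t_statistic, 0)

  ex <- compare_metric_draws(c(0.80, 0.82, 0.84), 0.76)
  expect_equal(ex$t_statistic, 3 * sqrt(3), tolerance = 1e-12)
  oracle <- t.test(c(0.80, 0.82, 0.84), mu = 0.76)
  expect_equal(ex$t_statistic, unname(oracle$statistic))
  expect_equal(ex$p_value, oracle$p.value)

  expect_error(compare_metric_draws(rep(0.8, 5), 0.7), "zero-variance")
  expect_error(compare_metric_draws(0.8, 0.7), "at least 2")
})

test_that("cross-validation is deterministic and partitions records correctly", {
  set.seed(27)
  n <- 60
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, 0.4)
  pid <- rep(paste0("P", 1:12), each = 5)
  spec <- model_spec("T", c("a", "b", "c"), n_iterations = 5, seed = 99,
                     k_folds = 4)
  cv1 <- cross_validate(X, y, spec, pid, return_assignments = TRUE)
  cv2 <- cross_validate(X, y, spec, pid)
  expect_identical(cv1$auc, cv2$auc)
  expect_identical(cv1$metrics, cv2$metrics)
  # every record belongs to exactly one test fold per iteration
  expect_true(all(cv1$assignments %in% 1:4))
  expect_false(anyNA(cv1$assignments))
  # patient-grouped: all records of a patient share the fold
  for (it in 1:5) {
    per_pat <- tapply(cv1$assignments[, it], pid, function(v) length(unique(v)))
    expect_true(all(per_pat == 1))
  }
  expect_length(cv1$auc, 5)
  expect_true(all(cv1$auc >= 0 & cv1$auc <= 1))
})

test_that("permuted labels yield chance-level cross-validated AUC", {
  set.seed(28)
  n <- 200
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- sample(rep(c(0, 1), each = n / 2))
  spec <- model_spec("null", c("a", "b"), n_iterations = 10, seed = 5,
                     group_by_patient = FALSE, lambda_grid = c(0.1, 10))
  cv <- cross_validate(X, y, spec)
  expect_gt(mean(cv$auc), 0.40)
  expect_lt(mean(cv$auc), 0.60)
})

test_that("degenerate CV inputs are refused with clear messages", {
  X <- data.frame(a = rnorm(10))
  y <- rbinom(10, 1, 0.5)
  expect_error(cross_validate(X[1:3, , drop = FALSE], y[1:3],
                              model_spec("T", "a", n_iterations = 1)),
               "fewer records")
  expect_error(cross_validate(X, y, model_spec("T", "a", n_iterations = 1)),
               "patient_ids")
  expect_error(cross_validate(X, y, model_spec("T", "a", n_iterations = 1),
                              patient_ids = rep("P1", 10)),
               "fewer patients")
})

test_that("the mean ROC curve is monotone on the FPR grid", {
  set.seed(29)
  n <- 80
  X <- data.frame(a = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  spec <- model_spec("T", "a", n_iterations = 3, seed = 1,
                     group_by_patient = FALSE, lambda_grid = 1)
  cv <- cross_validate(X, y, spec)
  expect_equal(nrow(cv$roc), 101)
  expect_true(all(diff(cv$roc$tpr_mean) >= -1e-12))
  expect_equal(cv$roc$tpr_mean[101], 1)
})
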