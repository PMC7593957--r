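test_that("autoscaling standardizes, handles constants and inverts", {
  X <- cbind(a = c(1, 3), b = c(5, 5))
  pre <- autoscale_fit(X)
  Xs <- autoscale_apply(pre, X)
  expect_equal(unname(Xs[, 1]), c(-1, 1) / sqrt(2))
  expect_equal(unname(Xs[, 2]), c(0, 0))
  expect_equal(pre$scale[["b"]], 1)
  expect_equal(autoscale_invert(pre, Xs), X, tolerance = 1e-10)

  set.seed(1)
  Y <- matrix(rnorm(50), 10, 5)
  preY <- autoscale_fit(Y)
  Ys <- autoscale_apply(preY, Y)
  expect_lt(max(abs(colMeans(Ys))), 1e-10)
  expect_equal(unname(apply(Ys, 2, sd)), rep(1, 5))
})

test_that("PCA diagnostics match brute-force formulas", {
  set.seed(2)
  X <- matrix(rnorm(12), 4, 3)
  m <- pca_fit(X, 2)
  expect_equal(crossprod(m$loadings), diag(2), tolerance = 1e-8)
  expect_true(all(diff(m$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(m$explained_variance_ratio), 1 + 1e-12)

  # Hotelling's T2 equals the Mahalanobis form computed from the scores
  rep <- outlier_screen(m)
  t2_oracle <- mahalanobis(m$scores, rep(0, 2), cov(m$scores))
  expect_equal(rep$t2, t2_oracle, tolerance = 1e-8)

  # data exactly in an A-dimensional subspace: all Q residuals zero
  Tm <- matrix(rnorm(20), 10, 2)
  P <- matrix(rnorm(12), 6, 2)
  m2 <- pca_fit(Tm %*% t(P), 2)
  expect_lt(max(m2$q_residuals), 1e-10)

  # a gross row is flagged against an otherwise tight cluster
  set.seed(3)
  Z <- matrix(rnorm(20 * 8, 100, 1), 20, 8)
  Z[7, ] <- Z[7, ] * 20
  rep2 <- outlier_screen(pca_fit(Z, 2))
  expect_true(rep2$outlier_flags[7])
  expect_identical(rep2$outlier_flags,
                   rep2$t2 > rep2$t2_limit | rep2$q > rep2$q_limit)

  expect_error(pca_fit(X, 5), "between 1 and")
})

test_that("PLS1 at full rank reproduces the least-squares fit", {
  set.seed(4)
  X <- matrix(rnorm(18), 6, 3)
  y <- c(1, 0, 1, 0, 1, 0)
  fit <- pls1_fit(X, y, 3)
  yhat <- pls1_predict(fit, X)
  ols <- lm.fit(cbind(1, X), y)$fitted.values
  expect_equal(yhat, unname(ols), tolerance = 1e-8)

  # first weight vector is proportional to X'y (after preprocessing)
  Xs <- autoscale_apply(fit$preprocessor, X)
  w1 <- crossprod(Xs, y - mean(y))
  w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(abs(sum(w1 * fit$weights[, 1])), 1, tolerance = 1e-10)

  # predictions are a row-wise operation
  p2 <- pls1_predict(fit, X[c(1, 1, 2), ])
  expect_equal(p2[1], p2[2])

  expect_error(pls1_fit(X, rep(1, 6), 2), "degenerate dummy")
})

test_that("a perfectly informative column yields an exact 1-LV model", {
  y <- rep(c(0, 1), 10)
  X <- matrix(y, ncol = 1)
  fit <- pls1_fit(X, y, 1)
  expect_equal(pls1_predict(fit, X), y, tolerance = 1e-10)
  cv <- cross_validate(X, y, max_lv = 1, seed = 1)
  expect_gt(cv$q2[1], 0.99)
  expect_lt(cv$rmsecv[1], 0.01)
})

test_that("cross-validation is seeded, stratified and leak-free", {
  set.seed(6)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- rep(c(0, 1), each = 20)
  cv1 <- cross_validate(X, y, max_lv = 4, seed = 9)
  cv2 <- cross_validate(X, y, max_lv = 4, seed = 9)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$oof_pv, cv2$oof_pv)
  # folds partition the samples and are stratified by class
  expect_equal(sort(unique(cv1$fold_assignment)), 1:10)
  expect_true(all(table(cv1$fold_assignment, y) == 2))

  # Q2 identity: q2 = 1 - n rmsecv^2 / TSS
  expect_equal(cv1$q2, 1 - nrow(X) * cv1$rmsecv^2 / cv1$tss,
               tolerance = 1e-12)

  # no leakage: a fold's model (preprocessing included) is a function of
  # the training rows only, so its out-of-fold predictions for mutated
  # held-out rows equal an outside refit on the same training rows
  mut <- which(cv1$fold_assignment == 1)
  X2 <- X
  X2[mut, ] <- X2[mut, ] * 100
  cv3 <- cross_validate(X2, y, max_lv = 4, seed = 9)
  outside <- pls1_fit(X[-mut, ], y[-mut], 4)
  expect_equal(cv3$oof_pv[mut, 4],
               pls1_predict(outside, X2[mut, ]), tolerance = 1e-10)

  expect_error(cross_validate(X[1:5, ], y[1:5], 2), "fewer samples")
})

test_that("shuffled labels destroy cross-validated predictivity", {
  ds <- small_study(15, 15, 10, seed = 13, n_points = 500)
  y <- as.integer(ds$truths$category == "EVOO")
  y_shuffled <- olivescreen:::with_seed(99, sample(y))
  cv <- cross_validate(ds$matrix$values, y_shuffled, max_lv = 6, seed = 2)
  expect_true(all(cv$q2 < 0.4))
})

test_that("permutation testing separates structure from noise", {
  ds <- small_study(12, 12, 8, seed = 21, n_points = 400)
  y <- as.integer(ds$truths$category == "EVOO")
  pt <- permutation_test(ds$matrix$values, y, n_lv = 3, n_perm = 20,
                         seed = 5)
  expect_true(pt$passes_strict)
  expect_equal(pt$empirical_p, 1 / 21)

  set.seed(7)
  Xn <- matrix(rnorm(30 * 20), 30, 20)
  yn <- rep(c(0, 1), 15)
  ptn <- permutation_test(Xn, yn, n_lv = 2, n_perm = 19, seed = 8)
  expect_gt(ptn$empirical_p, 0.05)

  expect_error(permutation_test(Xn, yn, 2, n_perm = 0), "n_perm")
})

test_that("CV-ANOVA reproduces the F arithmetic and its limits", {
  fake_cv <- function(press, n_lv = 2) {
    structure(list(press = rep(press, n_lv), chosen_lv = n_lv),
              class = "cv_result")
  }
  y <- c(rep(0, 12), rep(1, 11))  # n = 23
  ss_null <- sum((y - mean(y))^2)
  # hand case: ss_null = 10, PRESS = 2, n = 23, 2 LV -> F = 40
  yh <- c(rep(0, 22), sqrt(10 * 529 / 506))  # n = 23, ss_null = 10
  res <- cv_anova(fake_cv(2), yh)
  expect_equal(res$ss_null, 10, tolerance = 1e-12)
  expect_equal(res$f_stat, ((10 - 2) / 2) / (2 / 20), tolerance = 1e-12)
  expect_equal(res$f_stat, 40)
  expect_equal(res$p_value, pf(40, 2, 20, lower.tail = FALSE))

  # PRESS equal to the null SS: no evidence, F = 0, p = 1
  res0 <- cv_anova(fake_cv(ss_null), y)
  expect_equal(res0$f_stat, 0)
  expect_equal(res0$p_value, 1)
  # PRESS -> 0: p -> 0
  res1 <- cv_anova(fake_cv(1e-9), y)
  expect_lt(res1$p_value, 1e-12)

  expect_error(cv_anova(fake_cv(1), c(0, 1, 0)), "degrees of freedom")
})

test_that("PLS-DA models survive a JSON round trip", {
  set.seed(9)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rep(c(0, 1), 15)
  fit <- pls1_fit(X, y, 2, dummy_coding = c(EVOO = 1, `non-EVOO` = 0))
  path <- withr::local_tempfile(fileext = ".json")
  save_plsda_model(fit, path)
  fit2 <- load_plsda_model(path)
  expect_equal(pls1_predict(fit2, X), pls1_predict(fit, X),
               tolerance = 1e-12)
})
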