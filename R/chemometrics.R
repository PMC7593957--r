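# Multivariate core: autoscaling, PCA with Hotelling's T2 / Q-residual
# screening, NIPALS PLS1-DA, leave-10%-out cross-validation, permutation
# testing and CV-ANOVA.

#' Fit an autoscaling preprocessor (unit variance + mean centring)
#'
#' Column means and SDs (n-1 denominator) are learned on the training
#' rows; zero-variance columns are assigned scale 1 so they become exactly
#' zero after centring and stay inert downstream while keeping the column
#' indexing stable against the scan axis.
#'
#' @param X Numeric matrix with >= 2 rows.
#' @return A list of class `autoscaler` with `center`, `scale`,
#'   `fitted_on`.
#' @export
autoscale_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 rows")
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  s[s == 0] <- 1
  structure(list(center = mu, scale = s, fitted_on = nrow(X)),
            class = "autoscaler")
}

#' Apply an autoscaling preprocessor
#'
#' Uses only the training statistics, so held-out rows never leak into
#' the transform.
#'
#' @param pre An [autoscale_fit()] result.
#' @param X Matrix to transform (same column count as the training data).
#' @return The centred and scaled matrix.
#' @export
autoscale_apply <- function(pre, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(pre$center)) stop("column count mismatch")
  sweep(sweep(X, 2L, pre$center, "-"), 2L, pre$scale, "/")
}

#' Invert an autoscaling transform
#'
#' @inheritParams autoscale_apply
#' @return The matrix on the original scale.
#' @export
autoscale_invert <- function(pre, X) {
  sweep(sweep(as.matrix(X), 2L, pre$scale, "*"), 2L, pre$center, "+")
}

#' Fit a PCA by SVD of the autoscaled matrix
#'
#' @param X Numeric matrix (or [fingerprint_matrix()]).
#' @param A Number of components, `A <= min(n - 1, p)`.
#' @return A list of class `pca_model`: `loadings` (p x A, orthonormal),
#'   `scores` (n x A), `explained_variance_ratio`, `A`, `eigenvalues`
#'   (all min(n-1, p) of them), `q_residuals` (per training row),
#'   `preprocessor`, `n`.
#' @export
pca_fit <- function(X, A) {
  if (inherits(X, "fingerprint_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X); A <- as.integer(A)
  if (A < 1L || A > min(n - 1L, p))
    stop("A must be between 1 and min(n - 1, p)")
  pre <- autoscale_fit(X)
  Xs <- autoscale_apply(pre, X)
  sv <- svd(Xs)
  r <- min(n - 1L, p)
  d2 <- sv$d[seq_len(r)]^2
  scores <- sv$u[, seq_len(A), drop = FALSE] %*%
    diag(sv$d[seq_len(A)], A, A)
  q <- rowSums(Xs^2) - rowSums(scores^2)
  q[q < 0] <- 0
  structure(list(loadings = sv$v[, seq_len(A), drop = FALSE],
                 scores = scores,
                 explained_variance_ratio = d2[seq_len(A)] / sum(d2),
                 A = A, eigenvalues = d2 / (n - 1L), q_residuals = q,
                 preprocessor = pre, n = n),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> A = %d, explained variance %.1f%%\n", x$A,
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

# Jackson-Mudholkar upper control limit for Q residuals.
q_limit_jm <- function(lambda_residual, confidence) {
  th1 <- sum(lambda_residual)
  if (th1 < 1e-12) return(Inf)  # no residual subspace: nothing can deviate
  th2 <- sum(lambda_residual^2)
  th3 <- sum(lambda_residual^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
  ca <- qnorm(confidence)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
           1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Screen PCA training samples for outliers
#'
#' Hotelling's T2 (within-model distance) with its F-based limit
#' `A (n-1)(n+1) / (n (n-A)) * F(A, n-A)` and Q residuals (squared
#' distance to the model plane) with the Jackson-Mudholkar limit; a sample
#' is flagged when either statistic exceeds its limit.
#'
#' @param model A [pca_fit()] model.
#' @param confidence Confidence level (default 0.95).
#' @return A list of class `outlier_report` with `t2`, `t2_limit`, `q`,
#'   `q_limit`, `outlier_flags`.
#' @export
outlier_screen <- function(model, confidence = 0.95) {
  stopifnot(inherits(model, "pca_model"))
  n <- model$n; A <- model$A
  if (n <= A) stop("need n > A for the T2 limit")
  vt <- apply(model$scores, 2L, var)
  t2 <- rowSums(sweep(model$scores^2, 2L, vt, "/"))
  t2_lim <- A * (n - 1) * (n + 1) / (n * (n - A)) *
    qf(confidence, A, n - A)
  lam_res <- model$eigenvalues[-seq_len(A)]
  q_lim <- q_limit_jm(lam_res, confidence)
  structure(list(t2 = t2, t2_limit = t2_lim, q = model$q_residuals,
                 q_limit = q_lim,
                 outlier_flags = t2 > t2_lim | model$q_residuals > q_lim),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> T2 limit %.3g, Q limit %.3g, %d outlier(s)\n",
    x$t2_limit, x$q_limit, sum(x$outlier_flags)))
  invisible(x)
}

#' Fit a binary PLS1-DA model (NIPALS)
#'
#' PLS1 regression of a 0/1 class dummy on the autoscaled fingerprint:
#' per latent variable, `w = X'y / ||X'y||`, `t = X w`,
#' `p = X't / (t't)`, `q = y't / (t't)`, then deflation
#' `X <- X - t p'`, `y <- y - t q`. Regression coefficients are
#' accumulated as `b_A = W (P'W)^(-1) q`, one column per LV count, so the
#' model predicts at any number of components up to `n_lv`.
#'
#' @param X Training matrix (raw intensities; autoscaling is fitted
#'   internally).
#' @param y_dummy 0/1 dummy vector (both classes present).
#' @param n_lv Number of latent variables (>= 1).
#' @param dummy_coding Optional named map, e.g. `c(EVOO = 1, other = 0)`,
#'   stored for provenance.
#' @param sample_ids Optional training sample ids, stored for provenance.
#' @return A list of class `plsda_model`: `weights` W, `loadings` P,
#'   `scores` T, `y_loadings` q, `coefficients` (p x n_lv), `n_lv`,
#'   `preprocessor`, `y_mean`, `dummy_coding`, `sample_ids`.
#' @export
pls1_fit <- function(X, y_dummy, n_lv, dummy_coding = NULL,
                     sample_ids = NULL) {
  if (inherits(X, "fingerprint_matrix")) X <- X$values
  X <- as.matrix(X)
  y <- as.numeric(y_dummy)
  if (length(y) != nrow(X)) stop("y length must match rows of X")
  if (length(unique(y)) < 2L) stop("degenerate dummy: y has a single class")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L) stop("n_lv must be >= 1")
  pre <- autoscale_fit(X)
  Xd <- autoscale_apply(pre, X)
  y_mean <- mean(y)
  yd <- y - y_mean
  p <- ncol(Xd)
  W <- P <- base::matrix(0, p, n_lv)
  Tm <- base::matrix(0, nrow(Xd), n_lv)
  qv <- numeric(n_lv)
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # X fully deflated; no further LVs available
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pa <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pa)
    yd <- yd - t * qa
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t; qv[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) stop("no PLS component could be extracted")
  if (a_used < n_lv) {
    warning("X rank exhausted after ", a_used, " latent variables")
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    qv <- qv[seq_len(a_used)]
    n_lv <- a_used
  }
  B <- base::matrix(0, p, n_lv)
  for (a in seq_len(n_lv)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(Pa, Wa), qv[seq_len(a)])
  }
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = qv,
                 coefficients = B, n_lv = n_lv, preprocessor = pre,
                 y_mean = y_mean, dummy_coding = dummy_coding,
                 sample_ids = sample_ids),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d LV, %d variables%s\n", x$n_lv,
              nrow(x$coefficients),
              if (!is.null(x$dummy_coding))
                paste0(" (", paste(names(x$dummy_coding), "=",
                                   x$dummy_coding, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Predict class dummy values from a PLS1-DA model
#'
#' @param model A [pls1_fit()] model.
#' @param X_new New rows on the training scan grid.
#' @param n_lv Number of latent variables to use (default: all fitted).
#' @return Numeric predicted values (unbounded, nominally around 0/1).
#' @export
pls1_predict <- function(model, X_new, n_lv = model$n_lv) {
  if (inherits(X_new, "fingerprint_matrix")) X_new <- X_new$values
  X_new <- as.matrix(X_new)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > model$n_lv) stop("invalid n_lv")
  Xs <- autoscale_apply(model$preprocessor, X_new)
  as.numeric(Xs %*% model$coefficients[, n_lv]) + model$y_mean
}

# Seeded stratified fold assignment: within each class, shuffled indices
# are dealt round-robin across folds.
assign_folds <- function(y, n_folds, stratified, seed) {
  n <- length(y)
  if (n < n_folds) stop("fewer samples than folds")
  with_seed(seed, {
    fold <- integer(n)
    if (stratified && all(table(y) >= n_folds)) {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      if (stratified)
        warning("a class has fewer members than folds; ",
                "stratification relaxed")
      fold[sample(n)] <- rep_len(seq_len(n_folds), n)
    }
    fold
  })
}

#' Leave-10%-out cross-validation of a PLS1-DA model
#'
#' Stratified seeded folds (default 10, i.e. leave 10% out). For each
#' fold, both the autoscaling and the PLS model are refit on the
#' remaining rows, and out-of-fold predicted values are recorded for
#' every LV count up to `max_lv`. Reports PRESS, `RMSEcv =
#' sqrt(PRESS/n)` and `Q2 = 1 - PRESS/TSS` per LV (TSS about the mean of
#' y), and picks `chosen_lv` at the minimum RMSEcv, ties resolved
#' towards fewer LVs.
#'
#' @param X Training matrix (raw intensities).
#' @param y_dummy 0/1 dummy vector.
#' @param max_lv Largest LV count to evaluate (default 10).
#' @param n_folds Number of CV folds (default 10).
#' @param stratified Stratify folds by class?
#' @param seed Integer seed for the fold assignment.
#' @return A list of class `cv_result`: `fold_assignment`, `oof_pv`
#'   (n x max_lv), `press`, `rmsecv`, `q2` per LV, `chosen_lv`, `tss`,
#'   `seed`.
#' @export
cross_validate <- function(X, y_dummy, max_lv = 10, n_folds = 10,
                           stratified = TRUE, seed = 1L) {
  if (inherits(X, "fingerprint_matrix")) X <- X$values
  X <- as.matrix(X)
  y <- as.numeric(y_dummy)
  n <- nrow(X)
  if (length(y) != n) stop("y length must match rows of X")
  fold <- assign_folds(y, n_folds, stratified, seed)
  max_fold_size <- max(tabulate(fold, n_folds))
  max_lv <- min(as.integer(max_lv), n - max_fold_size - 1L, ncol(X))
  if (max_lv < 1L) stop("too few samples for cross-validation")
  oof <- base::matrix(NA_real_, n, max_lv)
  for (f in seq_len(n_folds)) {
    test <- which(fold == f)
    if (length(test) == 0L) next
    train <- which(fold != f)
    fit <- pls1_fit(X[train, , drop = FALSE], y[train], max_lv)
    for (a in seq_len(max_lv))
      oof[test, a] <- pls1_predict(fit, X[test, , drop = FALSE],
                                   min(a, fit$n_lv))
  }
  press <- colSums((oof - y)^2)
  tss <- sum((y - mean(y))^2)
  rmsecv <- sqrt(press / n)
  q2 <- 1 - press / tss
  structure(list(fold_assignment = fold, oof_pv = oof, press = press,
                 rmsecv = rmsecv, q2 = q2,
                 chosen_lv = which.min(rmsecv), tss = tss, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> chosen %d LV: Q2 = %.3f, RMSEcv = %.3f\n",
              x$chosen_lv, x$q2[x$chosen_lv], x$rmsecv[x$chosen_lv]))
  invisible(x)
}

# R2 of the full-data fit at n_lv latent variables.
fit_r2 <- function(X, y, n_lv) {
  fit <- pls1_fit(X, y, n_lv)
  yhat <- pls1_predict(fit, X, fit$n_lv)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Permutation test of a PLS1-DA model
#'
#' The class dummy is permuted `n_perm` times (seeded); the full
#' cross-validation is rerun on each permutation. Reports the permuted
#' Q2 and R2 distributions, the originals, the empirical p-value
#' `(1 + #[permuted Q2 >= original Q2]) / (n_perm + 1)`, and the strict
#' flag `original Q2 > max(permuted Q2)`.
#'
#' @inheritParams cross_validate
#' @param n_lv LV count at which the models are compared.
#' @param n_perm Number of permutations (default 20).
#' @return A list of class `permutation_result`.
#' @export
permutation_test <- function(X, y_dummy, n_lv, n_perm = 20, n_folds = 10,
                             seed = 1L) {
  if (inherits(X, "fingerprint_matrix")) X <- X$values
  X <- as.matrix(X)
  y <- as.numeric(y_dummy)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  cv0 <- cross_validate(X, y, max_lv = n_lv, n_folds = n_folds,
                        seed = seed)
  a <- min(n_lv, length(cv0$q2))
  q2_orig <- cv0$q2[a]
  r2_orig <- fit_r2(X, y, a)
  perms <- with_seed(seed + 1L,
                     replicate(n_perm, sample(y), simplify = FALSE))
  q2_perm <- numeric(n_perm)
  r2_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    yp <- perms[[i]]
    cvp <- cross_validate(X, yp, max_lv = a, n_folds = n_folds,
                          seed = seed)
    q2_perm[i] <- cvp$q2[min(a, length(cvp$q2))]
    r2_perm[i] <- fit_r2(X, yp, a)
  }
  structure(list(n_perm = n_perm, permuted_q2 = q2_perm,
                 permuted_r2 = r2_perm, original_q2 = q2_orig,
                 original_r2 = r2_orig,
                 empirical_p = (1 + sum(q2_perm >= q2_orig)) / (n_perm + 1),
                 passes_strict = q2_orig > max(q2_perm)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> Q2 %.3f vs permuted max %.3f (p = %.3f, %s)\n",
    x$original_q2, max(x$permuted_q2), x$empirical_p,
    ifelse(x$passes_strict, "pass", "FAIL")))
  invisible(x)
}

#' ANOVA on the cross-validation residuals (CV-ANOVA)
#'
#' Compares the predictive residuals against the null model that predicts
#' the mean: `F = ((SS_null - PRESS)/df1) / (PRESS/df2)` with
#' `df1 = chosen_lv` and `df2 = n - chosen_lv - 1`; the p-value is the
#' upper tail of the F distribution. A PRESS above SS_null clamps F to 0
#' with p = 1.
#'
#' @param cv A [cross_validate()] result.
#' @param y_dummy The dummy vector the CV was run on.
#' @param n_lv LV count (default the CV-chosen one).
#' @return A list of class `cv_anova_result` with `ss_null`, `ss_model`,
#'   `f_stat`, `df1`, `df2`, `p_value`.
#' @export
cv_anova <- function(cv, y_dummy, n_lv = cv$chosen_lv) {
  y <- as.numeric(y_dummy)
  n <- length(y)
  a <- as.integer(n_lv)
  df2 <- n - a - 1L
  if (df2 <= 0L) stop("non-positive residual degrees of freedom")
  ss_null <- sum((y - mean(y))^2)
  ss_model <- cv$press[min(a, length(cv$press))]
  num <- (ss_null - ss_model) / a
  f <- max(0, num / (ss_model / df2))
  p <- if (f == 0) 1 else pf(f, a, df2, lower.tail = FALSE)
  structure(list(ss_null = ss_null, ss_model = ss_model, f_stat = f,
                 df1 = a, df2 = df2, p_value = p),
            class = "cv_anova_result")
}

#' @export
print.cv_anova_result <- function(x, ...) {
  cat(sprintf("<cv_anova_result> F(%d, %d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}

#' Serialize a PLS1-DA model to a JSON bundle
#'
#' Writes coefficients, preprocessor statistics, dummy coding and
#' provenance as plain JSON, so a screening model can be reloaded
#' bit-for-bit.
#'
#' @param model A [pls1_fit()] model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_plsda_model <- function(model, path) {
  jsonlite::write_json(
    list(n_lv = model$n_lv,
         coefficients = model$coefficients[, model$n_lv],
         center = model$preprocessor$center,
         scale = model$preprocessor$scale,
         y_mean = model$y_mean,
         dummy_coding = as.list(model$dummy_coding),
         sample_ids = model$sample_ids),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized PLS1-DA model
#'
#' Restores a predict-capable model from [save_plsda_model()] output (the
#' NIPALS internals are not round-tripped, only what prediction needs).
#'
#' @param path JSON path written by [save_plsda_model()].
#' @return A `plsda_model` restricted to its prediction fields.
#' @export
load_plsda_model <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  pre <- structure(list(center = b$center, scale = b$scale,
                        fitted_on = NA_integer_),
                   class = "autoscaler")
  structure(list(coefficients = base::matrix(b$coefficients, ncol = 1L),
                 n_lv = 1L, preprocessor = pre, y_mean = b$y_mean,
                 dummy_coding = unlist(b$dummy_coding),
                 sample_ids = b$sample_ids),
            class = "plsda_model")
}
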