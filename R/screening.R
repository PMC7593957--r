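# ROC-derived uncertainty ranges and the two-step hierarchical
# EVOO -> (VOO vs LOO) screening cascade with a reject-to-panel outcome.

#' ROC curve from cross-validated predicted values
#'
#' Candidate cutoffs are all distinct predicted values plus sentinels
#' below the minimum and above the maximum. At a cutoff c, sensitivity is
#' the fraction of positives with PV >= c and specificity the fraction of
#' negatives with PV < c.
#'
#' @param oof_pv Out-of-fold predicted values.
#' @param labels Binary labels (0/1 or logical), 1 = positive.
#' @param positive_label Name of the positive class (stored).
#' @return A data frame of class `roc_curve` with columns `cutoff`,
#'   `sensitivity`, `specificity`; attribute `positive_label`.
#' @export
roc_from_cv <- function(oof_pv, labels, positive_label = "positive") {
  pv <- as.numeric(oof_pv)
  lab <- as.integer(labels)
  if (length(pv) != length(lab)) stop("pv and labels length mismatch")
  if (length(unique(lab)) < 2L) stop("both classes must be present")
  pos <- pv[lab == 1L]
  neg <- pv[lab == 0L]
  cutoffs <- c(min(pv) - 1, sort(unique(pv)), max(pv) + 1)
  sens <- vapply(cutoffs, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(cutoffs, function(c) mean(neg < c), numeric(1))
  out <- data.frame(cutoff = cutoffs, sensitivity = sens,
                    specificity = spec)
  attr(out, "positive_label") <- positive_label
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' ROC-derived uncertainty range
#'
#' The lower threshold is the smallest predicted value among true
#' positives (sensitivity = 1 for any cutoff at or below it) and the
#' upper threshold the largest among true negatives (specificity = 1
#' above it). When the classes separate perfectly the range is empty
#' (lower > upper) and collapses to a single midpoint threshold.
#'
#' @inheritParams roc_from_cv
#' @return A list of class `uncertainty_range` with `lower`, `upper`,
#'   `empty` and `single_threshold` (midpoint, only when empty).
#' @export
uncertainty_range <- function(oof_pv, labels, positive_label = "positive") {
  pv <- as.numeric(oof_pv)
  lab <- as.integer(labels)
  if (length(unique(lab)) < 2L) stop("both classes must be present")
  lower <- min(pv[lab == 1L])
  upper <- max(pv[lab == 0L])
  empty <- lower > upper
  structure(list(lower = lower, upper = upper, empty = empty,
                 single_threshold = if (empty) (lower + upper) / 2
                                    else NA_real_,
                 positive_label = positive_label),
            class = "uncertainty_range")
}

#' @export
print.uncertainty_range <- function(x, ...) {
  if (x$empty)
    cat(sprintf(
      "<uncertainty_range> empty; single threshold %.3f (positive: %s)\n",
      x$single_threshold, x$positive_label))
  else
    cat(sprintf("<uncertainty_range> [%.3f, %.3f] (positive: %s)\n",
                x$lower, x$upper, x$positive_label))
  invisible(x)
}

#' Decide a binary outcome from a predicted value and a range
#'
#' PV above the upper threshold: positive; below the lower: negative;
#' inside the closed interval: uncertain (boundary values defer to the
#' panel). An empty range uses its single midpoint threshold, positive at
#' or above it.
#'
#' @param pv Predicted value(s).
#' @param range An [uncertainty_range()].
#' @return Character vector over `pv` with values `"positive"`,
#'   `"negative"`, `"uncertain"`.
#' @export
decide_binary <- function(pv, range) {
  stopifnot(inherits(range, "uncertainty_range"))
  if (range$empty) {
    ifelse(pv >= range$single_threshold, "positive", "negative")
  } else {
    ifelse(pv > range$upper, "positive",
           ifelse(pv < range$lower, "negative", "uncertain"))
  }
}

fit_one_stage <- function(X, y, coding, ids, config) {
  cv <- cross_validate(X, y, max_lv = config$max_lv,
                       n_folds = config$n_folds, seed = config$seed)
  lv <- cv$chosen_lv
  model <- pls1_fit(X, y, lv, dummy_coding = coding, sample_ids = ids)
  range <- uncertainty_range(cv$oof_pv[, lv], y,
                             positive_label = names(coding)[coding == 1])
  anova <- cv_anova(cv, y)
  perm <- if (config$n_perm > 0)
    permutation_test(X, y, lv, n_perm = config$n_perm,
                     n_folds = config$n_folds, seed = config$seed)
  else NULL
  diag <- list(q2 = cv$q2[lv], rmsecv = cv$rmsecv[lv], chosen_lv = lv,
               anova_p = anova$p_value,
               perm_p = if (!is.null(perm)) perm$empirical_p else NA_real_,
               perm_strict = if (!is.null(perm)) perm$passes_strict else NA,
               flagged = cv$q2[lv] <= 0.4 || anova$p_value >= 0.05)
  # training-set guarantee: outside the band, the out-of-fold decision
  # must be correct for every training sample
  dec <- decide_binary(cv$oof_pv[, lv], range)
  ok <- (dec == "uncertain") | (dec == "positive" & y == 1) |
    (dec == "negative" & y == 0)
  stopifnot(all(ok))
  list(model = model, range = range, cv = cv, anova = anova, perm = perm,
       diagnostics = diag)
}

#' Fit the two-step hierarchical screening model
#'
#' Model 1 is a PLS1-DA of EVOO (dummy 1) against non-EVOO on all
#' training rows; model 2 is an independent PLS1-DA of LOO (dummy 1)
#' against VOO fitted, with its own autoscaling, on the true non-EVOO
#' training subset. Each model's uncertainty range comes from its own
#' out-of-fold predicted values; cross-validation, CV-ANOVA and
#' permutation diagnostics are stored, and a model with Q2 <= 0.4 or a
#' CV-ANOVA p >= 0.05 is flagged (not rejected).
#'
#' @param X Training fingerprint matrix (aligned; raw intensities) or
#'   [fingerprint_matrix()].
#' @param categories Character/factor vector of `"EVOO"`, `"VOO"`,
#'   `"LOO"` (all three present).
#' @param sample_ids Training sample ids (defaults to matrix rownames).
#' @param config List: `max_lv` (default 10), `n_folds` (10), `seed` (1),
#'   `n_perm` (20; 0 skips the permutation test).
#' @return A list of class `screening_model` with `model1`, `range1`,
#'   `model2`, `range2`, per-stage `cv`/`diagnostics`, and provenance.
#' @export
fit_screening_model <- function(X, categories, sample_ids = NULL,
                                config = list()) {
  if (inherits(X, "fingerprint_matrix")) {
    sample_ids <- sample_ids %||% X$sample_ids
    X <- X$values
  }
  X <- as.matrix(X)
  categories <- as.character(categories)
  sample_ids <- sample_ids %||% rownames(X) %||%
    paste0("row", seq_len(nrow(X)))
  if (!all(c("EVOO", "VOO", "LOO") %in% categories))
    stop("all three categories must be present in training")
  cfg <- utils::modifyList(
    list(max_lv = 10L, n_folds = 10L, seed = 1L, n_perm = 20L), config)
  y1 <- as.integer(categories == "EVOO")
  s1 <- fit_one_stage(X, y1, c(EVOO = 1, `non-EVOO` = 0), sample_ids, cfg)
  sub <- which(categories != "EVOO")
  y2 <- as.integer(categories[sub] == "LOO")
  s2 <- fit_one_stage(X[sub, , drop = FALSE], y2, c(LOO = 1, VOO = 0),
                      sample_ids[sub], cfg)
  structure(list(model1 = s1$model, range1 = s1$range, cv1 = s1$cv,
                 diagnostics1 = s1$diagnostics,
                 model2 = s2$model, range2 = s2$range, cv2 = s2$cv,
                 diagnostics2 = s2$diagnostics,
                 training_ids = sample_ids, config = cfg,
                 n_variables = ncol(X)),
            class = "screening_model")
}

#' @export
print.screening_model <- function(x, ...) {
  cat(sprintf(
    "<screening_model> %d training samples, %d variables\n",
    length(x$training_ids), x$n_variables))
  cat(sprintf("  model 1 (EVOO vs non-EVOO): %d LV, Q2 %.3f%s\n",
              x$diagnostics1$chosen_lv, x$diagnostics1$q2,
              if (x$diagnostics1$flagged) " [FLAGGED]" else ""))
  print(x$range1)
  cat(sprintf("  model 2 (VOO vs LOO): %d LV, Q2 %.3f%s\n",
              x$diagnostics2$chosen_lv, x$diagnostics2$q2,
              if (x$diagnostics2$flagged) " [FLAGGED]" else ""))
  print(x$range2)
  invisible(x)
}

#' Screen samples through the hierarchical cascade
#'
#' Per sample: model 1's predicted value classifies it as EVOO (above the
#' upper threshold), uncertain (inside the band; deferred to the panel,
#' model 2 is not consulted) or non-EVOO, in which case model 2's
#' predicted value yields LOO, VOO or uncertain.
#'
#' @param model A [fit_screening_model()] result.
#' @param X New samples on the training scan grid, or a
#'   [fingerprint_matrix()].
#' @param sample_ids Sample ids (defaults to rownames).
#' @return A data frame with columns `sample_id`, `pv1`, `pv2` (`NA` when
#'   model 2 was not consulted), `outcome` (`EVOO`, `VOO`, `LOO`,
#'   `UNCERTAIN`) and `deferred_at` (`model1`, `model2`, `none`).
#' @export
screen <- function(model, X, sample_ids = NULL) {
  stopifnot(inherits(model, "screening_model"))
  if (inherits(X, "fingerprint_matrix")) {
    sample_ids <- sample_ids %||% X$sample_ids
    X <- X$values
  }
  X <- as.matrix(X)
  if (ncol(X) != model$n_variables)
    stop("scan grid mismatch: model expects ", model$n_variables,
         " variables")
  sample_ids <- sample_ids %||% rownames(X) %||%
    paste0("row", seq_len(nrow(X)))
  pv1 <- pls1_predict(model$model1, X)
  d1 <- decide_binary(pv1, model$range1)
  pv2 <- rep(NA_real_, nrow(X))
  outcome <- character(nrow(X))
  deferred <- rep("none", nrow(X))
  outcome[d1 == "positive"] <- "EVOO"
  outcome[d1 == "uncertain"] <- "UNCERTAIN"
  deferred[d1 == "uncertain"] <- "model1"
  neg <- which(d1 == "negative")
  if (length(neg) > 0) {
    pv2[neg] <- pls1_predict(model$model2, X[neg, , drop = FALSE])
    d2 <- decide_binary(pv2[neg], model$range2)
    outcome[neg[d2 == "positive"]] <- "LOO"
    outcome[neg[d2 == "negative"]] <- "VOO"
    outcome[neg[d2 == "uncertain"]] <- "UNCERTAIN"
    deferred[neg[d2 == "uncertain"]] <- "model2"
  }
  data.frame(sample_id = sample_ids, pv1 = pv1, pv2 = pv2,
             outcome = outcome, deferred_at = deferred)
}

#' Write screening decisions to TSV
#'
#' @param decisions A [screen()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screening_tsv <- function(decisions, path) {
  write.table(decisions, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
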