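test_that("ROC counting matches a brute-force tally", {
  pv <- c(0.9, 0.1)
  roc <- roc_from_cv(pv, c(1, 0))
  at <- function(roc, c) roc[which.min(abs(roc$cutoff - c)), ]
  expect_equal(at(roc, 0.9)$sensitivity, 1)
  expect_equal(at(roc, 0.9)$specificity, 1)

  pv2 <- c(0.6, 0.7, 0.9, 0.2, 0.5, 0.65)
  lab2 <- c(1, 1, 1, 0, 0, 0)
  roc2 <- roc_from_cv(pv2, lab2)
  row <- roc2[roc2$cutoff == 0.65, ]
  # brute force at cutoff 0.65: positives >= 0.65 are {0.7, 0.9};
  # negatives < 0.65 are {0.2, 0.5}
  expect_equal(row$sensitivity, 2 / 3)
  expect_equal(row$specificity, 2 / 3)
  # monotone by construction: sensitivity falls, specificity rises
  expect_true(all(diff(roc2$sensitivity) <= 0))
  expect_true(all(diff(roc2$specificity) >= 0))
  # sentinels span the degenerate ends
  expect_equal(roc2$sensitivity[1], 1)
  expect_equal(roc2$specificity[1], 0)
  expect_equal(roc2$sensitivity[nrow(roc2)], 0)
  expect_equal(roc2$specificity[nrow(roc2)], 1)

  expect_error(roc_from_cv(pv2, rep(1, 6)), "both classes")
})

test_that("uncertainty ranges match an exhaustive cutoff scan", {
  # worked example: overlap region [0.6, 0.65]
  ur <- uncertainty_range(c(0.6, 0.7, 0.9, 0.2, 0.5, 0.65),
                          c(1, 1, 1, 0, 0, 0))
  expect_equal(ur$lower, 0.6)
  expect_equal(ur$upper, 0.65)
  expect_false(ur$empty)

  # perfect separation collapses to the midpoint threshold
  ur2 <- uncertainty_range(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_true(ur2$empty)
  expect_equal(ur2$single_threshold, 0.5)

  # property: on random PV sets, lower/upper equal the extreme cutoffs
  # at which sensitivity / specificity are still 1 (exhaustive scan)
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:20, 1)
    pv <- round(runif(n), 2)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) lab[1:2] <- c(0, 1)
    ur <- uncertainty_range(pv, lab)
    cand <- sort(unique(pv))
    sens1 <- cand[vapply(cand, function(c) all(pv[lab == 1] >= c) ||
                           mean(pv[lab == 1] >= c) == 1, logical(1))]
    spec1 <- cand[vapply(cand, function(c) mean(pv[lab == 0] <= c) == 1,
                         logical(1))]
    expect_equal(ur$lower, max(sens1))
    expect_equal(ur$upper, min(spec1))
    expect_identical(ur$empty, ur$lower > ur$upper)
    # every CV positive at or above lower, every negative at or below upper
    expect_true(all(pv[lab == 1] >= ur$lower))
    expect_true(all(pv[lab == 0] <= ur$upper))
  }
})

test_that("binary decisions honour the closed uncertainty interval", {
  ur <- structure(list(lower = 0.354, upper = 0.752, empty = FALSE,
                       single_threshold = NA_real_,
                       positive_label = "EVOO"),
                  class = "uncertainty_range")
  expect_equal(decide_binary(0.80, ur), "positive")
  expect_equal(decide_binary(0.354, ur), "uncertain")
  expect_equal(decide_binary(0.752, ur), "uncertain")
  expect_equal(decide_binary(0.5, ur), "uncertain")
  expect_equal(decide_binary(0.353, ur), "negative")
  expect_equal(decide_binary(c(0.1, 0.5, 0.9), ur),
               c("negative", "uncertain", "positive"))

  ur_empty <- structure(list(lower = 0.6, upper = 0.3, empty = TRUE,
                             single_threshold = 0.48,
                             positive_label = "EVOO"),
                        class = "uncertainty_range")
  expect_equal(decide_binary(0.48, ur_empty), "positive")
  expect_equal(decide_binary(0.4799, ur_empty), "negative")
})

test_that("widening a range only moves samples into the uncertain band", {
  set.seed(11)
  pv <- runif(50)
  ur <- structure(list(lower = 0.4, upper = 0.6, empty = FALSE,
                       single_threshold = NA_real_,
                       positive_label = "p"),
                  class = "uncertainty_range")
  wide <- structure(list(lower = 0.3, upper = 0.7, empty = FALSE,
                         single_threshold = NA_real_,
                         positive_label = "p"),
                    class = "uncertainty_range")
  d1 <- decide_binary(pv, ur)
  d2 <- decide_binary(pv, wide)
  expect_gte(sum(d2 == "uncertain"), sum(d1 == "uncertain"))
  # any changed decision changed to uncertain, never across classes
  changed <- d1 != d2
  expect_true(all(d2[changed] == "uncertain"))
  # decisions depend only on (pv, range): permutation equivariance
  perm <- sample(50)
  expect_identical(decide_binary(pv[perm], ur), d1[perm])
})

test_that("the hierarchical model trains cleanly on separable data", {
  ds <- small_study(seed = 31)
  al <- align_batched(ds$matrix)
  m <- fit_screening_model(al$matrix, ds$truths$category,
                           config = list(seed = 3, n_perm = 5))
  expect_s3_class(m, "screening_model")
  expect_false(m$diagnostics1$flagged)
  expect_false(m$diagnostics2$flagged)
  expect_true(m$diagnostics1$perm_strict)
  # model 2 is trained exactly on the non-EVOO training ids
  expect_setequal(m$model2$sample_ids,
                  ds$truths$sample_id[ds$truths$category != "EVOO"])

  # training-set guarantee on the out-of-fold predicted values
  lv1 <- m$diagnostics1$chosen_lv
  dec1 <- decide_binary(m$cv1$oof_pv[, lv1], m$range1)
  y1 <- as.integer(ds$truths$category == "EVOO")
  assigned <- dec1 != "uncertain"
  expect_true(all((dec1[assigned] == "positive") == (y1[assigned] == 1)))

  expect_error(
    fit_screening_model(al$matrix,
                        sub("LOO", "VOO", ds$truths$category)),
    "three categories")
})

test_that("label shuffling is caught by the model diagnostics", {
  ds <- small_study(12, 12, 10, seed = 77, n_points = 400)
  cats <- olivescreen:::with_seed(5, sample(ds$truths$category))
  m <- suppressWarnings(
    fit_screening_model(ds$matrix, cats,
                        config = list(seed = 2, n_perm = 0, max_lv = 6)))
  expect_true(m$diagnostics1$flagged)
  expect_lte(m$diagnostics1$q2, 0.4)
})

test_that("the screening cascade partitions and labels correctly", {
  ds <- small_study(seed = 31)
  al <- align_batched(ds$matrix)
  m <- fit_screening_model(al$matrix, ds$truths$category,
                           config = list(seed = 3, n_perm = 0))
  dec <- screen(m, al$matrix)
  expect_equal(nrow(dec), nrow(ds$truths))
  # partition: every sample is either assigned or uncertain
  expect_true(all(dec$outcome %in% c("EVOO", "VOO", "LOO", "UNCERTAIN")))
  expect_equal(sum(dec$outcome == "UNCERTAIN") +
                 sum(dec$outcome != "UNCERTAIN"), nrow(dec))
  # cascade contract: EVOO and model-1 deferrals never consult model 2
  expect_true(all(is.na(dec$pv2[dec$outcome == "EVOO"])))
  expect_true(all(is.na(dec$pv2[dec$deferred_at == "model1"])))
  expect_true(all(!is.na(dec$pv2[dec$outcome %in% c("VOO", "LOO")])))
  # low pv1 and low pv2 means VOO (LOO is the positive dummy of model 2)
  low <- !is.na(dec$pv2) & dec$pv2 < m$range2$lower &
    dec$pv1 < m$range1$lower
  expect_true(all(dec$outcome[low] == "VOO"))

  expect_error(screen(m, al$matrix$values[, 1:100]), "grid mismatch")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_screening_tsv(dec, path)
  back <- read.delim(path)
  expect_equal(back$outcome, dec$outcome)
})
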