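# Repeated stratified holdout validation of the screening tool and
# report assembly (per-category, per-defect, aggregate).

#' Format a count pair as "pct (k/n)"
#'
#' Percentages are printed to one decimal; a zero denominator prints as a
#' blank percentage with the bare count pair.
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @return A string like `"71.4 (10/14)"`, or `"(0/0)"` when `n = 0`.
#' @export
format_count_pct <- function(k, n) {
  if (n == 0) return(sprintf("(%d/%d)", k, n))
  sprintf("%s (%d/%d)", formatC(100 * k / n, format = "f", digits = 1), k, n)
}

count_pct <- function(k, n) if (n == 0) NA_real_ else 100 * k / n

#' Stratified train/validation split
#'
#' Seeded sampling without replacement within each category. The training
#' count per category is `round(fraction * n)` with halves rounded up;
#' the remainder goes to validation.
#'
#' @param metadata Data frame with columns `sample_id` and `category`.
#' @param fraction Training fraction, strictly inside (0, 1).
#' @param seed Integer seed.
#' @param split_id Identifier stored in the result.
#' @return A list of class `split_spec` with `train_ids`,
#'   `validation_ids`, `fraction`, `seed`, `split_id`.
#' @export
stratified_split <- function(metadata, fraction = 0.8, seed = 1L,
                             split_id = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be strictly between 0 and 1")
  if (!all(c("sample_id", "category") %in% names(metadata)))
    stop("metadata needs sample_id and category columns")
  train <- character(0)
  with_seed(seed, {
    for (cat in unique(metadata$category)) {
      ids <- metadata$sample_id[metadata$category == cat]
      if (length(ids) == 0L) stop("empty category: ", cat)
      n_train <- floor(fraction * length(ids) + 0.5)  # round half up
      train <- c(train, sample(ids, n_train))
    }
  })
  structure(list(train_ids = train,
                 validation_ids = setdiff(metadata$sample_id, train),
                 fraction = fraction, seed = seed, split_id = split_id),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> #%s: %d train / %d validation (seed %d)\n",
              x$split_id, length(x$train_ids), length(x$validation_ids),
              x$seed))
  invisible(x)
}

summarise_outcomes <- function(decisions, truths) {
  df <- merge(decisions, truths[, c("sample_id", "category")],
              by = "sample_id")
  rows <- lapply(c("EVOO", "VOO", "LOO", "Total"), function(cat) {
    sub <- if (cat == "Total") df else df[df$category == cat, ]
    n <- nrow(sub)
    n_unc <- sum(sub$outcome == "UNCERTAIN")
    n_asg <- n - n_unc
    n_cor <- sum(sub$outcome == sub$category)
    data.frame(category = cat, n_total = n, n_uncertain = n_unc,
               pct_uncertain = count_pct(n_unc, n), n_assigned = n_asg,
               pct_assigned = count_pct(n_asg, n), n_correct = n_cor,
               pct_correct_of_assigned = count_pct(n_cor, n_asg),
               pct_reliable = count_pct(n_cor + n_unc, n))
  })
  do.call(rbind, rows)
}

#' Evaluate a screening model on an external validation set
#'
#' Screens the validation samples and tabulates, per category and in
#' total: uncertain, assigned, correctly classified (as percent of
#' assigned) and the reliable assignment percent, which treats uncertain
#' samples as resolved correctly by the sensory panel.
#'
#' @param model A [fit_screening_model()] result.
#' @param X_val Validation rows (matrix or [fingerprint_matrix()]).
#' @param truths Data frame of ground truths with at least `sample_id`
#'   and `category` for the validation rows.
#' @param sample_ids Validation sample ids (defaults to rownames).
#' @return A list of class `split_result` with `table` (rows EVOO, VOO,
#'   LOO, Total) and `decisions`.
#' @export
evaluate_split <- function(model, X_val, truths, sample_ids = NULL) {
  if (inherits(X_val, "fingerprint_matrix")) {
    sample_ids <- sample_ids %||% X_val$sample_ids
  }
  decisions <- screen(model, X_val, sample_ids)
  overlap <- intersect(decisions$sample_id, model$training_ids)
  if (length(overlap) > 0)
    stop("leakage guard: validation overlaps training (",
         paste(head(overlap, 3), collapse = ", "), " ...)")
  tab <- summarise_outcomes(decisions, truths)
  # accounting identities hold by construction; verify anyway
  stopifnot(all(tab$n_uncertain + tab$n_assigned == tab$n_total),
            all(tab$n_correct <= tab$n_assigned))
  structure(list(table = tab, decisions = decisions),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

weighted_mean_sd <- function(x, w) {
  keep <- !is.na(x) & w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0) return(c(mean = NA_real_, sd = NA_real_))
  m <- sum(w * x) / sum(w)
  c(mean = m, sd = sqrt(sum(w * (x - m)^2) / sum(w)))
}

#' Repeated stratified holdout validation
#'
#' Runs `n_splits` seeded stratified 80/20 splits; on each, fits the full
#' hierarchical screening model on the training rows and evaluates it on
#' the held-out rows. Aggregates per-category means and SDs across
#' splits; the Total row's correct-of-assigned uses the assigned-count
#' weighted mean and SD. Also assembles the per-split uncertainty-range
#' table (thresholds and percent uncertain in cross-validation for both
#' models, with mean and SD rows).
#'
#' @param fm Aligned [fingerprint_matrix()] of all samples.
#' @param truths Ground-truth data frame (`sample_id`, `category`, and
#'   `mpd`/`boundary_flag` for defect breakdowns).
#' @param n_splits Number of repeated splits (default 7).
#' @param fraction Training fraction (default 0.8).
#' @param seed Master seed; per-split seeds are spawned from it and
#'   recorded.
#' @param config Passed to [fit_screening_model()].
#' @return A list of class `aggregate_report`: `splits` (per-split
#'   `split_result`s), `summary` (mean/SD table), `thresholds` (the
#'   per-split uncertainty-range table), `split_seeds`, `models`.
#' @export
run_repeated_validation <- function(fm, truths, n_splits = 7,
                                    fraction = 0.8, seed = 1L,
                                    config = list()) {
  if (n_splits < 2) stop("need at least 2 splits")
  split_seeds <- with_seed(seed, sample.int(2^31 - 2, n_splits))
  splits <- vector("list", n_splits)
  models <- vector("list", n_splits)
  thr <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    sp <- stratified_split(truths, fraction, split_seeds[s], s)
    tr <- fm_subset(fm, sp$train_ids)
    va <- fm_subset(fm, sp$validation_ids)
    cat_tr <- truths$category[match(sp$train_ids, truths$sample_id)]
    cfg <- utils::modifyList(list(seed = split_seeds[s]), config)
    model <- fit_screening_model(tr, cat_tr, config = cfg)
    truths_va <- truths[match(sp$validation_ids, truths$sample_id), ]
    splits[[s]] <- evaluate_split(model, va, truths_va)
    models[[s]] <- model
    n1 <- length(sp$train_ids)
    unc1 <- sum(decide_binary(model$cv1$oof_pv[, model$diagnostics1$chosen_lv],
                              model$range1) == "uncertain")
    n2 <- sum(cat_tr != "EVOO")
    unc2 <- sum(decide_binary(model$cv2$oof_pv[, model$diagnostics2$chosen_lv],
                              model$range2) == "uncertain")
    thr[[s]] <- data.frame(
      split = s,
      lower1 = model$range1$lower, upper1 = model$range1$upper,
      pct_uncertain1 = count_pct(unc1, n1),
      lower2 = if (model$range2$empty) model$range2$single_threshold
               else model$range2$lower,
      upper2 = if (model$range2$empty) NA_real_ else model$range2$upper,
      pct_uncertain2 = count_pct(unc2, n2))
  }
  thr <- do.call(rbind, thr)
  # aggregate per category across splits
  cats <- c("EVOO", "VOO", "LOO", "Total")
  metrics <- c("pct_uncertain", "pct_assigned", "pct_correct_of_assigned",
               "pct_reliable")
  summary <- do.call(rbind, lapply(cats, function(cat) {
    vals <- lapply(splits, function(sr) sr$table[sr$table$category == cat, ])
    row <- data.frame(category = cat)
    for (m in metrics) {
      x <- vapply(vals, `[[`, numeric(1), m)
      if (cat == "Total" && m == "pct_correct_of_assigned") {
        w <- vapply(vals, `[[`, numeric(1), "n_assigned")
        ms <- weighted_mean_sd(x, w)
      } else {
        ms <- c(mean = mean(x, na.rm = TRUE), sd = sd(x[!is.na(x)]))
      }
      row[[paste0(m, "_mean")]] <- unname(ms["mean"])
      row[[paste0(m, "_sd")]] <- unname(ms["sd"])
    }
    row
  }))
  structure(list(splits = splits, summary = summary, thresholds = thr,
                 split_seeds = split_seeds, models = models,
                 n_splits = n_splits, fraction = fraction, seed = seed),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf("<aggregate_report> %d splits at %.0f%% training\n",
              x$n_splits, 100 * x$fraction))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-defect breakdown of screening decisions
#'
#' For the non-EVOO samples of a decision set, tabulates by main
#' perceived defect (MPD): sample count, uncertain and assigned percents,
#' the fraction of assigned samples that survived model 1 as non-EVOO,
#' and the VOO/LOO correctness among the samples model 2 actually
#' assigned, all with their count pairs. Boundary-flagged samples are
#' tallied separately.
#'
#' @param decisions A [screen()] decision data frame.
#' @param truths Ground truths with `sample_id`, `category`, `mpd` (and
#'   optionally `boundary_flag`).
#' @return A data frame with one row per defect.
#' @export
mpd_breakdown <- function(decisions, truths) {
  df <- merge(decisions,
              truths[, intersect(names(truths),
                                 c("sample_id", "category", "mpd",
                                   "boundary_flag"))],
              by = "sample_id")
  df <- df[df$category != "EVOO", ]
  if (any(is.na(df$mpd) | df$mpd == "none"))
    stop("non-EVOO sample lacking a main perceived defect")
  if (!"boundary_flag" %in% names(df)) df$boundary_flag <- FALSE
  defects <- c("rancid", "fusty-muddy", "musty-humid-earthy")
  do.call(rbind, lapply(defects, function(d) {
    sub <- df[df$mpd == d, ]
    n <- nrow(sub)
    n_unc <- sum(sub$outcome == "UNCERTAIN")
    n_asg <- n - n_unc
    # survived model 1: assigned a category and it is not EVOO
    n_noneevoo <- sum(sub$outcome %in% c("VOO", "LOO"))
    voo <- sub[sub$category == "VOO" & sub$outcome %in% c("VOO", "LOO"), ]
    loo <- sub[sub$category == "LOO" & sub$outcome %in% c("VOO", "LOO"), ]
    nb <- sum(sub$boundary_flag)
    nb_hard <- sum(sub$boundary_flag &
                     (sub$outcome == "UNCERTAIN" |
                        sub$outcome != sub$category))
    data.frame(
      mpd = d, n = n,
      pct_uncertain = count_pct(n_unc, n),
      uncertain = format_count_pct(n_unc, n),
      pct_assigned = count_pct(n_asg, n),
      assigned = format_count_pct(n_asg, n),
      pct_correct_as_nonEVOO = count_pct(n_noneevoo, n_asg),
      correct_as_nonEVOO = format_count_pct(n_noneevoo, n_asg),
      pct_correct_as_VOO = count_pct(sum(voo$outcome == "VOO"), nrow(voo)),
      correct_as_VOO = format_count_pct(sum(voo$outcome == "VOO"),
                                        nrow(voo)),
      pct_correct_as_LOO = count_pct(sum(loo$outcome == "LOO"), nrow(loo)),
      correct_as_LOO = format_count_pct(sum(loo$outcome == "LOO"),
                                        nrow(loo)),
      n_boundary = nb, n_boundary_uncertain_or_wrong = nb_hard)
  }))
}

#' Write an aggregate validation report to TSV and JSON
#'
#' The summary table goes to `<prefix>_summary.tsv`, the per-split
#' threshold table to `<prefix>_thresholds.tsv`, and both plus the seeds
#' to `<prefix>.json`.
#'
#' @param report A [run_repeated_validation()] result.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_aggregate_report <- function(report, prefix) {
  p1 <- paste0(prefix, "_summary.tsv")
  p2 <- paste0(prefix, "_thresholds.tsv")
  p3 <- paste0(prefix, ".json")
  write.table(report$summary, p1, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(report$thresholds, p2, sep = "\t", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, thresholds = report$thresholds,
         split_seeds = report$split_seeds, n_splits = report$n_splits,
         fraction = report$fraction, master_seed = report$seed),
    p3, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(p1, p2, p3))
}
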