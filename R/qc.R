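# In-house validation of the fingerprint: noise estimation, signal
# gating, per-scan RSD repeatability, system suitability (S/N, peak
# resolution) and PCA distance-to-model QC.

#' Estimate baseline noise from a peak-free window
#'
#' Scans all contiguous windows of `window_len` scans and picks the one
#' with minimal variance as a proxy for a representative peak-free region,
#' then reports its mean and standard deviation.
#'
#' @param row Intensity vector of one chromatogram.
#' @param window_len Window length in scans (conventional floor: 300).
#' @return A list of class `noise_estimate` with `mean_noise`, `sd_noise`,
#'   `window` (start and end indices) and `window_len`.
#' @export
estimate_noise <- function(row, window_len = 300) {
  row <- as.numeric(row)
  p <- length(row)
  window_len <- as.integer(window_len)
  if (window_len < 2L) stop("window_len must be >= 2")
  if (p <= window_len) stop("row must be longer than window_len")
  # O(p) variance of every window via running sums
  cs <- cumsum(c(0, row))
  cs2 <- cumsum(c(0, row^2))
  starts <- seq_len(p - window_len + 1L)
  s1 <- cs[starts + window_len] - cs[starts]
  s2 <- cs2[starts + window_len] - cs2[starts]
  v <- (s2 - s1^2 / window_len) / (window_len - 1L)
  best <- which.min(v)
  idx <- best:(best + window_len - 1L)
  structure(list(mean_noise = mean(row[idx]), sd_noise = sd(row[idx]),
                 window = c(start = best, end = best + window_len - 1L),
                 window_len = window_len),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> mean %.4g, sd %.4g (scans %d-%d)\n",
              x$mean_noise, x$sd_noise, x$window["start"], x$window["end"]))
  invisible(x)
}

#' Gate scan points by the noise threshold
#'
#' A scan point is retained when the mean replicate intensity strictly
#' exceeds `mean_noise + 3 * sd_noise`.
#'
#' @param replicates A [fingerprint_matrix()] or numeric matrix of
#'   replicate rows.
#' @param noise A [estimate_noise()] result.
#' @return Logical vector over scan points (`TRUE` = retained).
#' @export
signal_mask <- function(replicates, noise) {
  X <- if (inherits(replicates, "fingerprint_matrix")) replicates$values
       else as.matrix(replicates)
  if (nrow(X) == 0L) stop("replicate matrix is empty")
  colMeans(X) > noise$mean_noise + 3 * noise$sd_noise
}

#' Per-scan-point RSD repeatability
#'
#' For every retained scan point, the relative standard deviation percent
#' `100 * sd / mean` (n-1 denominator) across replicate injections.
#' Points with zero mean are reported as `NA` and excluded from the
#' summary fractions (with a message). The benchmark fractions of points
#' at or below 15% and 20% RSD are reported.
#'
#' @param replicates A [fingerprint_matrix()] (pre-aligned replicate
#'   injections) or numeric matrix with >= 2 rows.
#' @param mask Logical retained-point mask, e.g. from [signal_mask()];
#'   default keeps all points.
#' @param mode Label: `"intra_day"` or `"inter_day"`.
#' @return A list of class `repeatability_report` with `mode`,
#'   `retained_mask`, `retained_fraction`, `rsd_percent` (NA at excluded
#'   points), `frac_rsd_le_15` and `frac_rsd_le_20`.
#' @export
rsd_per_point <- function(replicates, mask = NULL,
                          mode = c("intra_day", "inter_day")) {
  mode <- match.arg(mode)
  X <- if (inherits(replicates, "fingerprint_matrix")) replicates$values
       else as.matrix(replicates)
  if (nrow(X) < 2L) stop("need at least 2 replicates")
  p <- ncol(X)
  if (is.null(mask)) mask <- rep(TRUE, p)
  if (length(mask) != p) stop("mask length must equal the number of points")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  rsd <- rep(NA_real_, p)
  ok <- mask & mu != 0
  if (any(mask & mu == 0))
    message(sum(mask & mu == 0),
            " retained point(s) with zero mean excluded from RSD")
  rsd[ok] <- 100 * sdv[ok] / mu[ok]
  vals <- rsd[ok]
  structure(list(mode = mode, retained_mask = mask,
                 retained_fraction = mean(mask),
                 rsd_percent = rsd,
                 frac_rsd_le_15 = if (length(vals)) mean(vals <= 15) else NA_real_,
                 frac_rsd_le_20 = if (length(vals)) mean(vals <= 20) else NA_real_),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf(
    "<repeatability_report> %s: %.1f%% of points retained; RSD<=15%%: %.1f%%, <=20%%: %.1f%%\n",
    x$mode, 100 * x$retained_fraction, 100 * x$frac_rsd_le_15,
    100 * x$frac_rsd_le_20))
  invisible(x)
}

#' Plot per-point RSD against mean signal intensity
#'
#' @param x A [rsd_per_point()] report.
#' @param replicates The replicate matrix the report was computed from.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_rsd_vs_intensity <- function(x, replicates, ...) {
  X <- if (inherits(replicates, "fingerprint_matrix")) replicates$values
       else as.matrix(replicates)
  mu <- colMeans(X)
  ok <- !is.na(x$rsd_percent)
  graphics::plot(mu[ok], x$rsd_percent[ok], log = "x",
                 xlab = "mean intensity", ylab = "RSD (%)",
                 main = paste("repeatability,", x$mode), ...)
  graphics::abline(h = c(15, 20), lty = c(2, 3))
}

locate_apex <- function(chrom, peak_rt, rt_tol = 0.2) {
  idx <- which(abs(chrom$rt - peak_rt) <= rt_tol)
  if (length(idx) == 0L)
    stop("no scans within ", rt_tol, " min of rt ", peak_rt)
  apex <- idx[which.max(chrom$intensity[idx])]
  if (chrom$intensity[apex] <= 0) stop("no apex found near rt ", peak_rt)
  apex
}

#' Signal-to-noise ratio of a compound peak
#'
#' `(apex intensity - mean noise) / noise SD`, with the apex located as
#' the intensity maximum within `rt_tol` minutes of the stated retention
#' time. The system-suitability convention requires S/N > 3.
#'
#' @param chrom A [chromatogram()].
#' @param peak_rt Expected retention time (minutes).
#' @param noise A [estimate_noise()] result.
#' @param rt_tol Search half-window in minutes.
#' @return The S/N ratio (`Inf` with a warning if the noise SD is zero).
#' @export
snr <- function(chrom, peak_rt, noise, rt_tol = 0.2) {
  apex <- locate_apex(chrom, peak_rt, rt_tol)
  if (noise$sd_noise == 0) {
    warning("noise SD is zero; S/N reported as Inf")
    return(Inf)
  }
  (chrom$intensity[apex] - noise$mean_noise) / noise$sd_noise
}

# Gaussian sigma (minutes) from a log-quadratic fit around the apex,
# using points above `frac` of the apex intensity.
fit_peak_sigma <- function(chrom, apex, rt_tol = 0.2, frac = 0.4) {
  idx <- which(abs(chrom$rt - chrom$rt[apex]) <= rt_tol &
                 chrom$intensity > frac * chrom$intensity[apex] &
                 chrom$intensity > 0)
  if (length(idx) < 3L) stop("too few points to fit a peak shape")
  t <- chrom$rt[idx]
  z <- log(chrom$intensity[idx])
  co <- stats::lm.fit(cbind(1, t, t^2), z)$coefficients
  if (!is.finite(co[3L]) || co[3L] >= 0)
    stop("peak near rt ", chrom$rt[apex], " is not locally Gaussian")
  sqrt(-1 / (2 * co[3L]))
}

#' Chromatographic resolution of a peak pair
#'
#' R = (t2 - t1) / ((w1 + w2) / 2), with each baseline peak width taken
#' as w = 4 sigma from a local Gaussian fit around the apex. Suitability
#' requires R >= 1 for the closest-eluting marker pair.
#'
#' @param chrom A [chromatogram()].
#' @param rt1,rt2 Stated retention times of the two peaks (minutes).
#' @param rt_tol Apex search half-window in minutes.
#' @return The resolution R (0 for coincident apices).
#' @export
peak_resolution <- function(chrom, rt1, rt2, rt_tol = 0.2) {
  a1 <- locate_apex(chrom, rt1, rt_tol)
  a2 <- locate_apex(chrom, rt2, rt_tol)
  if (a1 == a2) return(0)
  w1 <- 4 * fit_peak_sigma(chrom, a1, rt_tol)
  w2 <- 4 * fit_peak_sigma(chrom, a2, rt_tol)
  unname(abs(chrom$rt[a2] - chrom$rt[a1]) / ((w1 + w2) / 2))
}

#' System-suitability report
#'
#' Checks the S/N of named marker compounds (pass: all > 3) and the
#' resolution of one close-eluting peak pair (pass: R >= 1).
#'
#' @param chrom A standard-solution [chromatogram()].
#' @param compounds Named numeric vector of expected retention times for
#'   the sensitivity markers.
#' @param resolution_pair Numeric length-2 vector with the retention
#'   times of the resolution pair.
#' @param noise A [estimate_noise()] result (default: estimated from the
#'   chromatogram).
#' @param window_len Noise window length when `noise` is `NULL`.
#' @return A list of class `suitability_report` with `snr_by_compound`,
#'   `resolution`, `pass_snr`, `pass_resolution`.
#' @export
suitability_report <- function(chrom, compounds, resolution_pair,
                               noise = NULL, window_len = 300) {
  if (is.null(noise)) noise <- estimate_noise(chrom$intensity, window_len)
  ratios <- vapply(compounds, function(rt) snr(chrom, rt, noise), numeric(1))
  R <- peak_resolution(chrom, resolution_pair[1L], resolution_pair[2L])
  structure(list(snr_by_compound = ratios, resolution = R,
                 pass_snr = all(ratios > 3), pass_resolution = R >= 1),
            class = "suitability_report")
}

#' @export
print.suitability_report <- function(x, ...) {
  cat("<suitability_report>\n  S/N:",
      paste(sprintf("%s=%.1f", names(x$snr_by_compound),
                    x$snr_by_compound), collapse = ", "),
      sprintf("[%s]\n", ifelse(x$pass_snr, "pass", "FAIL")))
  cat(sprintf("  resolution R = %.2f [%s]\n", x$resolution,
              ifelse(x$pass_resolution, "pass", "FAIL")))
  invisible(x)
}

#' PCA-based QC with distance-to-model diagnostics
#'
#' Fits a PCA (unit-variance scaling and mean centring) to QC replicates
#' plus control samples and reports each sample's normalized residual
#' standard deviation: `sqrt(RSS_i / (p - A))` divided by the pooled
#' residual SD of the model. By default the critical value comes from the
#' F distribution at the given confidence on that ratio; a fixed
#' `critical_value` override reproduces plotting conventions that place
#' the cut at another value.
#'
#' @param fm A [fingerprint_matrix()] or numeric matrix (rows >=
#'   `n_components + 2`).
#' @param n_components Number of principal components A.
#' @param confidence Confidence level for the default critical value.
#' @param critical_value Optional fixed override of the critical value.
#' @return A list with `scores` (data frame of sample scores) and
#'   `report`, a `dmodx_report` with `residual_sd_per_sample`,
#'   `critical_value` and `flags`.
#' @export
pca_qc <- function(fm, n_components = 4, confidence = 0.95,
                   critical_value = NULL) {
  X <- if (inherits(fm, "fingerprint_matrix")) fm$values else as.matrix(fm)
  ids <- rownames(X) %||% paste0("row", seq_len(nrow(X)))
  n <- nrow(X); p <- ncol(X); A <- as.integer(n_components)
  if (n < A + 2L) stop("need at least n_components + 2 rows")
  model <- pca_fit(X, A)
  rss <- model$q_residuals
  s_i <- sqrt(rss / (p - A))
  denom_df <- (n - A - 1) * (p - A)
  s0 <- sqrt(sum(rss) / denom_df)
  # a model that captures the data exactly has no residual scale to
  # normalise by; report zero distances rather than 0/0 noise
  d <- if (sum(rss) > n * p * 1e-12) s_i / s0 else rep(0, n)
  crit <- critical_value %||% sqrt(qf(confidence, p - A, denom_df))
  structure_scores <- data.frame(sample_id = ids, model$scores)
  names(structure_scores)[-1L] <- paste0("PC", seq_len(A))
  report <- structure(list(residual_sd_per_sample = d,
                           critical_value = crit, flags = d > crit,
                           n_components = A),
                      class = "dmodx_report")
  list(scores = structure_scores, report = report)
}

#' @export
print.dmodx_report <- function(x, ...) {
  cat(sprintf(
    "<dmodx_report> A = %d, critical value %.3g, %d/%d sample(s) deviating\n",
    x$n_components, x$critical_value, sum(x$flags), length(x$flags)))
  invisible(x)
}

#' Write a repeatability report to TSV and JSON
#'
#' The per-point table goes to `<prefix>_rsd.tsv`; the summary to
#' `<prefix>_summary.json`.
#'
#' @param report A [rsd_per_point()] report.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_repeatability_report <- function(report, prefix) {
  tsv <- paste0(prefix, "_rsd.tsv")
  js <- paste0(prefix, "_summary.json")
  write.table(
    data.frame(point = seq_along(report$rsd_percent),
               retained = report$retained_mask,
               rsd_percent = report$rsd_percent),
    tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(mode = report$mode,
         retained_fraction = report$retained_fraction,
         frac_rsd_le_15 = report$frac_rsd_le_15,
         frac_rsd_le_20 = report$frac_rsd_le_20),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
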