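#' Construct a total-ion chromatogram
#'
#' A chromatogram holds one sample's TIC: a strictly increasing retention
#' time axis (minutes) and the per-scan summed intensity.
#'
#' @param rt Numeric vector of retention times in minutes, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of non-negative intensities, same length
#'   as `rt`.
#' @param sample_id Sample identifier.
#' @param batch Integer analytical batch label (may be `NA`).
#' @param metadata Free-form named list of acquisition metadata.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(rt, intensity, sample_id = "sample",
                         batch = NA_integer_, metadata = list()) {
  rt <- as.numeric(rt)
  intensity <- as.numeric(intensity)
  if (length(rt) < 2L)
    stop("chromatogram needs at least 2 scans")
  if (length(rt) != length(intensity))
    stop("rt and intensity must have equal length")
  if (any(diff(rt) <= 0))
    stop("rt must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensity must be finite and non-negative")
  structure(
    list(sample_id = as.character(sample_id), rt = rt,
         intensity = intensity, batch = as.integer(batch),
         metadata = metadata),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s: %d scans, %.2f-%.2f min, batch %s\n",
              x$sample_id, length(x$rt), min(x$rt), max(x$rt),
              ifelse(is.na(x$batch), "?", x$batch)))
  invisible(x)
}

#' Read a TIC from a two-column CSV
#'
#' Expects columns `rt_min` and `intensity` (header required). Scans before
#' `rt_min_cutoff` are dropped, mirroring the convention of extracting the
#' TIC from minute 5 onwards.
#'
#' @param path Path to the CSV file.
#' @param sample_id Sample identifier; defaults to the file name.
#' @param batch Integer batch label.
#' @param rt_min_cutoff Drop scans with `rt < rt_min_cutoff` (minutes);
#'   `NULL` keeps everything.
#' @return A [chromatogram()].
#' @export
read_tic_csv <- function(path, sample_id = NULL, batch = NA_integer_,
                         rt_min_cutoff = NULL) {
  df <- read.csv(path)
  if (!all(c("rt_min", "intensity") %in% names(df)))
    stop("TIC CSV must have columns rt_min and intensity: ", path)
  rt <- df$rt_min
  y <- df$intensity
  if (!is.null(rt_min_cutoff)) {
    keep <- rt >= rt_min_cutoff
    rt <- rt[keep]; y <- y[keep]
    if (length(rt) < 2L) stop("chromatogram empty after rt cutoff: ", path)
  }
  if (any(diff(rt) <= 0)) stop("non-monotone rt axis in ", path)
  chromatogram(rt, y,
               sample_id = sample_id %||% sub("\\.csv$", "", basename(path)),
               batch = batch)
}

#' Write a TIC to CSV (columns rt_min, intensity)
#'
#' @param x A [chromatogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tic_csv <- function(x, path) {
  stopifnot(inherits(x, "chromatogram"))
  write.csv(data.frame(rt_min = x$rt, intensity = x$intensity), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a TIC from an mzML file
#'
#' Sums intensities over the full acquired m/z range of every MS1 scan and
#' drops scans acquired before `rt_min_cutoff` minutes (default 5, the
#' start of the informative volatile region on the 60 m wax column method
#' this tool targets).
#'
#' @param path Path to an mzML file.
#' @param rt_min_cutoff Retention-time cutoff in minutes.
#' @param sample_id Sample identifier; defaults to the file name.
#' @param batch Integer batch label.
#' @return A [chromatogram()].
#' @export
read_tic_mzml <- function(path, rt_min_cutoff = 5, sample_id = NULL,
                          batch = NA_integer_) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  ms1 <- which(hd$msLevel == 1L)
  if (length(ms1) == 0L) stop("no MS1 scans in ", path)
  tic <- vapply(ms1, function(i) sum(mzR::peaks(fh, i)[, 2L]), numeric(1))
  rt <- hd$retentionTime[ms1] / 60  # seconds -> minutes
  ord <- order(rt)
  rt <- rt[ord]; tic <- tic[ord]
  keep <- rt >= rt_min_cutoff
  if (sum(keep) < 2L) stop("fewer than 2 MS1 scans after rt cutoff in ", path)
  chromatogram(rt[keep], pmax(tic[keep], 0),
               sample_id = sample_id %||% sub("\\.mzML$", "", basename(path),
                                              ignore.case = TRUE),
               batch = batch)
}

#' Construct a fingerprint matrix
#'
#' The samples-by-scan-points intensity matrix on a shared retention axis
#' that all multivariate stages operate on.
#'
#' @param values n x p numeric matrix of intensities.
#' @param rt_axis Shared retention axis (minutes), length p.
#' @param sample_ids Character vector of length n.
#' @param batches Integer vector of length n (batch per sample).
#' @param aligned Logical: has retention-time alignment been applied?
#' @return An object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(values, rt_axis, sample_ids,
                               batches = rep(NA_integer_, nrow(values)),
                               aligned = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("fingerprint matrix needs at least one row")
  if (ncol(values) != length(rt_axis))
    stop("rt_axis length must equal the number of columns")
  if (length(sample_ids) != nrow(values))
    stop("one sample_id per row required")
  if (length(batches) != nrow(values))
    stop("one batch label per row required")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  dimnames(values) <- list(sample_ids, NULL)
  structure(
    list(values = values, rt_axis = as.numeric(rt_axis),
         sample_ids = as.character(sample_ids),
         batches = as.integer(batches), aligned = isTRUE(aligned)),
    class = "fingerprint_matrix"
  )
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf(
    "<fingerprint_matrix> %d samples x %d points, %.2f-%.2f min, %s\n",
    nrow(x$values), ncol(x$values), min(x$rt_axis), max(x$rt_axis),
    if (x$aligned) "aligned" else "unaligned"))
  invisible(x)
}

#' Subset a fingerprint matrix by row
#'
#' @param x A [fingerprint_matrix()].
#' @param i Row index, logical mask or character sample ids.
#' @return A [fingerprint_matrix()] with the selected rows.
#' @export
fm_subset <- function(x, i) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (anyNA(i)) stop("unknown sample id in subset")
  fingerprint_matrix(x$values[i, , drop = FALSE], x$rt_axis,
                     x$sample_ids[i], x$batches[i], x$aligned)
}

#' Interpolate chromatograms onto a common uniform grid
#'
#' Linearly interpolates each chromatogram onto a uniform retention grid
#' spanning the retention window shared by all inputs.
#'
#' @param chromatograms A list of [chromatogram()] objects.
#' @param n_points Number of grid points.
#' @return An unaligned [fingerprint_matrix()].
#' @export
resample_to_grid <- function(chromatograms, n_points = 2000) {
  stopifnot(length(chromatograms) >= 1L, n_points >= 2L)
  lo <- max(vapply(chromatograms, function(ch) min(ch$rt), numeric(1)))
  hi <- min(vapply(chromatograms, function(ch) max(ch$rt), numeric(1)))
  if (lo >= hi) stop("chromatograms share no common retention window")
  grid <- seq(lo, hi, length.out = n_points)
  vals <- t(vapply(chromatograms, function(ch) {
    approx(ch$rt, ch$intensity, xout = grid)$y
  }, numeric(n_points)))
  fingerprint_matrix(
    vals, grid,
    sample_ids = vapply(chromatograms, `[[`, character(1), "sample_id"),
    batches = vapply(chromatograms, `[[`, integer(1), "batch"),
    aligned = FALSE
  )
}
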