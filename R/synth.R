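# Synthetic GC-MS volatile fingerprints of virgin olive oils.
#
# Forward model: each sample's TIC is a flat baseline plus Gaussian peaks
# for a library of marker volatiles; a peak's log-amplitude is linear in
# the sample's sensory-attribute intensities (fruity plus the main
# perceived defect), so defect intensity acts multiplicatively on marker
# abundance. Retention-time drift is a per-batch systematic shift plus
# per-sample jitter; analytical noise is additive Gaussian relative to
# the baseline.

DEFECTS <- c("rancid", "fusty-muddy", "musty-humid-earthy")
ATTRS <- c("fruity", DEFECTS)
CATEGORIES <- c("EVOO", "VOO", "LOO")

#' Simulation configuration
#'
#' @param rt_start,rt_end Retention window in minutes. The defaults cover
#'   minute 5 to minute 58.4 (the span of 16,347 scans at 5.1 scans/s on
#'   the reference GC method).
#' @param n_points Scan-grid size (default 2000; the instrument-resolution
#'   grid of 16,347 points is one configuration change away).
#' @param baseline_level Baseline intensity (arbitrary units).
#' @param noise_sd_intra Within-day analytical noise, as a fraction (SD
#'   relative to intensity for QC replicates, relative to baseline for the
#'   additive term of single samples).
#' @param noise_sd_inter Between-day effect (relative SD of the day-level
#'   response factor).
#' @param rt_jitter_sd Per-sample retention jitter, in scans.
#' @param batch_shift Systematic shift per batch step, in scans.
#' @param amp_log_sd Biological lognormal spread of peak amplitudes
#'   (SD on the log scale).
#' @param voo_loo_cut Defect median separating VOO from LOO (trade
#'   convention 3.5).
#' @param boundary_band Half-width (in defect-median units) of the band
#'   around `voo_loo_cut` used to simulate panel-boundary samples.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(rt_start = 5, rt_end = 58.4, n_points = 2000,
                       baseline_level = 100, noise_sd_intra = 0.05,
                       noise_sd_inter = 0.03, rt_jitter_sd = 1.5,
                       batch_shift = 3, amp_log_sd = 0.25,
                       voo_loo_cut = 3.5, boundary_band = 0.5) {
  if (rt_start >= rt_end) stop("rt_start must be below rt_end")
  if (n_points < 100) stop("n_points must be >= 100")
  sds <- c(noise_sd_intra, noise_sd_inter, rt_jitter_sd, amp_log_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  structure(list(rt_start = rt_start, rt_end = rt_end,
                 n_points = as.integer(n_points),
                 baseline_level = baseline_level,
                 noise_sd_intra = noise_sd_intra,
                 noise_sd_inter = noise_sd_inter,
                 rt_jitter_sd = rt_jitter_sd, batch_shift = batch_shift,
                 amp_log_sd = amp_log_sd, voo_loo_cut = voo_loo_cut,
                 boundary_band = boundary_band),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys are the arguments of [sim_config()]; a `seed` key, if present, is
#' returned as the `seed` attribute.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` (with optional `seed` attribute).
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  seed <- vals$seed
  vals$seed <- NULL
  cfg <- do.call(sim_config, vals)
  if (!is.null(seed)) attr(cfg, "seed") <- as.integer(seed)
  cfg
}

sim_grid <- function(config) {
  seq(config$rt_start, config$rt_end, length.out = config$n_points)
}

#' Default marker-peak library
#'
#' A fixed library of volatile marker peaks on the retention axis, with
#' per-attribute log-amplitude slopes: fruity markers dominate sound oils,
#' while each sensory defect family (rancid, fusty-muddy,
#' musty-humid-earthy) elevates its own markers. Amplitude slopes are free
#' parameters of the simulator, not estimates of real concentration-to-
#' sensory relations.
#'
#' @return A data frame with one row per peak: `name`, `rt_center` (min),
#'   `rt_sigma` (min), `base_log_amp`, and one loading column per
#'   attribute (`fruity`, `rancid`, `fusty.muddy`, `musty.humid.earthy`).
#' @export
default_peak_library <- function() {
  lib <- data.frame(
    name = c("ethanol", "ethyl acetate", "1-penten-3-one", "hexanal",
             "(E)-2-hexenal", "3-methyl-1-butanol", "(Z)-3-hexenyl acetate",
             "(E)-2-heptenal", "hexyl acetate", "1-hexanol",
             "(Z)-3-hexen-1-ol", "1-octen-3-ol", "nonanal", "acetic acid",
             "pentanoic acid", "hexanoic acid", "guaiacol"),
    rt_center = c(7.5, 8.6, 10.5, 12.0, 15.8, 16.5, 19.2,
                  19.8, 20.6, 21.5, 22.3, 24.5, 25.8, 27.5,
                  33.0, 35.5, 38.2),
    rt_sigma = c(0.07, 0.06, 0.06, 0.08, 0.08, 0.09, 0.08,
                 0.08, 0.08, 0.10, 0.10, 0.10, 0.10, 0.18,
                 0.15, 0.16, 0.12),
    base_log_amp = c(6.2, 5.8, 5.2, 6.8, 6.5, 5.4, 5.9,
                     5.3, 5.6, 6.0, 6.1, 5.0, 5.7, 5.9,
                     5.0, 5.5, 4.6),
    fruity = c(0, 0.05, 0.40, 0.10, 0.60, 0, 0.70,
               0, 0.50, 0.20, 0.50, 0, 0, 0,
               0, 0, 0),
    rancid = c(0, 0, 0, 0.50, 0, 0, 0,
               0.70, 0, 0, 0, 0, 0.40, 0,
               0.50, 0.50, 0),
    fusty.muddy = c(0.40, 0.50, 0, 0, 0, 0.60, 0,
                    0, 0, 0.30, 0, 0, 0, 0.50,
                    0.10, 0.10, 0),
    musty.humid.earthy = c(0, 0, 0, 0, 0, 0.10, 0,
                           0, 0, 0, 0, 0.80, 0, 0.20,
                           0, 0, 0.70)
  )
  lib
}

attr_vector <- function(truth) {
  v <- stats::setNames(numeric(length(ATTRS)), ATTRS)
  v["fruity"] <- truth$fruity_median
  if (truth$mpd != "none") v[truth$mpd] <- truth$defect_median
  v
}

#' Construct and validate a sample ground truth
#'
#' Encodes the sensory-panel ground truth of one simulated oil. Category
#' invariants are enforced: EVOO has no defect and positive fruitiness;
#' VOO has a defect median in (0, cut]; LOO has a defect median above the
#' cut (or no fruitiness).
#'
#' @param sample_id Identifier.
#' @param category `"EVOO"`, `"VOO"` or `"LOO"`.
#' @param mpd Main perceived defect: `"none"`, `"rancid"`,
#'   `"fusty-muddy"` or `"musty-humid-earthy"`.
#' @param defect_median Panel median intensity of the MPD (>= 0).
#' @param fruity_median Panel median of the fruity attribute (>= 0).
#' @param boundary_flag Is the sample inside the boundary band around the
#'   VOO/LOO cut?
#' @param batch,day,replicate Integer acquisition structure labels.
#' @param voo_loo_cut Defect-median cut between VOO and LOO.
#' @return A list of class `sample_truth`.
#' @export
sample_truth <- function(sample_id, category, mpd = "none",
                         defect_median = 0, fruity_median = 0,
                         boundary_flag = FALSE, batch = 1L, day = 1L,
                         replicate = 1L, voo_loo_cut = 3.5) {
  category <- match.arg(category, CATEGORIES)
  mpd <- match.arg(mpd, c("none", DEFECTS))
  if (defect_median < 0 || fruity_median < 0)
    stop("attribute medians must be >= 0")
  if (category == "EVOO" && (defect_median != 0 || fruity_median <= 0))
    stop("invariant violated: EVOO requires defect_median = 0 and fruity_median > 0")
  if (category != "EVOO" && mpd == "none")
    stop("invariant violated: non-EVOO samples need a main perceived defect")
  if (category == "VOO" &&
      !(defect_median > 0 && defect_median <= voo_loo_cut))
    stop("invariant violated: VOO requires 0 < defect_median <= ", voo_loo_cut)
  if (category == "LOO" &&
      !(defect_median > voo_loo_cut || fruity_median == 0))
    stop("invariant violated: LOO requires defect_median > ", voo_loo_cut,
         " or fruity_median = 0")
  structure(list(sample_id = as.character(sample_id), category = category,
                 mpd = mpd, defect_median = defect_median,
                 fruity_median = fruity_median,
                 boundary_flag = isTRUE(boundary_flag),
                 batch = as.integer(batch), day = as.integer(day),
                 replicate = as.integer(replicate)),
            class = "sample_truth")
}

truths_to_df <- function(truths) {
  do.call(rbind, lapply(truths, function(t)
    data.frame(sample_id = t$sample_id, category = t$category, mpd = t$mpd,
               defect_median = t$defect_median,
               fruity_median = t$fruity_median,
               boundary_flag = t$boundary_flag, batch = t$batch,
               day = t$day, replicate = t$replicate)))
}

# Noise-free peak amplitudes of one sample (no biological spread term).
peak_amplitudes <- function(truth, library) {
  attrs <- attr_vector(truth)
  L <- as.matrix(library[, c("fruity", "rancid", "fusty.muddy",
                             "musty.humid.earthy")])
  colnames(L) <- ATTRS
  exp(library$base_log_amp + as.numeric(L %*% attrs))
}

# Evaluate baseline + sum of Gaussians on the grid.
peak_signal <- function(grid, library, amps, delta_min, baseline) {
  y <- rep(baseline, length(grid))
  for (k in seq_len(nrow(library))) {
    mu <- library$rt_center[k] + delta_min
    s <- library$rt_sigma[k]
    y <- y + amps[k] * exp(-(grid - mu)^2 / (2 * s^2))
  }
  y
}

#' Simulate one sample's TIC
#'
#' Intensity model: `baseline + sum_k A_k exp(-(t - rt_k - delta)^2 /
#' (2 sigma_k^2)) + eps(t)`, with `log A_k = base_log_amp_k +
#' sum_attr loading * attribute_intensity + N(0, amp_log_sd)`; `delta`
#' combines the systematic batch shift and per-sample jitter; `eps` is
#' Gaussian with SD `noise_sd_intra * baseline`. Intensities are clipped
#' at zero. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param truth A [sample_truth()].
#' @param library A peak library, see [default_peak_library()].
#' @param config A [sim_config()].
#' @return A [chromatogram()].
#' @export
simulate_sample <- function(truth, library = default_peak_library(),
                            config = sim_config()) {
  if (!inherits(truth, "sample_truth"))
    truth <- do.call(sample_truth, truth)
  grid <- sim_grid(config)
  dt <- grid[2L] - grid[1L]
  amps <- peak_amplitudes(truth, library)
  if (config$amp_log_sd > 0)
    amps <- amps * exp(rnorm(length(amps), 0, config$amp_log_sd))
  delta_scans <- config$batch_shift * (truth$batch - 1L)
  if (config$rt_jitter_sd > 0)
    delta_scans <- delta_scans + rnorm(1L, 0, config$rt_jitter_sd)
  y <- peak_signal(grid, library, amps, delta_scans * dt,
                   config$baseline_level)
  if (config$noise_sd_intra > 0)
    y <- y + rnorm(length(y), 0,
                   config$noise_sd_intra * config$baseline_level)
  chromatogram(grid, pmax(y, 0), sample_id = truth$sample_id,
               batch = truth$batch)
}

draw_truth <- function(i, category, mpd, boundary, config) {
  cut <- config$voo_loo_cut
  band <- config$boundary_band
  if (category == "EVOO") {
    defect <- 0
    fruity <- runif(1L, 2, 5)
    mpd <- "none"
  } else if (category == "VOO") {
    defect <- if (boundary) runif(1L, cut - band, cut) else
      runif(1L, 0.5, cut - band)
    fruity <- runif(1L, 0.5, 3)
  } else {
    defect <- if (boundary) runif(1L, cut + 1e-6, cut + band) else
      runif(1L, cut + band, 6)
    fruity <- runif(1L, 0, 1.5)
  }
  list(sample_id = sprintf("S%03d", i), category = category, mpd = mpd,
       defect_median = defect, fruity_median = fruity,
       boundary_flag = boundary, voo_loo_cut = cut)
}

#' Simulate a full sample set
#'
#' Draws per-sample ground truths (categories, defects with intensities
#' drawn per category, a configurable fraction of boundary samples near
#' the VOO/LOO cut), assigns batches round-robin, and simulates every TIC
#' on the common grid. The returned matrix is unaligned: each row carries
#' its own batch shift and jitter.
#'
#' @param n_evoo,n_voo,n_loo Per-category sample counts.
#' @param mpd_mix Named proportions over the three defects (must sum
#'   to 1); defects are assigned to non-EVOO samples in these proportions.
#' @param n_batches Number of analytical batches (round-robin assignment).
#' @param boundary_fraction Fraction of non-EVOO samples whose defect
#'   median lies within the boundary band around the VOO/LOO cut.
#' @param config A [sim_config()].
#' @param seed Integer seed; the run is fully reproducible.
#' @return A list with `matrix` (unaligned [fingerprint_matrix()]) and
#'   `truths` (a data frame of ground truths).
#' @export
simulate_dataset <- function(n_evoo, n_voo, n_loo,
                             mpd_mix = c("rancid" = 0.40,
                                         "fusty-muddy" = 0.45,
                                         "musty-humid-earthy" = 0.15),
                             n_batches = 2, boundary_fraction = 0.13,
                             config = sim_config(), seed = 1L) {
  counts <- c(n_evoo, n_voo, n_loo)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("empty dataset")
  if (abs(sum(mpd_mix) - 1) > 1e-8) stop("mpd_mix must sum to 1")
  if (!all(names(mpd_mix) %in% DEFECTS)) stop("unknown defect in mpd_mix")
  library <- default_peak_library()
  with_seed(seed, {
    categories <- rep(CATEGORIES, counts)
    n <- length(categories)
    non_evoo <- which(categories != "EVOO")
    mpd <- rep("none", n)
    if (length(non_evoo) > 0) {
      k <- length(non_evoo)
      pool <- rep(names(mpd_mix), times = floor(mpd_mix * k))
      if (length(pool) < k)
        pool <- c(pool, sample(names(mpd_mix), k - length(pool),
                               replace = TRUE, prob = mpd_mix))
      mpd[non_evoo] <- sample(pool)
    }
    boundary <- rep(FALSE, n)
    if (length(non_evoo) > 0) {
      nb <- round(boundary_fraction * length(non_evoo))
      boundary[sample(non_evoo, nb)] <- TRUE
    }
    batch <- rep_len(seq_len(n_batches), n)
    truths <- vector("list", n)
    chroms <- vector("list", n)
    for (i in seq_len(n)) {
      spec <- draw_truth(i, categories[i], mpd[i], boundary[i], config)
      spec$batch <- batch[i]
      truth <- do.call(sample_truth, spec)
      truths[[i]] <- truth
      chroms[[i]] <- simulate_sample(truth, library, config)
    }
    fm <- fingerprint_matrix(
      t(vapply(chroms, `[[`, numeric(config$n_points), "intensity")),
      sim_grid(config),
      vapply(chroms, `[[`, character(1), "sample_id"),
      batch, aligned = FALSE)
    list(matrix = fm, truths = truths_to_df(truths))
  })
}

#' Default pooled-QC control set
#'
#' Two EVOO and four LOO control oils: two rancid (median above 4), one
#' fusty-muddy and one combined fusty-muddy + musty-humid-earthy (medians
#' above 5; the combined defect is represented by its dominant
#' fusty-muddy attribute).
#'
#' @return A list of [sample_truth()] objects.
#' @export
default_qc_controls <- function() {
  list(
    sample_truth("QC-E1", "EVOO", fruity_median = 3.5),
    sample_truth("QC-E2", "EVOO", fruity_median = 2.8),
    sample_truth("QC-LR1", "LOO", "rancid", 4.5, 0.5),
    sample_truth("QC-LR2", "LOO", "rancid", 4.2, 0.8),
    sample_truth("QC-LF", "LOO", "fusty-muddy", 5.5, 0.3),
    sample_truth("QC-LFH", "LOO", "fusty-muddy", 5.2, 0.2)
  )
}

#' Simulate pooled-QC replicate fingerprints
#'
#' The pooled QC mixes the control oils in equal volumes: its underlying
#' peak-amplitude vector is the arithmetic mean of the controls'
#' noise-free amplitude vectors. Replicates then add only analytical
#' noise, multiplicative with coefficient of variation `noise_sd_intra`
#' (intra-day mode), plus a day-level response factor of relative SD
#' `noise_sd_inter` and a day-level retention jitter of `rt_jitter_sd`
#' scans (inter-day mode). The biological amplitude spread is not
#' re-sampled per replicate.
#'
#' @param controls List of [sample_truth()] control oils (default
#'   [default_qc_controls()]).
#' @param n_replicates Number of replicate injections (>= 2).
#' @param mode `"intra_day"` or `"inter_day"`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A [fingerprint_matrix()] of the replicates (unaligned).
#' @export
simulate_qc_pool <- function(controls = default_qc_controls(),
                             n_replicates = 7,
                             mode = c("intra_day", "inter_day"),
                             config = sim_config(), seed = 1L) {
  mode <- match.arg(mode)
  if (length(controls) == 0) stop("controls must be non-empty")
  if (n_replicates < 2) stop("need at least 2 replicates")
  library <- default_peak_library()
  grid <- sim_grid(config)
  dt <- grid[2L] - grid[1L]
  amp_mat <- vapply(controls, peak_amplitudes, numeric(nrow(library)),
                    library = library)
  pooled <- rowMeans(amp_mat)
  with_seed(seed, {
    reps <- base::matrix(0, n_replicates, config$n_points)
    for (r in seq_len(n_replicates)) {
      delta <- 0
      day_factor <- 1
      if (mode == "inter_day") {
        if (config$rt_jitter_sd > 0)
          delta <- rnorm(1L, 0, config$rt_jitter_sd) * dt
        if (config$noise_sd_inter > 0)
          day_factor <- 1 + rnorm(1L, 0, config$noise_sd_inter)
      }
      y <- peak_signal(grid, library, pooled * day_factor, delta,
                       config$baseline_level)
      if (config$noise_sd_intra > 0)
        y <- y * (1 + rnorm(length(y), 0, config$noise_sd_intra))
      reps[r, ] <- pmax(y, 0)
    }
    fingerprint_matrix(
      reps, grid,
      sprintf("QC_%s_%02d", ifelse(mode == "intra_day", "intra", "inter"),
              seq_len(n_replicates)),
      rep(1L, n_replicates), aligned = FALSE)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes one TIC CSV per sample (`rt_min,intensity`), a metadata TSV, and
#' optionally the combined matrix CSV (first column `sample_id`, remaining
#' columns the scan grid).
#'
#' @param dataset A list with `matrix` and `truths`, as returned by
#'   [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @param combined_csv Also write the combined matrix CSV?
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir, combined_csv = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- dataset$matrix
  for (i in seq_along(fm$sample_ids)) {
    write.csv(data.frame(rt_min = fm$rt_axis, intensity = fm$values[i, ]),
              file.path(dir, paste0(fm$sample_ids[i], ".csv")),
              row.names = FALSE)
  }
  write.table(dataset$truths, file.path(dir, "metadata.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (combined_csv) {
    df <- data.frame(sample_id = fm$sample_ids, fm$values,
                     check.names = FALSE)
    names(df)[-1L] <- sprintf("%.4f", fm$rt_axis)
    write.csv(df, file.path(dir, "matrix.csv"), row.names = FALSE)
  }
  invisible(dir)
}
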