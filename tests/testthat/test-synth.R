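test_that("default peak library satisfies the marker contract", {
  lib <- default_peak_library()
  expect_gte(nrow(lib), 12)
  markers <- c("hexanal", "1-hexanol", "(Z)-3-hexenyl acetate",
               "(E)-2-heptenal", "pentanoic acid")
  expect_true(all(markers %in% lib$name))
  expect_gt(lib$rancid[lib$name == "(E)-2-heptenal"], 0)
  for (attr in c("fruity", "rancid", "fusty.muddy", "musty.humid.earthy"))
    expect_gte(sum(lib[[attr]] > 0), 2)
  cfg <- sim_config()
  expect_true(all(lib$rt_center > cfg$rt_start & lib$rt_center < cfg$rt_end))
  expect_true(all(lib$rt_sigma > 0))
  expect_identical(lib, default_peak_library())
})

test_that("sample truth invariants are enforced with named errors", {
  expect_error(sample_truth("x", "EVOO", defect_median = 1,
                            fruity_median = 2), "EVOO requires")
  expect_error(sample_truth("x", "EVOO", fruity_median = 0),
               "EVOO requires")
  expect_error(sample_truth("x", "VOO", "rancid", defect_median = 4,
                            fruity_median = 1), "VOO requires")
  expect_error(sample_truth("x", "LOO", "rancid", defect_median = 2,
                            fruity_median = 1), "LOO requires")
  expect_error(sample_truth("x", "VOO", "none", defect_median = 2),
               "main perceived defect")
  expect_s3_class(sample_truth("x", "LOO", "rancid", defect_median = 5,
                               fruity_median = 0.5), "sample_truth")
})

test_that("noise-free simulation is deterministic and defect-monotone", {
  cfg <- quiet_config(n_points = 600)
  evoo <- sample_truth("e", "EVOO", fruity_median = 3)
  a <- simulate_sample(evoo, config = cfg)
  b <- simulate_sample(evoo, config = cfg)
  expect_identical(a$intensity, b$intensity)

  lib <- default_peak_library()
  loo <- sample_truth("l", "LOO", "rancid", defect_median = 5,
                      fruity_median = 0.5)
  ch_l <- simulate_sample(loo, lib, cfg)
  # the rancid marker peak area grows with the defect median
  k <- which(lib$name == "(E)-2-heptenal")
  win <- abs(a$rt - lib$rt_center[k]) < 4 * lib$rt_sigma[k]
  area <- function(ch) sum(diff(ch$rt[win]) *
                             (head(ch$intensity[win], -1) +
                                ch$intensity[win][-1]) / 2)
  expect_gt(area(ch_l), area(a))

  # monotonicity across a defect ladder
  areas <- vapply(c(1, 2, 3), function(m) {
    tr <- sample_truth("v", "VOO", "rancid", defect_median = m,
                       fruity_median = 1)
    area(simulate_sample(tr, lib, cfg))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("single simulated peak integrates to the Gaussian closed form", {
  cfg <- quiet_config(n_points = 4000, baseline_level = 0)
  lib <- data.frame(name = "only", rt_center = 30, rt_sigma = 0.15,
                    base_log_amp = log(500), fruity = 0, rancid = 0,
                    fusty.muddy = 0, musty.humid.earthy = 0)
  tr <- sample_truth("e", "EVOO", fruity_median = 1)
  ch <- simulate_sample(tr, lib, cfg)
  trapz <- sum(diff(ch$rt) * (head(ch$intensity, -1) + ch$intensity[-1]) / 2)
  expect_equal(trapz, 500 * 0.15 * sqrt(2 * pi), tolerance = 0.01)
})

test_that("dataset simulation honours counts, seeds and degenerate input", {
  ds <- simulate_dataset(12, 10, 8, n_batches = 3, seed = 9,
                         config = sim_config(n_points = 400))
  expect_equal(nrow(ds$matrix$values), 30)
  expect_equal(as.vector(table(ds$truths$category)[c("EVOO", "VOO", "LOO")]),
               c(12, 10, 8))
  expect_setequal(unique(ds$truths$batch), 1:3)
  expect_true(all(ds$truths$mpd[ds$truths$category != "EVOO"] != "none"))

  ds2 <- simulate_dataset(12, 10, 8, n_batches = 3, seed = 9,
                          config = sim_config(n_points = 400))
  expect_identical(ds$matrix$values, ds2$matrix$values)
  expect_identical(ds$truths, ds2$truths)

  expect_error(simulate_dataset(0, 0, 0), "empty dataset")
})

test_that("class separation holds for noise-free mean fingerprints", {
  ds <- simulate_dataset(4, 4, 4, n_batches = 1, seed = 3,
                         config = quiet_config(n_points = 500))
  means <- sapply(c("EVOO", "VOO", "LOO"), function(cat)
    colMeans(ds$matrix$values[ds$truths$category == cat, , drop = FALSE]))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_gt(sqrt(sum((means[, pair[1]] - means[, pair[2]])^2)), 0)
})

test_that("retention jitter conserves total integrated signal", {
  cfg0 <- quiet_config(n_points = 2000)
  tr <- sample_truth("v", "VOO", "fusty-muddy", defect_median = 3,
                     fruity_median = 1)
  base <- simulate_sample(tr, config = cfg0)
  cfgj <- sim_config(noise_sd_intra = 0, noise_sd_inter = 0,
                     batch_shift = 0, amp_log_sd = 0,
                     n_points = 2000, rt_jitter_sd = 3)
  set.seed(10)
  jit <- simulate_sample(tr, config = cfgj)
  area <- function(ch) sum(diff(ch$rt) *
                             (head(ch$intensity, -1) + ch$intensity[-1]) / 2)
  expect_lt(abs(area(jit) - area(base)) / area(base), 0.005)
})

test_that("pooled QC replicates follow the requested noise modes", {
  cfg0 <- quiet_config(n_points = 600)
  qc0 <- simulate_qc_pool(n_replicates = 3, mode = "intra_day",
                          config = cfg0, seed = 1)
  expect_equal(nrow(qc0$values), 3)
  expect_identical(qc0$values[1, ], qc0$values[2, ])

  qc <- simulate_qc_pool(n_replicates = 7, mode = "intra_day",
                         config = sim_config(n_points = 1000), seed = 4)
  expect_equal(nrow(qc$values), 7)
  ne <- estimate_noise(qc$values[1, ], 300)
  msk <- signal_mask(qc, ne)
  rep <- rsd_per_point(qc, msk)
  # multiplicative CV 5% noise: per-point RSD concentrates near 5%
  med <- median(rep$rsd_percent[!is.na(rep$rsd_percent)])
  expect_gt(med, 2.5)
  expect_lt(med, 8)

  expect_error(simulate_qc_pool(list(), 7), "non-empty")
  expect_error(simulate_qc_pool(n_replicates = 1), "at least 2")
})

test_that("simulated datasets round-trip through the disk format", {
  ds <- simulate_dataset(2, 2, 2, seed = 5,
                         config = sim_config(n_points = 300))
  dir <- withr::local_tempdir()
  write_simulated_dataset(ds, dir, combined_csv = TRUE)
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
  expect_true(file.exists(file.path(dir, "matrix.csv")))
  ch <- read_tic_csv(file.path(dir, "S001.csv"))
  expect_equal(ch$intensity, unname(ds$matrix$values[1, ]))
  md <- read.delim(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, ds$truths$sample_id)
})

test_that("config files parse and invalid configs are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_points: 500", "noise_sd_intra: 0.02", "seed: 77"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_points, 500L)
  expect_equal(cfg$noise_sd_intra, 0.02)
  expect_equal(attr(cfg, "seed"), 77L)
  expect_error(sim_config(rt_start = 10, rt_end = 5), "rt_start")
  expect_error(sim_config(n_points = 50), "n_points")
  expect_error(sim_config(amp_log_sd = -1), "SDs")
})
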