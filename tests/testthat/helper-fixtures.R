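# Shared fixtures, all generated in code.

# A quiet simulation: no analytical noise, no jitter, no biological spread.
quiet_config <- function(...) {
  sim_config(noise_sd_intra = 0, noise_sd_inter = 0, rt_jitter_sd = 0,
             batch_shift = 0, amp_log_sd = 0, ...)
}

make_noise <- function(mean_noise, sd_noise) {
  structure(list(mean_noise = mean_noise, sd_noise = sd_noise,
                 window = c(start = 1L, end = 300L), window_len = 300L),
            class = "noise_estimate")
}

# Single-Gaussian fingerprint rows with per-row integer scan shifts.
gaussian_rows <- function(shifts, p = 400, center = 200, sigma = 10,
                          amp = 1000, baseline = 10, noise_sd = 0,
                          seed = 1) {
  set.seed(seed)
  t(vapply(shifts, function(s) {
    y <- baseline + amp * exp(-((seq_len(p) - center - s)^2) / (2 * sigma^2))
    if (noise_sd > 0) y <- y + rnorm(p, 0, noise_sd)
    pmax(y, 0)
  }, numeric(p)))
}

gaussian_fm <- function(shifts, batches = rep(1L, length(shifts)), ...) {
  X <- gaussian_rows(shifts, ...)
  fingerprint_matrix(X, seq_len(ncol(X)) / 10,
                     sprintf("G%02d", seq_along(shifts)), batches)
}

# Small separable study set for model tests: drift-free (retention drift
# is exercised by the alignment tests and the full-grid end-to-end run;
# at reduced grids, sub-scan peak widths would alias under jitter).
small_study <- function(n_evoo = 20, n_voo = 20, n_loo = 15, seed = 42,
                        n_points = 1000) {
  simulate_dataset(n_evoo, n_voo, n_loo, n_batches = 2, seed = seed,
                   config = sim_config(n_points = n_points,
                                       rt_jitter_sd = 0, batch_shift = 0))
}

# Minimal uncompressed mzML writer (64-bit little-endian floats).
write_mini_mzml <- function(path, rt_sec, mzs, intens, ms_levels = NULL) {
  enc64 <- function(x)
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  if (is.null(ms_levels)) ms_levels <- rep(1L, length(rt_sec))
  spec_xml <- function(i, rt, mz, inten, lvl) {
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
      '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>',
      '</scan></scanList><binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i, i + 1, length(mz), lvl, rt,
      nchar(enc64(mz)), enc64(mz), nchar(enc64(inten)), enc64(inten))
  }
  specs <- paste(mapply(spec_xml, seq_along(rt_sec) - 1, rt_sec, mzs,
                        intens, ms_levels),
                 collapse = "\n")
  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="x"/>',
    '<cv id="UO" fullName="UO" URI="x"/></cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="s" version="1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="ic"/></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="s">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="r" defaultInstrumentConfigurationRef="ic">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">\n%s\n',
    '</spectrumList></run></mzML>'),
    length(rt_sec), specs)
  writeLines(xml, path)
  path
}
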