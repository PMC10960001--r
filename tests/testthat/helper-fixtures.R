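# shared fixtures; heavyweight featurized datasets are cached as RDS in
# tempdir() so several test files can reuse them within one session
fixture_cache <- function(key, expr) {
  path <- file.path(tempdir(), paste0("serstax-cache-", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- force(expr)
  saveRDS(val, path)
  val
}

# all stochastic channels off: the separable-by-construction oracle world
zero_noise_config <- function(replicates = 4L) {
  synthetic_config(noise_sd = 0, jitter_sd = 0, band_noise_sd = 0,
                   r1330_noise_sd = 0, baseline_scale = 0,
                   replicates = replicates)
}

# featurized zero-noise panel, 4 replicates per class (56 spectra)
zero_noise_features <- function() {
  fixture_cache("fs-zero4", {
    featurize_set(generate_dataset(zero_noise_config(4L), seed = 11))
  })
}

# featurized default-noise panel at the full 60-replicate design (840
# spectra); this is the dataset the acceptance criteria run on
default_panel_features <- function() {
  fixture_cache("fs-default60", {
    featurize_set(generate_dataset(synthetic_config(), seed = 20240322))
  })
}

# dilution series of one analyte, featurized
dilution_series_features <- function(analyte, replicates, cfg, seed_base) {
  label <- parse_nomenclature(analyte)
  concs <- 10^-(4:10)
  n <- length(concs) * replicates
  spectra <- vector("list", n)
  cc <- character(n)
  k <- 0L
  for (ci in seq_along(concs)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      spectra[[k]] <- generate_spectrum(label, concs[ci], cfg,
                                        seed = derive_seed(seed_base + ci,
                                                           r))
      cc[k] <- format(concs[ci], scientific = TRUE)
    }
  }
  featurize_set(spectrum_set(spectra, rep(list(label), n), cc))
}

# a fully specified 19-band truth table for fit-recovery oracles: base
# reporter bands with the diagnostic amplitudes filled in
oracle_peak_truth <- function(seed = 7) {
  set.seed(seed)
  truth <- base_peak_table()[, c("center", "amplitude", "fwhm", "eta",
                                 "skew")]
  truth$amplitude[is.na(truth$amplitude)] <- c(0.5, 0.35, 0.8)
  truth$amplitude <- truth$amplitude * stats::runif(19, 0.8, 1.2)
  truth$fwhm <- truth$fwhm * stats::runif(19, 0.95, 1.05)
  truth$skew <- stats::runif(19, -0.05, 0.05)
  truth$skew[17:18] <- 0  # the overlapped a1/b2 pair is symmetric
  truth$eta <- stats::runif(19, 0.35, 0.65)
  truth
}

# noiseless spectrum from a truth table, normalized, flagged canonical
oracle_spectrum <- function(truth) {
  grid <- canonical_grid()
  y <- serstax:::peak_sum(grid, truth)
  spectrum(grid, y / max(y), meta = list(canonical = "true"))
}

quiet_fit <- function(sp, ...) {
  fit_peaks(sp, control = list(on_nonconvergence = "quiet", ...))
}
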