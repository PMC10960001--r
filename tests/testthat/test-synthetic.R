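test_that("the concentration response is the clipped log-linear ramp", {
  cfg <- synthetic_config()
  expect_equal(conc_alpha(1e-4, cfg), 1)
  expect_equal(conc_alpha(1e-10, cfg), 0)
  expect_equal(conc_alpha(1e-7, cfg), 0.5)
  expect_equal(conc_alpha(1e-12, cfg), 0)
  a <- conc_alpha(10^seq(-10, -4, by = 0.5), cfg)
  expect_true(all(diff(a) > 0))
})

test_that("generated spectra obey the five structural rules at c_max", {
  cfg <- synthetic_config()
  measure <- function(nm, n = 12L) {
    lab <- parse_nomenclature(nm)
    vals <- vapply(seq_len(n), function(r) {
      pp <- preprocess_spectrum(generate_spectrum(
        lab, if (lab$category == "blank") NA else 1e-4, cfg,
        seed = derive_seed(match(nm, names(analyte_panel())), r)))
      c(r1330 = intensity_ratio(pp, 1330, 1567),
        r1023 = intensity_ratio(pp, 1023, 1567),
        r691 = intensity_ratio(pp, 691, 1567),
        p414 = band_position(pp, 416.5, 9),
        a1 = band_position(pp, 1597, 14))
    }, numeric(5))
    rowMeans(vals)
  }
  for (nm in cerebroside_names()) {
    m <- measure(nm)
    lab <- parse_nomenclature(nm)
    # R1: epimer capture ratio inside the printed span
    expect_gt(m[["r1330"]], 0.07)
    expect_lt(m[["r1330"]], 2.2 * 1.05)
    # R3: hexose-specific position window
    if (lab$hexose == "glc") {
      expect_gt(m[["p414"]], 414 - 0.3)
      expect_lt(m[["p414"]], 417 + 0.3)
    } else {
      expect_gt(m[["p414"]], 417 - 0.3)
      expect_lt(m[["p414"]], 419 + 0.3)
    }
    # R2: a1 position by saturation
    if (lab$saturation > 0L) {
      expect_lt(m[["a1"]], 1598)
    } else {
      expect_gt(m[["a1"]], 1599.5)
    }
  }
  blank <- measure("MPBA blank")
  expect_lt(abs(blank[["r1330"]] - 0.6), 0.06)
  expect_lt(abs(blank[["p414"]] - 414), 0.5)
  gal24 <- measure("GalCer24")
  expect_lt(abs(gal24[["a1"]] - 1601), 1)
  expect_lt(abs(gal24[["p414"]] - 419), 0.6)
})

test_that("chain-length ratios increase strictly with X at zero noise", {
  cfg0 <- zero_noise_config()
  glc_ratio <- vapply(c(8L, 12L, 16L, 18L), function(x) {
    pp <- preprocess_spectrum(generate_spectrum(
      analyte_label("cerebroside", "glc", 0L, x), 1e-4, cfg0))
    intensity_ratio(pp, 1023, 1567)
  }, numeric(1))
  expect_true(all(diff(glc_ratio) > 0))
  gal_ratio <- vapply(c(8L, 12L, 16L, 18L, 24L), function(x) {
    pp <- preprocess_spectrum(generate_spectrum(
      analyte_label("cerebroside", "gal", 0L, x), 1e-4, cfg0))
    intensity_ratio(pp, 691, 1567)
  }, numeric(1))
  expect_true(all(diff(gal_ratio) > 0))
  # GlcCer8 vs GlcCer24:1 ordering of the Glc chain diagnostic
  r8 <- glc_ratio[1]
  pp241 <- preprocess_spectrum(generate_spectrum(
    parse_nomenclature("GlcCer24:1"), 1e-4, cfg0))
  expect_gt(intensity_ratio(pp241, 1023, 1567), r8)
})

test_that("the default design yields 14 x 60 = 840 labeled spectra", {
  cfg <- synthetic_config(noise_sd = 0, jitter_sd = 0, band_noise_sd = 0,
                          r1330_noise_sd = 0, baseline_scale = 0)
  ds <- generate_dataset(cfg, seed = 1)
  expect_length(ds, 14L * 60L)
  rc <- replicate_counts(ds)
  expect_true(all(rc$n == 60L))
  # replicate count 5 gives 70
  ds5 <- generate_dataset(cfg, replicates = 5L, seed = 1)
  expect_length(ds5, 70L)
})

test_that("datasets are bit-identical under a fixed master seed", {
  cfg <- synthetic_config(replicates = 2L)
  a <- generate_dataset(cfg, seed = 99)
  b <- generate_dataset(cfg, seed = 99)
  expect_identical(lapply(a$spectra, `[[`, "intensities"),
                   lapply(b$spectra, `[[`, "intensities"))
  c2 <- generate_dataset(cfg, seed = 100)
  expect_false(identical(a$spectra[[1]]$intensities,
                         c2$spectra[[1]]$intensities))
})

test_that("below-LOD concentrations warn and fall back to a blank", {
  cfg <- synthetic_config()
  lab <- parse_nomenclature("GalCer16")
  expect_warning(sp <- generate_spectrum(lab, 1e-12, cfg, seed = 4),
                 "below the detection limit")
  expect_identical(sp$meta$below_lod, "true")
  # below the detection limit every identity diagnostic collapses onto the
  # blank values (the analyte-loading channel still reflects the dilution)
  cfgq <- synthetic_config(noise_sd = 0, jitter_sd = 0, band_noise_sd = 0,
                           r1330_noise_sd = 0, baseline_scale = 0)
  suppressWarnings(below <- preprocess_spectrum(
    generate_spectrum(lab, 1e-12, cfgq)))
  blank <- preprocess_spectrum(generate_spectrum(analyte_label("blank"),
                                                 NA, cfgq))
  expect_equal(intensity_ratio(below, 1330, 1567),
               intensity_ratio(blank, 1330, 1567), tolerance = 0.02)
  expect_equal(band_position(below, 414, 8), band_position(blank, 414, 8),
               tolerance = 0.2)
  expect_equal(band_position(below, 1600, 12),
               band_position(blank, 1600, 12), tolerance = 0.3)
})

test_that("mixtures are convex in mol fraction with exact endpoints", {
  cfg0 <- zero_noise_config()
  pure_gal <- generate_mixture(100, cfg = cfg0)
  gal_sig <- generate_spectrum(parse_nomenclature("GalCer24:1"), 1e-4,
                               cfg0)
  expect_equal(pure_gal$intensities, gal_sig$intensities,
               tolerance = 1e-10)
  glc_sig <- generate_spectrum(parse_nomenclature("GlcCer24:1"), 1e-4,
                               cfg0)
  half <- generate_mixture(50, cfg = cfg0)
  expect_equal(half$intensities,
               0.5 * gal_sig$intensities + 0.5 * glc_sig$intensities,
               tolerance = 1e-10)
  expect_error(generate_mixture(120, cfg = cfg0), "frac_gal")
  # calibration design: 5 compositions x 60 replicates = 300 spectra
  cal <- generate_mixture_set(c(0, 25, 50, 75, 100), replicates = 60L,
                              cfg = synthetic_config(noise_sd = 0,
                                jitter_sd = 0, band_noise_sd = 0,
                                r1330_noise_sd = 0, baseline_scale = 0),
                              seed = 2)
  expect_length(cal$set, 300L)
  expect_equal(table(cal$frac_gal)[["50"]], 60L)
})

test_that("class separability degrades gracefully with intensity noise", {
  # the blank/cerebroside capture-ratio gap shrinks relative to its spread
  # as noise grows, but ordering is preserved at realistic levels
  seps <- vapply(c(0.005, 0.02, 0.08), function(s) {
    cfg <- synthetic_config(noise_sd = s, jitter_sd = 0, band_noise_sd = 0,
                            r1330_noise_sd = 0, baseline_scale = 0)
    blank <- vapply(1:8, function(r) intensity_ratio(
      preprocess_spectrum(generate_spectrum(analyte_label("blank"), NA,
                                            cfg, seed = derive_seed(5, r))),
      1330, 1567), numeric(1))
    cer <- vapply(1:8, function(r) intensity_ratio(
      preprocess_spectrum(generate_spectrum(parse_nomenclature("GalCer18"),
                                            1e-4, cfg,
                                            seed = derive_seed(6, r))),
      1330, 1567), numeric(1))
    abs(mean(cer) - mean(blank)) / sqrt(stats::var(cer) + stats::var(blank))
  }, numeric(1))
  expect_true(all(diff(seps) < 0))
  expect_gt(seps[1], 5)
})
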