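test_that("line shape has the pseudo-Voigt limit cases and symmetry", {
  # pure Lorentzian: apex equals the amplitude
  expect_equal(line_shape(700, 700, 2, 10, 0, 1), 2)
  # pure Gaussian: half maximum at center +/- fwhm/2
  expect_equal(line_shape(705, 700, 2, 10, 0, 0), 1)
  expect_equal(line_shape(695, 700, 2, 10, 0, 0), 1)
  # symmetric when skew = 0
  d <- seq(0.5, 30, by = 0.7)
  expect_equal(line_shape(700 + d, 700, 1, 12, 0, 0.3),
               line_shape(700 - d, 700, 1, 12, 0, 0.3))
  # skew widens one side
  expect_gt(line_shape(710, 700, 1, 10, 0.3, 0.5),
            line_shape(690, 700, 1, 10, 0.3, 0.5))
  expect_error(line_shape(700, 700, 1, -1), "fwhm")
  expect_error(line_shape(700, 700, 1, 10, 0, 2), "eta")
})

test_that("fit recovers known components at the seed positions", {
  truth <- oracle_peak_truth(seed = 7)
  sp <- oracle_spectrum(truth)
  scale <- max(serstax:::peak_sum(canonical_grid(), truth))
  ft <- quiet_fit(sp)
  expect_true(ft$converged)
  expect_lt(max(abs(ft$peaks$center - truth$center)), 0.5)
  expect_lt(max(abs(ft$peaks$amplitude * scale - truth$amplitude) /
                  truth$amplitude), 0.02)
  expect_lt(max(abs(ft$peaks$fwhm - truth$fwhm) / truth$fwhm), 0.05)
})

test_that("fitted centers stay within 1.5 cm-1 under intensity noise", {
  truth <- oracle_peak_truth(seed = 13)
  grid <- canonical_grid()
  y0 <- serstax:::peak_sum(grid, truth)
  worst <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    y <- (y0 + stats::rnorm(1200, 0, 0.01 * max(y0))) / max(y0)
    sp <- spectrum(grid, y, meta = list(canonical = "true"))
    ft <- quiet_fit(sp)
    worst <- max(worst, max(abs(ft$peaks$center - truth$center)))
  }
  expect_lt(worst, 1.5)
})

test_that("an absent component fits to (near) zero amplitude", {
  truth <- oracle_peak_truth(seed = 21)
  truth$amplitude[truth$center == 860] <- 0
  sp <- oracle_spectrum(truth)
  ft <- quiet_fit(sp)
  expect_lt(ft$peaks$amplitude[ft$peaks$peak == 8L], 0.02)
})

test_that("fit reports non-convergence with best-so-far parameters", {
  truth <- oracle_peak_truth(seed = 3)
  sp <- oracle_spectrum(truth)
  expect_error(
    fit_peaks(sp, control = list(maxiter = 1L, global_maxiter = 1L,
                                 on_nonconvergence = "error")),
    class = "serstax_fit_failure")
  cond <- tryCatch(
    fit_peaks(sp, control = list(maxiter = 1L, global_maxiter = 1L,
                                 on_nonconvergence = "error")),
    serstax_fit_failure = function(e) e)
  expect_s3_class(cond$fit$peaks, "data.frame")
  expect_false(cond$fit$converged)
})

test_that("feature vectors have the fixed 95-entry schema", {
  truth <- oracle_peak_truth(seed = 5)
  sp <- oracle_spectrum(truth)
  ft <- quiet_fit(sp)
  fv <- to_features(ft)
  expect_length(fv, 95L)
  expect_identical(names(fv), feature_schema())
  # the intensity attribute is referenced to the 1567 cm-1 band
  expect_equal(unname(fv["p17_intensity"]), 1)
  # permuted rows produce the identical vector
  perm <- ft$peaks[sample(19), ]
  expect_identical(to_features(perm), fv)
  expect_error(to_features(ft$peaks[1:18, ]), "arity")
})

test_that("featurization is deterministic for a fixed spectrum", {
  cfg <- synthetic_config()
  sp <- generate_spectrum(parse_nomenclature("GlcCer12"), 1e-4, cfg,
                          seed = 9)
  expect_identical(featurize_spectrum(sp), featurize_spectrum(sp))
})

test_that("intensity ratios and band positions read the diagnostics", {
  cfg <- synthetic_config()
  # blank capture-band ratio: 0.6 +/- 0.05 over the replicate design
  blank <- analyte_label("blank")
  ratios <- vapply(1:60, function(r) {
    pp <- preprocess_spectrum(generate_spectrum(blank, NA, cfg,
                                                seed = derive_seed(1, r)))
    intensity_ratio(pp, 1330, 1567)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.6), 0.05)

  # monosaccharides sit below the 0.07 epimer threshold
  glc <- analyte_label("monosaccharide", "glc")
  mono_ratio <- mean(vapply(1:10, function(r) {
    pp <- preprocess_spectrum(generate_spectrum(glc, 1e-4, cfg,
                                                seed = derive_seed(2, r)))
    intensity_ratio(pp, 1330, 1567)
  }, numeric(1)))
  expect_lt(mono_ratio, 0.07)

  # a spectrum empty except at the denominator band gives ratio 0
  grid <- canonical_grid()
  sp0 <- spectrum(grid, line_shape(grid, 1567, 1, 10))
  expect_lt(intensity_ratio(sp0, 1330, 1567), 1e-3)
  expect_error(intensity_ratio(sp0, 395, 1567), "range error")

  # sub-grid apex refinement recovers an off-grid center
  sp1 <- spectrum(grid, line_shape(grid, 417.3, 1, 9))
  expect_lt(abs(band_position(sp1, 417, 8) - 417.3), 0.2)
  # a symmetric peak centered exactly on a grid node is recovered exactly
  node <- grid[13]
  sp2 <- spectrum(grid, line_shape(grid, node, 1, 9))
  expect_equal(band_position(sp2, node, 8), node)
  # monotone window has no apex
  sp3 <- spectrum(grid, grid / 1800)
  expect_error(band_position(sp3, 1000, 8), "no-peak")
})
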