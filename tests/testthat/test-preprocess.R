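test_that("airPLS leaves a flat signal untouched and rejects bad input", {
  y <- rep(5, 300)
  z <- airpls_baseline(y)
  expect_lt(max(abs(z - 5)), 1e-6 * 5)
  expect_error(airpls_baseline(c(1, NA, 3, 4, 5)), "finite")
  expect_error(airpls_baseline(c(1, 2, 3)), "length")
  expect_error(airpls_settings(lambda = -1), "lambda")
  expect_error(airpls_settings(convergence_ratio = 2), "convergence_ratio")
})

test_that("airPLS recovers an injected linear baseline under a peak", {
  x <- seq(400, 1800, length.out = 1200)
  ramp <- 0.2 + 0.4 * (x - 400) / 1400
  peak_amp <- 1
  # narrow Gaussian peak: the Lorentzian-free case the oracle prescribes
  y <- ramp + line_shape(x, 1100, peak_amp, 10, 0, 0)
  z <- airpls_baseline(y)
  # the injected baseline is the oracle: recovered within 2% of the peak
  # amplitude everywhere
  expect_lt(max(abs(z - ramp)), 0.02 * peak_amp)
  # peak is preserved: corrected signal matches the injected peak closely
  corrected <- y - z
  expect_lt(max(abs(corrected - line_shape(x, 1100, peak_amp, 10, 0, 0))),
            0.02 * peak_amp)
})

test_that("airPLS removes a pure ramp almost completely", {
  x <- seq_len(600)
  y <- 1 + 0.01 * x
  z <- airpls_baseline(y)
  expect_lt(sum(abs(y - z)), 1e-3 * sum(abs(y)))
})

test_that("min-max normalization maps to [0, 1] and is idempotent", {
  expect_equal(minmax_normalize(c(0, 2, 4)), c(0, 0.5, 1))
  v <- minmax_normalize(stats::rnorm(50))
  expect_equal(minmax_normalize(v), v)
  expect_equal(range(v), c(0, 1))
  expect_error(minmax_normalize(c(5, 5, 5)), "degenerate")
})

test_that("canonical regridding preserves values and detects gaps", {
  grid <- canonical_grid()
  expect_length(grid, 1200L)
  expect_equal(range(grid), c(400, 1800))

  y <- line_shape(grid, 1000, 1, 20)
  sp <- spectrum(grid, y)
  out <- to_canonical_grid(sp)
  expect_equal(out$intensities, y)
  expect_identical(out$meta$canonical, "true")

  # a double-resolution spectrum agrees at shared nodes
  fine <- seq(400, 1800, length.out = 2399)
  sp2 <- to_canonical_grid(spectrum(fine, line_shape(fine, 1000, 1, 20)))
  shared <- seq(1, 2399, by = 2)
  expect_lt(max(abs(sp2$intensities - line_shape(grid, 1000, 1, 20))),
            1e-9 + 1e-4)

  expect_error(to_canonical_grid(spectrum(seq(600, 1800, 2),
                                          rep(1, 601))), "coverage")
})

test_that("the full pipeline lands in [0, 1] with max exactly 1", {
  cfg <- synthetic_config()
  for (nm in c("MPBA blank", "glucose", "GlcCer8", "GalCer24:1")) {
    lab <- parse_nomenclature(nm)
    sp <- generate_spectrum(lab, 1e-4, cfg, seed = 3)
    pp <- preprocess_spectrum(sp)
    expect_length(pp, 1200L)
    expect_equal(max(pp$intensities), 1)
    expect_gte(min(pp$intensities), 0)
    expect_identical(pp$meta$canonical, "true")
  }
})

test_that("repeated preprocessing of the same input is reproducible", {
  cfg <- synthetic_config()
  sp <- generate_spectrum(parse_nomenclature("GalCer16"), 1e-4, cfg,
                          seed = 5)
  expect_identical(preprocess_spectrum(sp)$intensities,
                   preprocess_spectrum(sp)$intensities)
})
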