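test_that("noise-free dilution series calibrate almost perfectly", {
  fsq <- fixture_cache("fs-quant-zero", {
    dilution_series_features("GlcCer12", 4L, zero_noise_config(), 300L)
  })
  qm <- train_quant(fsq, seed = 2)
  # the residual reflects feature-extraction nonlinearity across decades,
  # not noise: R2 is 1.00 at printed precision
  expect_gt(qm$r2, 0.995)
  expect_equal(round(qm$r2, 2), 1)
  expect_lt(qm$rmsep, 0.15)
  # single concentration level is degenerate
  one <- list(features = fsq$features[1:4, ], labels = fsq$labels[1:4],
              analyte = fsq$analyte[1:4], concentration = rep(1e-4, 4))
  class(one) <- "feature_set"
  expect_error(train_quant(one), "degenerate")
})

test_that("quantification is scale-equivariant in log space", {
  fsq <- fixture_cache("fs-quant-zero", {
    dilution_series_features("GlcCer12", 4L, zero_noise_config(), 300L)
  })
  shifted <- fsq
  shifted$concentration <- fsq$concentration * 10
  qm1 <- train_quant(fsq, seed = 2)
  qm2 <- train_quant(shifted, seed = 2)
  p1 <- predict_concentration(fsq$features[5:10, ], qm1)$predicted_M
  p2 <- predict_concentration(fsq$features[5:10, ], qm2)$predicted_M
  expect_equal(log10(p2) - log10(p1), rep(1, 6), tolerance = 1e-6)
})

test_that("percent difference follows the absolute-relative formula", {
  fsq <- fixture_cache("fs-quant-zero", {
    dilution_series_features("GlcCer12", 4L, zero_noise_config(), 300L)
  })
  qm <- train_quant(fsq, seed = 2)
  out <- predict_concentration(fsq$features[1, ], qm, truth = 1e-8)
  expect_equal(out$percent_difference,
               abs(1e-8 - out$predicted_M) / 1e-8 * 100)
  # predicted == truth gives exactly zero
  out2 <- predict_concentration(fsq$features[1, ], qm,
                                truth = out$predicted_M)
  expect_equal(out2$percent_difference, 0)
  # hand-checked example: truth 1e-8, predicted 1.07e-8 -> 7%
  expect_equal(abs(1e-8 - 1.07e-8) / 1e-8 * 100, 7)
})

test_that("noise-free mixture calibration is nearly exact and monotone", {
  cfg0 <- zero_noise_config()
  cal <- generate_mixture_set(c(0, 25, 50, 75, 100), replicates = 4L,
                              cfg = cfg0, seed = 5)
  fsm <- fixture_cache("fs-mix-zero", featurize_set(cal$set))
  mm <- train_multiplex(fsm, cal$frac_gal, seed = 2)
  expect_lt(mm$rmse_cal, 1)
  expect_gt(mm$r2_cv, 0.999)
  # predictions increase monotonically with the true mol fraction
  probe <- t(vapply(c(10, 35, 65, 90), function(f)
    featurize_spectrum(generate_mixture(f, cfg = cfg0)), numeric(95)))
  pr <- predict_mixture(probe, mm)
  expect_true(all(diff(pr$samples$gal_uM) > 0))
  # complement rule: the pair always totals 100 uM
  expect_equal(pr$samples$gal_uM + pr$samples$glc_uM, rep(100, 4))
  # 0% gal blind: glc close to the full 100 uM
  pure <- featurize_spectrum(generate_mixture(0, cfg = cfg0))
  pr0 <- predict_mixture(pure, mm)
  expect_gt(pr0$glc_uM_mean, 97)
  expect_error(train_multiplex(fsm[1:2], c(0, 100)), "3 calibration")
})

test_that("analytical enhancement factor is the signal-per-conc ratio", {
  expect_equal(aef(1, 1, 1, 1), 1)
  expect_equal(aef(10, 1, 1, 0.1), 100)
  expect_equal(aef(250, 5, 1, 1e-4), 5e5)
  expect_error(aef(1, 0, 1, 1), "i_raman")
})
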