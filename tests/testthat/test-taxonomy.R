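hp_fast <- taxonomy_hyperparameters(num_trees = 400L)

test_that("training validates stage composition and is deterministic", {
  fs0 <- zero_noise_features()
  keep <- fs0$analyte != "MPBA blank"
  no_blank <- list(features = fs0$features[keep, , drop = FALSE],
                   labels = fs0$labels[keep])
  expect_error(train_taxonomy(no_blank, hp_fast, seed = 1), "stage1")

  model_a <- train_taxonomy(fs0, hp_fast, seed = 7)
  model_b <- train_taxonomy(fs0, hp_fast, seed = 7)
  probe <- fs0$features[fs0$analyte == "GalCer12", , drop = FALSE]
  expect_identical(predict_taxonomy(probe, model_a),
                   predict_taxonomy(probe, model_b))
})

test_that("routing assembles identities with probabilities that sum to 1", {
  fs0 <- zero_noise_features()
  model <- train_taxonomy(fs0, hp_fast, seed = 7)

  blank_fv <- fs0$features[fs0$analyte == "MPBA blank", ][1, ]
  pb <- predict_sample(blank_fv, model)
  expect_equal(pb$nomenclature, "MPBA blank")
  expect_equal(pb$path[1], "blank")
  expect_equal(sum(pb$stages$stage1), 1)

  glc8_fv <- fs0$features[fs0$analyte == "GlcCer8", ][1, ]
  p8 <- predict_sample(glc8_fv, model)
  expect_equal(p8$path,
               c("epimer", "cerebroside", "saturated", "GlcCer"))
  expect_equal(p8$nomenclature, "GlcCer8")
  expect_lt(abs(p8$chain_raw - 8), 1.5)
  for (st in p8$stages) expect_equal(sum(st), 1)

  mono_fv <- fs0$features[fs0$analyte == "glucose", ][1, ]
  expect_equal(predict_sample(mono_fv, model)$nomenclature,
               "monosaccharide")

  expect_error(predict_taxonomy(matrix(0, 1, 3), model), "schema")
})

test_that("low-confidence stages are flagged but never halt routing", {
  fs0 <- zero_noise_features()
  model <- train_taxonomy(fs0, hp_fast, seed = 7)
  fv <- fs0$features[fs0$analyte == "GalCer16", ][1, ]
  tab <- predict_taxonomy(matrix(fv, 1, dimnames = list(NULL, names(fv))),
                          model)
  # synthetic check of the flag rule itself: perturb the table the way a
  # 0.48/0.52 stage-3 vote would look
  expect_true(is.data.frame(tab))
  expect_equal(tab$nomenclature, "GalCer16")
  # a probe mixing the two hexose signatures drives stage 4 toward 0.5;
  # the prediction still routes and carries the flag when <= 0.5
  glc_fv <- colMeans(fs0$features[fs0$analyte == "GlcCer16", , drop = FALSE])
  mix <- 0.5 * fv + 0.5 * glc_fv
  tab2 <- predict_taxonomy(matrix(mix, 1, dimnames = list(NULL, names(fv))),
                           model)
  expect_false(is.na(tab2$stage4))
  if (max(tab2$p_glc, tab2$p_gal) <= 0.5) {
    expect_match(tab2$flags, "stage4")
  }
})

test_that("majority voting takes modal classes and mean chain length", {
  fs0 <- zero_noise_features()
  model <- train_taxonomy(fs0, hp_fast, seed = 7)
  reps <- fs0$features[fs0$analyte == "GalCer12", , drop = FALSE]
  cons <- predict_majority(reps, model)
  expect_equal(cons$consensus$stage4, "GalCer")
  expect_equal(cons$chain_rounded, 12L)
  expect_equal(cons$nomenclature, "GalCer12")
  # single replicate consensus equals that prediction
  single <- predict_majority(reps[1, , drop = FALSE], model)
  expect_equal(single$nomenclature,
               predict_sample(reps[1, ], model)$nomenclature)
})

test_that("ablating a component makes its characteristic unrecoverable", {
  fs0 <- zero_noise_features()
  model <- train_taxonomy(fs0, hp_fast, seed = 7)
  fv <- fs0$features[fs0$analyte == "GlcCer18", ][1, ]

  no_hexose <- taxonomy_ablate(model, "stage4")
  p <- predict_sample(fv, no_hexose)
  expect_true(is.na(p$stages$stage4[["GlcCer"]]))
  expect_match(p$nomenclature, "hexose undetermined")

  no_reg <- taxonomy_ablate(taxonomy_ablate(model, "reg_glc"), "reg_gal")
  p2 <- predict_sample(fv, no_reg)
  expect_true(is.na(p2$chain_raw))
  expect_match(p2$nomenclature, "chain undetermined")
})

test_that("forward prediction validates its hold-out argument", {
  fs0 <- zero_noise_features()
  expect_error(forward_prediction(fs0, "glucose", hp = hp_fast),
               "11 cerebrosides")
  sub <- list(features = fs0$features[fs0$analyte != "GlcCer8", ],
              labels = fs0$labels[fs0$analyte != "GlcCer8"],
              analyte = fs0$analyte[fs0$analyte != "GlcCer8"])
  expect_error(forward_prediction(sub, "GlcCer8", hp = hp_fast), "absent")
})

test_that("hold-outs are recovered perfectly on noise-free data", {
  fs0 <- zero_noise_features()
  for (h in c("GlcCer16", "GalCer24:1", "GlcCer24:1")) {
    fp <- forward_prediction(fs0, h, iterations = 1L, hp = hp_fast,
                             seed = 3)
    expect_equal(fp$overall_accuracy, 1, info = h)
    expect_equal(unname(fp$stage_accuracy), rep(1, 4), info = h)
  }
})

test_that("the cv5 protocol runs and reports the same structure", {
  fs0 <- zero_noise_features()
  fp <- forward_prediction(fs0, "GalCer16", iterations = 2L,
                           protocol = "cv5", hp = hp_fast, seed = 3)
  expect_equal(nrow(fp$per_iteration), 2L)
  expect_equal(fp$overall_accuracy, 1)
})

test_that("confusion-count metrics follow the standard formulas", {
  m <- classification_metrics(tp = 9, fp = 0, tn = 0, fn = 1)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$precision, 1)
  expect_equal(m$f1, 2 * 1 * 0.9 / 1.9)
  # all-negative input leaves precision undefined rather than erroring
  m2 <- classification_metrics(0, 0, 10, 0)
  expect_equal(m2$accuracy, 1)
  expect_true(is.na(m2$precision))
  expect_true("precision" %in% m2$undefined)
  m3 <- classification_metrics(25, 0, 30, 0)
  expect_equal(m3$accuracy, 1)
  expect_equal(m3$f1, 1)
})

test_that("the 2-D embedding is deterministic and shape-correct", {
  fs0 <- zero_noise_features()
  coords <- embed_2d(fs0$features)
  expect_equal(dim(coords), c(nrow(fs0$features), 2L))
  expect_identical(coords, embed_2d(fs0$features))
  # duplicated rows (drawn from three different classes) coincide
  dup <- fs0$features[c(1, 1, 6, 6, 11, 11), ]
  cd <- embed_2d(dup)
  expect_lt(max(abs(cd[1, ] - cd[2, ])), 1e-8)
  expect_error(embed_2d(fs0$features[1:2, ]), "at least 3")
  expect_error(embed_2d(fs0$features, method = "tsne"), "t-SNE")
})
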