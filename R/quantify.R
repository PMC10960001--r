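#' Train a single-analyte concentration model
#'
#' Regression of log10 molar concentration on the PCA-compressed 95-feature
#' vectors of one analyte's dilution series (an epsilon-SVR, like the
#' chain-length regressors). The series is stratified by concentration into
#' a 75% train / 25% test split in one iteration; the held-out quarter
#' provides the calibration statistics.
#'
#' @param fs a `feature_set` of one analyte across the dilution series.
#' @param hp a [taxonomy_hyperparameters()] (only the SVR/PCA entries are
#'   used).
#' @param train_frac training fraction (default 0.75).
#' @param seed integer seed for the stratified split.
#' @return list of class `"quant_model"`: the fitted regressor, the test
#'   split statistics `r2` (squared Pearson correlation between predicted
#'   and true log10 concentration) and `rmsep` (log10 units), the analyte
#'   name and calibrated concentration range.
#' @export
train_quant <- function(fs, hp = taxonomy_hyperparameters(),
                        train_frac = 0.75, seed = 1L) {
  conc <- fs$concentration
  if (any(is.na(conc))) stop("all spectra need concentrations", call. = FALSE)
  levels_present <- sort(unique(conc))
  if (length(levels_present) < 2L) {
    stop("degenerate series: need at least 2 concentration levels",
         call. = FALSE)
  }
  y <- log10(conc)
  set.seed(as.integer(seed))
  train_idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    size <- ceiling(train_frac * length(ix))
    if (size >= length(ix) && length(ix) > 1L) size <- length(ix) - 1L
    sample(ix, max(1L, size))
  }))
  test_idx <- setdiff(seq_along(y), train_idx)
  model <- fit_pca_svr(fs$features[train_idx, , drop = FALSE], y[train_idx],
                       hp, seed = seed + 7L)
  if (length(test_idx) >= 2L) {
    pred <- predict_pca_svr(model, fs$features[test_idx, , drop = FALSE])
    r2 <- stats::cor(pred, y[test_idx])^2
    rmsep <- sqrt(mean((pred - y[test_idx])^2))
  } else {
    pred <- predict_pca_svr(model, fs$features[train_idx, , drop = FALSE])
    r2 <- stats::cor(pred, y[train_idx])^2
    rmsep <- NA_real_
  }
  structure(list(model = model,
                 analyte = unique(fs$analyte),
                 r2 = r2, rmsep = rmsep,
                 conc_range = range(levels_present),
                 train_idx = sort(train_idx), test_idx = sort(test_idx)),
            class = "quant_model")
}

#' @export
print.quant_model <- function(x, ...) {
  cat(sprintf("concentration model for %s: R2 = %.4f, RMSEP = %.3f log10 units\n",
              paste(x$analyte, collapse = "/"), x$r2, x$rmsep))
  cat(sprintf("  calibrated range: %g to %g M\n", x$conc_range[1],
              x$conc_range[2]))
  invisible(x)
}

#' Predict molar concentrations from feature vectors
#'
#' Inverse-log transform of the regression output. Estimates outside
#' one decade beyond the calibrated range are flagged (`out_of_range`) but
#' still returned. When the true concentration is supplied, the percent
#' difference `|actual - predicted| / actual * 100` is reported per
#' spectrum.
#'
#' @param features matrix of feature vectors (or one named vector).
#' @param qm a `quant_model`.
#' @param truth optional true molar concentration(s).
#' @return data.frame with `predicted_M`, `out_of_range`, and when truth is
#'   given, `truth_M` and `percent_difference`.
#' @export
predict_concentration <- function(features, qm, truth = NULL) {
  stopifnot(inherits(qm, "quant_model"))
  if (inherits(features, "feature_set")) features <- features$features
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL,
                                                   names(features)))
  pred <- 10^predict_pca_svr(qm$model, features)
  out <- data.frame(
    predicted_M = pred,
    out_of_range = pred < qm$conc_range[1] / 10 | pred > qm$conc_range[2] * 10)
  if (!is.null(truth)) {
    out$truth_M <- truth
    out$percent_difference <- abs(truth - pred) / truth * 100
  }
  out
}

#' Train the binary-mixture composition model
#'
#' Regression of GalCer24:1 mol percent on the mixture feature vectors of a
#' calibration series at fixed total concentration. The series is
#' stratified into an 80% train / 20% cross-validation split; the
#' cross-validation fifth provides `r2_cv` and `rmse_cal` (mol%). The
#' GlcCer24:1 share is always derived by complement so predicted pairs sum
#' to the total.
#'
#' @param fs a `feature_set` of calibration mixtures.
#' @param frac_gal GalCer24:1 mol percent of each calibration spectrum.
#' @param total total molar concentration of every mixture (default 1e-4,
#'   i.e. 100 uM).
#' @param hp a [taxonomy_hyperparameters()].
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @return list of class `"multiplex_model"`.
#' @export
train_multiplex <- function(fs, frac_gal, total = 1e-4,
                            hp = taxonomy_hyperparameters(),
                            train_frac = 0.8, seed = 1L) {
  if (length(unique(frac_gal)) < 3L) {
    stop("need at least 3 calibration compositions", call. = FALSE)
  }
  set.seed(as.integer(seed))
  train_idx <- unlist(lapply(split(seq_along(frac_gal), frac_gal),
                             function(ix) {
    size <- ceiling(train_frac * length(ix))
    if (size >= length(ix) && length(ix) > 1L) size <- length(ix) - 1L
    sample(ix, max(1L, size))
  }))
  cv_idx <- setdiff(seq_along(frac_gal), train_idx)
  model <- fit_pca_svr(fs$features[train_idx, , drop = FALSE],
                       frac_gal[train_idx], hp, seed = seed + 7L)
  pred_cv <- predict_pca_svr(model, fs$features[cv_idx, , drop = FALSE])
  structure(list(model = model, total = total,
                 r2_cv = stats::cor(pred_cv, frac_gal[cv_idx])^2,
                 rmse_cal = sqrt(mean((pred_cv - frac_gal[cv_idx])^2))),
            class = "multiplex_model")
}

#' @export
print.multiplex_model <- function(x, ...) {
  cat(sprintf("multiplex model: cross-validation R2 = %.4f, RMSE = %.2f mol%%\n",
              x$r2_cv, x$rmse_cal))
  invisible(x)
}

#' Predict the composition of blind binary mixtures
#'
#' Converts the predicted GalCer24:1 mol percent to micromolar assuming the
#' model's fixed total; the GlcCer24:1 concentration is the complement, so
#' every predicted pair sums to the total. Predictions are clipped to
#' \[0, total\] with a flag. When the actual mol percent is given, per-set
#' mean +/- SD and absolute differences are reported.
#'
#' @param features matrix of blind-mixture feature vectors.
#' @param mm a `multiplex_model`.
#' @param actual_frac_gal optional true GalCer24:1 mol percent (scalar or
#'   vector).
#' @return list of class `"mixture_prediction"`: per-sample table plus
#'   `gal_uM_mean`, `gal_uM_sd`, `glc_uM_mean`, `glc_uM_sd` and, with
#'   truth, `gal_abs_diff_uM` / `glc_abs_diff_uM` (of the means).
#' @export
predict_mixture <- function(features, mm, actual_frac_gal = NULL) {
  stopifnot(inherits(mm, "multiplex_model"))
  if (inherits(features, "feature_set")) features <- features$features
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL,
                                                   names(features)))
  total_uM <- mm$total * 1e6
  raw <- predict_pca_svr(mm$model, features)
  clipped <- pmin(pmax(raw, 0), 100)
  tab <- data.frame(
    frac_gal_pred = clipped,
    gal_uM = clipped / 100 * total_uM,
    glc_uM = (100 - clipped) / 100 * total_uM,
    clipped = raw < 0 | raw > 100)
  out <- list(samples = tab, total_uM = total_uM,
              gal_uM_mean = mean(tab$gal_uM), gal_uM_sd = stats::sd(tab$gal_uM),
              glc_uM_mean = mean(tab$glc_uM), glc_uM_sd = stats::sd(tab$glc_uM))
  if (!is.null(actual_frac_gal)) {
    actual_gal_uM <- mean(actual_frac_gal) / 100 * total_uM
    out$actual_gal_uM <- actual_gal_uM
    out$actual_glc_uM <- total_uM - actual_gal_uM
    out$gal_abs_diff_uM <- abs(out$gal_uM_mean - actual_gal_uM)
    out$glc_abs_diff_uM <- abs(out$glc_uM_mean - out$actual_glc_uM)
    out$samples$gal_abs_err_uM <- abs(tab$gal_uM - actual_frac_gal / 100 *
                                        total_uM)
  }
  structure(out, class = "mixture_prediction")
}

#' @export
print.mixture_prediction <- function(x, ...) {
  cat(sprintf("mixture prediction (total %.0f uM): GalCer24:1 %.1f +/- %.1f uM, GlcCer24:1 %.1f +/- %.1f uM\n",
              x$total_uM, x$gal_uM_mean, x$gal_uM_sd, x$glc_uM_mean,
              x$glc_uM_sd))
  if (!is.null(x$gal_abs_diff_uM)) {
    cat(sprintf("  absolute difference: Gal %.2f uM, Glc %.2f uM\n",
                x$gal_abs_diff_uM, x$glc_abs_diff_uM))
  }
  invisible(x)
}

#' Analytical enhancement factor
#'
#' `AEF = (I_SERS / I_Raman) * (C_Raman / C_SERS)`: the signal-per-
#' concentration gain of the SERS substrate over normal Raman.
#'
#' @param i_sers,i_raman band intensities under SERS and normal Raman.
#' @param c_raman,c_sers the corresponding analyte concentrations.
#' @return numeric enhancement factor.
#' @export
aef <- function(i_sers, i_raman, c_raman, c_sers) {
  vals <- c(i_sers = i_sers, i_raman = i_raman, c_raman = c_raman,
            c_sers = c_sers)
  if (any(vals <= 0)) {
    stop("all AEF inputs must be positive, got ",
         paste(names(vals)[vals <= 0], collapse = ", "), call. = FALSE)
  }
  (i_sers / i_raman) * (c_raman / c_sers)
}
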