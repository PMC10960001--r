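#' Hyperparameters for the taxonomy cascade
#'
#' Defaults follow the study protocol for the random-forest stages: 1000
#' trees, `sqrt(p)` candidate features per split, maximum depth 10, nodes
#' with fewer than 5 samples are not split. The chain-length regressors are
#' epsilon-SVRs on PCA-compressed features (components explaining 99% of
#' variance, capped at 15). The SVR kernel defaults to linear because
#' forward prediction must extrapolate to chain lengths absent from
#' training.
#'
#' @param num_trees,max_depth,min_node,mtry random-forest controls
#'   (`mtry = NULL` means `floor(sqrt(p))`).
#' @param svr_kernel,svr_cost,svr_epsilon support-vector regressor controls.
#' @param pca_var,pca_max PCA compression: keep the smallest number of
#'   components explaining `pca_var` of the variance, at most `pca_max`.
#' @return list of class `"taxonomy_hp"`.
#' @export
taxonomy_hyperparameters <- function(num_trees = 1000L, max_depth = 10L,
                                     min_node = 5L, mtry = NULL,
                                     svr_kernel = "linear", svr_cost = 1,
                                     svr_epsilon = 0.01,
                                     pca_var = 0.99, pca_max = 15L) {
  structure(list(num_trees = as.integer(num_trees),
                 max_depth = as.integer(max_depth),
                 min_node = as.integer(min_node), mtry = mtry,
                 svr_kernel = svr_kernel, svr_cost = svr_cost,
                 svr_epsilon = svr_epsilon,
                 pca_var = pca_var, pca_max = as.integer(pca_max)),
            class = "taxonomy_hp")
}

label_field <- function(labels, field) {
  vapply(labels, function(l) {
    v <- l[[field]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) NA else v
  }, if (field %in% c("saturation", "chain_length")) NA_integer_
     else NA_character_)
}

train_rf_stage <- function(x, y, hp, seed, stage_name) {
  y <- factor(y)
  if (nlevels(y) < 2L) {
    stop("training error: stage '", stage_name,
         "' has a single class (", levels(y), ")", call. = FALSE)
  }
  ranger::ranger(
    x = x, y = y, probability = TRUE,
    num.trees = hp$num_trees,
    mtry = if (is.null(hp$mtry)) floor(sqrt(ncol(x))) else hp$mtry,
    max.depth = hp$max_depth, min.node.size = hp$min_node,
    seed = seed, num.threads = 1L)
}

# unit-aware standardization floors: features whose training spread is
# below these are effectively constant, and dividing by a numerically tiny
# SD would blow up any probe that deviates there (a hazard for noise-free
# fixtures and for classes outside the training manifold)
attribute_sd_floor <- function(feature_names) {
  floors <- c(position = 0.1, intensity = 0.01, fwhm = 0.1,
              skew = 0.01, ratio = 0.01)
  suffix <- sub("^p[0-9]+_", "", feature_names)
  unname(floors[suffix])
}

# PCA compression followed by an epsilon-SVR. Features are put on fixed,
# unit-aware scales (1 cm^-1 for positions and widths, 0.1 for the
# dimensionless attributes) rather than standardized by the training SD:
# data-driven standardization inflates low-variance nuisance directions
# into unit variance, and a regressor interpolating few classes will
# happily abuse them
fit_pca_svr <- function(x, y, hp, seed) {
  mu <- colMeans(x)
  sds <- attribute_sd_floor(colnames(x)) * 10
  xs <- sweep(sweep(x, 2, mu), 2, sds, "/")
  pca <- stats::prcomp(xs, center = FALSE)
  cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  ncomp <- max(2L, min(which(cumvar >= hp$pca_var)[1], hp$pca_max,
                       ncol(pca$x)))
  scores <- pca$x[, seq_len(ncomp), drop = FALSE]
  set.seed(seed)
  svr <- e1071::svm(x = scores, y = y, type = "eps-regression",
                    kernel = hp$svr_kernel, cost = hp$svr_cost,
                    epsilon = hp$svr_epsilon)
  list(mu = mu, sds = sds, rotation = pca$rotation[, seq_len(ncomp),
                                                   drop = FALSE],
       svr = svr)
}

predict_pca_svr <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$mu), 2, model$sds, "/")
  scores <- xs %*% model$rotation
  as.numeric(stats::predict(model$svr, scores))
}

#' Train the five-level chemical taxonomy
#'
#' Trains four sequential binary random-forest classifiers and two
#' chain-length SVRs on a featurized dataset. Each stage models a
#' conditional question along the routing path, so stage training sets are
#' label-filtered subsets: stage 1 (blank vs epimer) sees everything,
#' stage 2 (monosaccharide vs cerebroside) excludes blanks, stages 3
#' (saturated vs unsaturated) and 4 (GlcCer vs GalCer) see cerebrosides
#' only, and each regressor sees cerebrosides of its own hexose with the
#' acyl chain length as target.
#'
#' @param fs a `feature_set` from [featurize_set()], or a list with
#'   `features` (matrix) and `labels` (list of [analyte_label()]).
#' @param hp a [taxonomy_hyperparameters()].
#' @param seed integer seed; each sub-model gets a derived seed recorded in
#'   the metadata.
#' @return list of class `"taxonomy_model"`.
#' @export
train_taxonomy <- function(fs, hp = taxonomy_hyperparameters(), seed = 1L) {
  x <- fs$features
  labels <- fs$labels
  category <- label_field(labels, "category")
  hexose <- label_field(labels, "hexose")
  saturation <- label_field(labels, "saturation")
  chain <- label_field(labels, "chain_length")
  seed <- as.integer(seed)

  is_epimer <- category != "blank"
  is_cer <- category == "cerebroside"

  stage1 <- train_rf_stage(x, ifelse(is_epimer, "epimer", "blank"),
                           hp, seed + 11L, "stage1 blank vs epimer")
  stage2 <- train_rf_stage(x[is_epimer, , drop = FALSE],
                           ifelse(is_cer[is_epimer], "cerebroside",
                                  "monosaccharide"),
                           hp, seed + 22L,
                           "stage2 monosaccharide vs cerebroside")
  stage3 <- train_rf_stage(x[is_cer, , drop = FALSE],
                           ifelse(saturation[is_cer] > 0L, "unsaturated",
                                  "saturated"),
                           hp, seed + 33L, "stage3 saturated vs unsaturated")
  stage4 <- train_rf_stage(x[is_cer, , drop = FALSE],
                           ifelse(hexose[is_cer] == "glc", "GlcCer",
                                  "GalCer"),
                           hp, seed + 44L, "stage4 GlcCer vs GalCer")
  glc_rows <- is_cer & hexose == "glc"
  gal_rows <- is_cer & hexose == "gal"
  if (!any(glc_rows) || !any(gal_rows)) {
    stop("training error: chain-length regressors need cerebrosides of ",
         "both hexoses", call. = FALSE)
  }
  reg_glc <- fit_pca_svr(x[glc_rows, , drop = FALSE],
                         as.numeric(chain[glc_rows]), hp, seed + 55L)
  reg_gal <- fit_pca_svr(x[gal_rows, , drop = FALSE],
                         as.numeric(chain[gal_rows]), hp, seed + 66L)

  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 stage4 = stage4, reg_glc = reg_glc, reg_gal = reg_gal,
                 schema = colnames(x),
                 meta = list(seed = seed, hp = hp, n_train = nrow(x),
                             classes = table(vapply(labels, nomenclature,
                                                    character(1))))),
            class = "taxonomy_model")
}

#' Remove one component from a trained taxonomy
#'
#' Ablation utility: with a stage removed the corresponding structural
#' characteristic becomes unrecoverable (predictions report `NA` there),
#' mirroring what happens to the framework if a classifier or regressor is
#' omitted.
#'
#' @param model a `taxonomy_model`.
#' @param component one of `"stage1"`..`"stage4"`, `"reg_glc"`, `"reg_gal"`.
#' @return the model with that component set to `NULL`.
#' @export
taxonomy_ablate <- function(model, component) {
  stopifnot(inherits(model, "taxonomy_model"),
            component %in% c("stage1", "stage2", "stage3", "stage4",
                             "reg_glc", "reg_gal"))
  model[[component]] <- NULL
  model
}

rf_probs <- function(stage, x) {
  if (is.null(stage)) {
    return(matrix(NA_real_, nrow(x), 2L))
  }
  stats::predict(stage, data = x, num.threads = 1L)$predictions
}

#' Route feature vectors through the taxonomy
#'
#' Batch prediction: every spectrum is scored by all four stages and both
#' regressors; the routing path, assembled nomenclature and low-confidence
#' flags are derived per row. A stage whose winning probability is <= 0.5
#' is flagged but never halts routing.
#'
#' @param features numeric matrix (n x 95) or a `feature_set`.
#' @param model a `taxonomy_model`.
#' @return data.frame with per-stage probabilities (`p_blank`, `p_epimer`,
#'   `p_mono`, `p_cer`, `p_sat`, `p_unsat`, `p_glc`, `p_gal`), stage
#'   winners, `chain_raw`, `chain_rounded`, `nomenclature`, `flags`.
#' @export
predict_taxonomy <- function(features, model) {
  stopifnot(inherits(model, "taxonomy_model"))
  if (inherits(features, "feature_set")) features <- features$features
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL,
                                                   names(features)))
  if (!identical(colnames(features), model$schema)) {
    stop("feature schema mismatch: columns differ from the training schema",
         call. = FALSE)
  }
  n <- nrow(features)
  get2 <- function(p, a, b) {
    if (all(is.na(p))) return(cbind(rep(NA_real_, n), rep(NA_real_, n)))
    cbind(p[, a], p[, b])
  }
  p1 <- rf_probs(model$stage1, features)
  if (!is.null(model$stage1)) p1 <- get2(p1, "blank", "epimer")
  p2 <- rf_probs(model$stage2, features)
  if (!is.null(model$stage2)) p2 <- get2(p2, "monosaccharide", "cerebroside")
  p3 <- rf_probs(model$stage3, features)
  if (!is.null(model$stage3)) p3 <- get2(p3, "saturated", "unsaturated")
  p4 <- rf_probs(model$stage4, features)
  if (!is.null(model$stage4)) p4 <- get2(p4, "GlcCer", "GalCer")
  chain_glc <- if (is.null(model$reg_glc)) rep(NA_real_, n) else
    predict_pca_svr(model$reg_glc, features)
  chain_gal <- if (is.null(model$reg_gal)) rep(NA_real_, n) else
    predict_pca_svr(model$reg_gal, features)

  out <- data.frame(
    p_blank = p1[, 1], p_epimer = p1[, 2],
    p_mono = p2[, 1], p_cer = p2[, 2],
    p_sat = p3[, 1], p_unsat = p3[, 2],
    p_glc = p4[, 1], p_gal = p4[, 2]
  )
  out$stage1 <- ifelse(is.na(out$p_epimer), NA,
                       ifelse(out$p_epimer >= out$p_blank, "epimer", "blank"))
  out$stage2 <- ifelse(is.na(out$p_cer), NA,
                       ifelse(out$p_cer >= out$p_mono, "cerebroside",
                              "monosaccharide"))
  out$stage3 <- ifelse(is.na(out$p_unsat), NA,
                       ifelse(out$p_unsat > out$p_sat, "unsaturated",
                              "saturated"))
  out$stage4 <- ifelse(is.na(out$p_gal), NA,
                       ifelse(out$p_gal > out$p_glc, "GalCer", "GlcCer"))
  out$chain_raw <- ifelse(is.na(out$stage4), NA_real_,
                          ifelse(out$stage4 == "GlcCer", chain_glc,
                                 chain_gal))
  out$chain_rounded <- ifelse(is.na(out$chain_raw), NA_integer_,
                              as.integer(round(out$chain_raw)))

  nomen <- character(n)
  flags <- character(n)
  for (i in seq_len(n)) {
    fl <- character()
    if (!is.na(out$stage1[i]) && max(out$p_blank[i], out$p_epimer[i]) <= 0.5)
      fl <- c(fl, "stage1")
    if (!is.na(out$stage2[i]) && max(out$p_mono[i], out$p_cer[i]) <= 0.5)
      fl <- c(fl, "stage2")
    if (!is.na(out$stage3[i]) && max(out$p_sat[i], out$p_unsat[i]) <= 0.5)
      fl <- c(fl, "stage3")
    if (!is.na(out$stage4[i]) && max(out$p_glc[i], out$p_gal[i]) <= 0.5)
      fl <- c(fl, "stage4")
    flags[i] <- paste(fl, collapse = ",")
    nomen[i] <- if (is.na(out$stage1[i])) {
      NA_character_
    } else if (out$stage1[i] == "blank") {
      "MPBA blank"
    } else if (is.na(out$stage2[i])) {
      "epimer (undetermined)"
    } else if (out$stage2[i] == "monosaccharide") {
      "monosaccharide"
    } else if (is.na(out$stage4[i])) {
      "cerebroside (hexose undetermined)"
    } else {
      stem <- out$stage4[i]
      sat <- if (!is.na(out$stage3[i]) && out$stage3[i] == "unsaturated")
        ":1" else ""
      if (is.na(out$chain_rounded[i])) paste0(stem, " (chain undetermined)")
      else paste0(sub("Cer$", "Cer", stem), out$chain_rounded[i], sat)
    }
  }
  out$nomenclature <- nomen
  out$flags <- flags
  out
}

#' Predict one spectrum's identity
#'
#' Single-sample wrapper around [predict_taxonomy()] returning a structured
#' prediction: per-stage probability pairs, the routing path, raw and
#' rounded chain length, assembled nomenclature and low-confidence flags.
#'
#' @param fv named numeric vector of 95 features (schema of
#'   [feature_schema()]).
#' @param model a `taxonomy_model`.
#' @return list of class `"taxonomy_prediction"`.
#' @export
predict_sample <- function(fv, model) {
  row <- predict_taxonomy(fv, model)
  path <- c(row$stage1, if (!is.na(row$stage1) && row$stage1 == "epimer")
    c(row$stage2, if (!is.na(row$stage2) && row$stage2 == "cerebroside")
      c(row$stage3, row$stage4)))
  structure(list(
    stages = list(
      stage1 = c(blank = row$p_blank, epimer = row$p_epimer),
      stage2 = c(monosaccharide = row$p_mono, cerebroside = row$p_cer),
      stage3 = c(saturated = row$p_sat, unsaturated = row$p_unsat),
      stage4 = c(GlcCer = row$p_glc, GalCer = row$p_gal)),
    path = path[!is.na(path)],
    chain_raw = row$chain_raw,
    chain_rounded = row$chain_rounded,
    nomenclature = row$nomenclature,
    flags = if (nzchar(row$flags)) strsplit(row$flags, ",")[[1]]
            else character()),
    class = "taxonomy_prediction")
}

#' @export
print.taxonomy_prediction <- function(x, ...) {
  cat("taxonomy prediction:", x$nomenclature, "\n")
  cat("  path:", paste(x$path, collapse = " -> "), "\n")
  if (!is.na(x$chain_raw)) {
    cat(sprintf("  chain length: %.2f (rounded %d)\n", x$chain_raw,
                x$chain_rounded))
  }
  if (length(x$flags)) cat("  low-confidence:",
                           paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

modal_class <- function(winners, mean_probs) {
  tab <- table(winners)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(list(class = top, tie = FALSE))
  # exact tie: resolve toward the class with the larger mean probability
  best <- top[which.max(mean_probs[top])]
  list(class = best, tie = TRUE)
}

#' Consensus prediction over replicate spectra
#'
#' Majority voting: the consensus class at each stage is the modal routed
#' class over replicates; an exact tie is resolved toward the class with
#' the larger mean probability and flagged. The consensus chain length is
#' the mean of the raw per-replicate estimates, reported as mean +/- SD and
#' then rounded.
#'
#' @param features matrix of replicate feature vectors (>= 1 row).
#' @param model a `taxonomy_model`.
#' @return list of class `"taxonomy_consensus"`: consensus stages,
#'   nomenclature, `chain_mean`, `chain_sd`, `chain_rounded`, `ties`, and
#'   the per-replicate prediction table in `$replicates`.
#' @export
predict_majority <- function(features, model) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL,
                                                   names(features)))
  if (nrow(features) < 1L) stop("need at least one replicate", call. = FALSE)
  tab <- predict_taxonomy(features, model)
  ties <- character()
  s1 <- modal_class(tab$stage1, c(blank = mean(tab$p_blank),
                                  epimer = mean(tab$p_epimer)))
  if (s1$tie) ties <- c(ties, "stage1")
  cons <- list(stage1 = s1$class, stage2 = NA, stage3 = NA, stage4 = NA)
  chain_mean <- chain_sd <- NA_real_
  chain_rounded <- NA_integer_
  nomen <- "MPBA blank"
  if (s1$class == "epimer") {
    s2 <- modal_class(tab$stage2, c(monosaccharide = mean(tab$p_mono),
                                    cerebroside = mean(tab$p_cer)))
    if (s2$tie) ties <- c(ties, "stage2")
    cons$stage2 <- s2$class
    if (s2$class == "monosaccharide") {
      nomen <- "monosaccharide"
    } else {
      s3 <- modal_class(tab$stage3, c(saturated = mean(tab$p_sat),
                                      unsaturated = mean(tab$p_unsat)))
      s4 <- modal_class(tab$stage4, c(GlcCer = mean(tab$p_glc),
                                      GalCer = mean(tab$p_gal)))
      if (s3$tie) ties <- c(ties, "stage3")
      if (s4$tie) ties <- c(ties, "stage4")
      cons$stage3 <- s3$class
      cons$stage4 <- s4$class
      chain_mean <- mean(tab$chain_raw, na.rm = TRUE)
      chain_sd <- stats::sd(tab$chain_raw)
      chain_rounded <- as.integer(round(chain_mean))
      nomen <- paste0(s4$class, chain_rounded,
                      if (s3$class == "unsaturated") ":1" else "")
    }
  }
  structure(list(consensus = cons, nomenclature = nomen,
                 chain_mean = chain_mean, chain_sd = chain_sd,
                 chain_rounded = chain_rounded, ties = ties,
                 replicates = tab),
            class = "taxonomy_consensus")
}

#' @export
print.taxonomy_consensus <- function(x, ...) {
  cat("consensus:", x$nomenclature, "\n")
  if (!is.na(x$chain_mean)) {
    cat(sprintf("  chain length: %.1f +/- %.1f\n", x$chain_mean,
                ifelse(is.na(x$chain_sd), 0, x$chain_sd)))
  }
  if (length(x$ties)) cat("  ties at:", paste(x$ties, collapse = ", "), "\n")
  invisible(x)
}

stage_truth <- function(label) {
  c(stage1 = if (label$category == "blank") "blank" else "epimer",
    stage2 = if (label$category == "cerebroside") "cerebroside"
             else if (label$category == "monosaccharide") "monosaccharide"
             else NA,
    stage3 = if (label$category == "cerebroside") {
      if (label$saturation > 0L) "unsaturated" else "saturated"
    } else NA,
    stage4 = if (label$category == "cerebroside") {
      if (label$hexose == "glc") "GlcCer" else "GalCer"
    } else NA)
}

#' Leave-one-cerebroside-out forward prediction
#'
#' Removes all spectra of one cerebroside class, trains the taxonomy on a
#' stratified subsample of the remainder, and evaluates the held-out class
#' as a blind test; this is repeated over iterations with fresh splits. A
#' held-out spectrum counts as correct overall only when every applicable
#' stage is correct. The chain-length report gives the consensus mean +/-
#' SD of the raw regressor estimates and the absolute difference of the
#' rounded consensus from truth.
#'
#' @param fs a `feature_set` covering the panel.
#' @param held_out nomenclature string of the cerebroside to hold out.
#' @param iterations number of re-training iterations (10 is the mini
#'   protocol; the study-scale protocol uses 100).
#' @param protocol `"split"` for stratified 80/20 resampling of the
#'   training pool, `"cv5"` to rotate through the folds of a stratified
#'   5-fold partition (equivalent training fraction).
#' @param train_frac training fraction for `"split"` (default 0.8).
#' @param hp a [taxonomy_hyperparameters()].
#' @param seed integer seed.
#' @return list of class `"forward_prediction"` with per-stage accuracies,
#'   overall accuracy, chain-length summary and the per-iteration table.
#' @export
forward_prediction <- function(fs, held_out, iterations = 10L,
                               protocol = c("split", "cv5"),
                               train_frac = 0.8,
                               hp = taxonomy_hyperparameters(),
                               seed = 1L) {
  protocol <- match.arg(protocol)
  analyte <- fs$analyte
  if (!held_out %in% cerebroside_names()) {
    stop("held_out must be one of the 11 cerebrosides, got '", held_out,
         "'", call. = FALSE)
  }
  test_idx <- which(analyte == held_out)
  if (length(test_idx) == 0L) {
    stop("held-out class '", held_out, "' is absent from the dataset",
         call. = FALSE)
  }
  pool_idx <- setdiff(seq_along(analyte), test_idx)
  truth <- stage_truth(fs$labels[[test_idx[1]]])
  truth_chain <- fs$labels[[test_idx[1]]]$chain_length

  per_iter <- vector("list", iterations)
  chain_raw_all <- numeric()
  for (it in seq_len(iterations)) {
    set.seed(seed + 1000L * it)
    if (protocol == "split") {
      train_idx <- unlist(lapply(split(pool_idx, analyte[pool_idx]),
                                 function(ix) sample(ix, ceiling(
                                   train_frac * length(ix)))))
    } else {
      fold <- ((it - 1L) %% 5L) + 1L
      set.seed(seed + 1000L * ((it - 1L) %/% 5L + 1L))
      fold_id <- integer(length(analyte))
      for (ix in split(pool_idx, analyte[pool_idx])) {
        fold_id[ix] <- sample(rep_len(1:5, length(ix)))
      }
      train_idx <- pool_idx[fold_id[pool_idx] != fold]
    }
    sub <- list(features = fs$features[train_idx, , drop = FALSE],
                labels = fs$labels[train_idx])
    model <- train_taxonomy(sub, hp, seed = seed + it)
    pred <- predict_taxonomy(fs$features[test_idx, , drop = FALSE], model)
    ok1 <- pred$stage1 == truth[["stage1"]]
    ok2 <- pred$stage2 == truth[["stage2"]]
    ok3 <- pred$stage3 == truth[["stage3"]]
    ok4 <- pred$stage4 == truth[["stage4"]]
    per_iter[[it]] <- data.frame(
      iteration = it,
      stage1 = mean(ok1), stage2 = mean(ok2),
      stage3 = mean(ok3), stage4 = mean(ok4),
      overall = mean(ok1 & ok2 & ok3 & ok4),
      chain_mean = mean(pred$chain_raw))
    chain_raw_all <- c(chain_raw_all, pred$chain_raw)
  }
  per_iter <- do.call(rbind, per_iter)
  chain_mean <- mean(chain_raw_all)
  chain_sd <- stats::sd(chain_raw_all)
  structure(list(
    held_out = held_out, iterations = iterations, protocol = protocol,
    stage_accuracy = colMeans(per_iter[, c("stage1", "stage2", "stage3",
                                           "stage4")]),
    overall_accuracy = mean(per_iter$overall),
    chain_mean = chain_mean, chain_sd = chain_sd,
    chain_rounded = as.integer(round(chain_mean)),
    chain_abs_diff = abs(round(chain_mean) - truth_chain),
    truth_chain = truth_chain,
    per_iteration = per_iter),
    class = "forward_prediction")
}

#' @export
print.forward_prediction <- function(x, ...) {
  cat(sprintf("forward prediction, hold-out %s (%d iterations, %s)\n",
              x$held_out, x$iterations, x$protocol))
  cat(sprintf("  stage accuracies: %s\n",
              paste(sprintf("%s %.1f%%", names(x$stage_accuracy),
                            100 * x$stage_accuracy), collapse = ", ")))
  cat(sprintf("  overall: %.1f%%  chain: %.1f +/- %.1f (|diff| = %d)\n",
              100 * x$overall_accuracy, x$chain_mean, x$chain_sd,
              x$chain_abs_diff))
  invisible(x)
}

#' Concentration-transfer evaluation
#'
#' Trains the taxonomy on the top-concentration dataset with the probe
#' class excluded, then generates probe spectra at each requested
#' concentration, featurizes them and routes them through the model. The
#' report gives per-concentration overall accuracy (all four stages
#' correct) and the consensus chain-length difference.
#'
#' @param fs featurized dataset at the top calibration concentration
#'   (all 14 classes).
#' @param probe nomenclature of the probe cerebroside (excluded from
#'   training).
#' @param concentrations molar probe concentrations (default
#'   `10^-(5:10)`).
#' @param cfg [synthetic_config()] used to generate probe spectra.
#' @param n_per_conc probe replicates per concentration (default 10).
#' @param hp a [taxonomy_hyperparameters()].
#' @param seed integer seed.
#' @return list of class `"concentration_transfer"`: per-concentration
#'   table and the minimum overall accuracy.
#' @export
concentration_transfer <- function(fs, probe,
                                   concentrations = 10^-(5:10),
                                   cfg = synthetic_config(),
                                   n_per_conc = 10L,
                                   hp = taxonomy_hyperparameters(),
                                   seed = 1L) {
  keep <- which(fs$analyte != probe)
  model <- train_taxonomy(list(features = fs$features[keep, , drop = FALSE],
                               labels = fs$labels[keep]), hp, seed = seed)
  label <- parse_nomenclature(probe)
  truth <- stage_truth(label)
  rows <- vector("list", length(concentrations))
  for (ci in seq_along(concentrations)) {
    conc <- concentrations[ci]
    feats <- matrix(NA_real_, n_per_conc, length(fs$features[1, ]),
                    dimnames = list(NULL, colnames(fs$features)))
    for (r in seq_len(n_per_conc)) {
      sp <- generate_spectrum(label, conc, cfg,
                              seed = derive_seed(seed + ci, r))
      feats[r, ] <- featurize_spectrum(sp)
    }
    pred <- predict_taxonomy(feats, model)
    ok <- pred$stage1 == truth[["stage1"]] &
          pred$stage2 == truth[["stage2"]] &
          pred$stage3 == truth[["stage3"]] &
          pred$stage4 == truth[["stage4"]]
    rows[[ci]] <- data.frame(
      concentration = conc,
      overall_accuracy = mean(ok),
      chain_mean = mean(pred$chain_raw),
      chain_sd = stats::sd(pred$chain_raw),
      chain_abs_diff = abs(round(mean(pred$chain_raw)) -
                             label$chain_length))
  }
  tab <- do.call(rbind, rows)
  structure(list(probe = probe, table = tab,
                 min_overall_accuracy = min(tab$overall_accuracy),
                 max_chain_abs_diff = max(tab$chain_abs_diff)),
            class = "concentration_transfer")
}

#' @export
print.concentration_transfer <- function(x, ...) {
  cat("concentration transfer, probe", x$probe, "\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("  minimum overall accuracy: %.1f%%\n",
              100 * x$min_overall_accuracy))
  invisible(x)
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 from true/false positive/negative
#' counts. A zero denominator yields `NA` for that metric plus an entry in
#' `$undefined` rather than an error.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `undefined`.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  undefined <- character()
  total <- tp + fp + tn + fn
  accuracy <- if (total > 0) (tp + tn) / total else {
    undefined <- c(undefined, "accuracy"); NA_real_ }
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); NA_real_ }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NA_real_ }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else { undefined <- c(undefined, "f1"); NA_real_ }
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, undefined = undefined)
}

#' Two-dimensional embedding of a feature table
#'
#' Visual QC view of the 95-feature space. The PCA view standardizes the
#' features, truncates to `n_components` principal components and returns
#' the first two (deterministic up to a fixed sign convention). A t-SNE
#' backend is not bundled; requesting it raises an informative error.
#'
#' @param features numeric matrix or `feature_set`.
#' @param method `"pca"` (implemented) or `"tsne"`.
#' @param n_components components retained before truncation (default 15).
#' @return n x 2 matrix of coordinates.
#' @export
embed_2d <- function(features, method = c("pca", "tsne"),
                     n_components = 15L) {
  method <- match.arg(method)
  if (inherits(features, "feature_set")) features <- features$features
  if (method == "tsne") {
    stop("no t-SNE backend is bundled; use method = 'pca'", call. = FALSE)
  }
  if (nrow(features) < 3L) {
    stop("parameter error: need at least 3 samples to embed", call. = FALSE)
  }
  sds <- apply(features, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    stop("degenerate input: all features are constant", call. = FALSE)
  }
  xs <- scale(features[, keep, drop = FALSE])
  pca <- stats::prcomp(xs, center = FALSE, rank. = min(n_components,
                                                       ncol(xs)))
  coords <- pca$x[, 1:2, drop = FALSE]
  # fix signs so the embedding is deterministic across BLAS builds
  for (j in 1:2) {
    k <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[k, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- c("dim1", "dim2")
  coords
}
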