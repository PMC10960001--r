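#' Fit the 19-peak model to a preprocessed spectrum
#'
#' Bounded nonlinear least squares of a sum of 19 skewed pseudo-Voigt
#' components (see [line_shape()]) against a canonical-grid spectrum. Each
#' component's center is constrained to its seed window. Because the seed
#' bands are well separated except for the 1567/1575/1584-1603 cm^-1 region,
#' the 95-parameter problem is solved block-wise: seeds are grouped into
#' overlap regions (the `region` column of the seed table), each region is
#' fitted by Levenberg-Marquardt over a local window against the spectrum
#' minus the current model of all other regions, and the sweep over regions
#' is repeated so overlapping tails are accounted for. The result is ordered
#' by seed index.
#'
#' @param sp a [spectrum()] on the canonical grid (meta flag `canonical`,
#'   see [preprocess_spectrum()]).
#' @param seeds a seed table from [peak_seed_table()] (or a replacement with
#'   the same columns).
#' @param control list: `maxiter` per-region Levenberg-Marquardt iterations
#'   of the warm start (default 40), `sweeps` region sweeps (default 1),
#'   `window_pad` cm^-1 added around each region (default 25),
#'   `global_maxiter` iterations of the final joint refinement with the
#'   analytic Jacobian (default 60; 0 skips it), `on_nonconvergence` one of
#'   `"warn"`, `"error"`, `"quiet"`.
#' @return list of class `"peak_fit"`: `peaks` (data.frame of 19 rows with
#'   columns `peak`, `center`, `amplitude`, `fwhm`, `skew`, `eta`),
#'   `residual_norm` (L2 norm over the full grid), `converged` (logical).
#' @export
fit_peaks <- function(sp, seeds = peak_seed_table(), control = list()) {
  stopifnot(is_spectrum(sp))
  if (!identical(sp$meta$canonical, "true")) {
    stop("fit_peaks expects a preprocessed spectrum on the canonical grid ",
         "(run preprocess_spectrum() or to_canonical_grid() first)",
         call. = FALSE)
  }
  ctrl <- utils::modifyList(
    list(maxiter = 40L, sweeps = 1L, window_pad = 25, global_maxiter = 60L,
         on_nonconvergence = "warn"), control)
  x <- sp$wavenumbers
  y <- sp$intensities
  np <- nrow(seeds)
  amp_hi <- max(3 * max(y), 1)

  region_size <- stats::ave(seq_len(np), seeds$region, FUN = length)
  # mobile bands (wide center windows, like the a1 nu(CC)) start at the
  # apex of the data inside their window; narrow windows start at the seed,
  # since their in-window apex may be a neighbour's tail
  center0 <- numeric(np)
  amp0 <- numeric(np)
  for (i in seq_len(np)) {
    iw <- which(x >= seeds$center_lo[i] & x <= seeds$center_hi[i])
    if (seeds$center_hi[i] - seeds$center_lo[i] > 15) {
      center0[i] <- x[iw[which.max(y[iw])]]
    } else {
      center0[i] <- seeds$seed[i]
    }
    amp0[i] <- max(y[iw])
  }
  pk <- data.frame(
    peak = seeds$peak,
    center = center0,
    # in shared regions the local maximum counts every overlapping band, so
    # split it between them at initialization
    amplitude = pmax(amp0 / pmax(region_size - 0.5, 1), 1e-4),
    fwhm = rep(12, np), skew = rep(0, np), eta = rep(0.5, np)
  )

  regions <- split(seq_len(np), seeds$region)
  converged <- TRUE

  fit_region <- function(idx, target) {
    win <- x >= min(seeds$center_lo[idx]) - ctrl$window_pad &
           x <= max(seeds$center_hi[idx]) + ctrl$window_pad
    xw <- x[win]; tw <- target[win]
    k <- length(idx)
    par0 <- as.numeric(t(as.matrix(pk[idx, c("center", "amplitude",
                                             "fwhm", "skew", "eta")])))
    lower <- as.numeric(t(cbind(seeds$center_lo[idx], 0,
                                seeds$fwhm_lo[idx], seeds$skew_lo[idx], 0)))
    upper <- as.numeric(t(cbind(seeds$center_hi[idx], amp_hi,
                                seeds$fwhm_hi[idx], seeds$skew_hi[idx], 1)))
    free <- lower < upper  # pinned parameters stay out of the optimizer
    full_par <- par0
    resid_fn <- function(p) {
      full_par[free] <- p
      m <- matrix(full_par, nrow = k, byrow = TRUE)
      model <- numeric(length(xw))
      for (j in seq_len(k)) {
        model <- model + line_shape(xw, m[j, 1], m[j, 2], m[j, 3],
                                    m[j, 4], m[j, 5])
      }
      tw - model
    }
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = par0[free], lower = lower[free], upper = upper[free],
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = ctrl$maxiter,
                                           ptol = 1e-9, ftol = 1e-9)))
    if (fit$info <= 0L || fit$info == 5L) converged <<- FALSE
    full_par[free] <- fit$par
    m <- matrix(full_par, nrow = k, byrow = TRUE)
    pk[idx, c("center", "amplitude", "fwhm", "skew", "eta")] <<-
      as.data.frame(m)
    invisible(NULL)
  }

  for (sweep in seq_len(ctrl$sweeps)) {
    for (idx in regions) {
      others <- setdiff(seq_len(np), idx)
      target <- y - peak_sum(x, pk[others, , drop = FALSE])
      fit_region(idx, target)
    }
  }

  # joint refinement of all components over the full grid: the block-wise
  # warm start mis-attributes the summed far tails of the Lorentzian
  # components, which biases the shape parameters of weak bands
  if (ctrl$global_maxiter > 0L) {
    par0 <- as.numeric(t(as.matrix(pk[, c("center", "amplitude", "fwhm",
                                          "skew", "eta")])))
    lower <- as.numeric(t(cbind(seeds$center_lo, 0, seeds$fwhm_lo,
                                seeds$skew_lo, 0)))
    upper <- as.numeric(t(cbind(seeds$center_hi, amp_hi, seeds$fwhm_hi,
                                seeds$skew_hi, 1)))
    par0 <- pmin(pmax(par0, lower), upper)
    free <- lower < upper
    full_par <- par0
    unpack <- function(p) {
      full_par[free] <- p
      matrix(full_par, nrow = np, byrow = TRUE)
    }
    gfn <- function(p) {
      m <- unpack(p)
      model <- numeric(length(x))
      for (j in seq_len(np)) {
        model <- model + line_shape(x, m[j, 1], m[j, 2], m[j, 3], m[j, 4],
                                    m[j, 5])
      }
      y - model
    }
    gjac <- function(p) {
      m <- unpack(p)
      J <- matrix(0, length(x), 5L * np)
      for (j in seq_len(np)) {
        g <- line_shape_grad(x, m[j, 1], m[j, 2], m[j, 3], m[j, 4], m[j, 5])
        J[, (5L * (j - 1L) + 1L):(5L * j)] <- cbind(g$dc, g$da, g$df,
                                                    g$ds, g$deta)
      }
      -J[, free, drop = FALSE]
    }
    gfit <- suppressWarnings(minpack.lm::nls.lm(
      par = par0[free], lower = lower[free], upper = upper[free],
      fn = gfn, jac = gjac,
      control = minpack.lm::nls.lm.control(maxiter = ctrl$global_maxiter,
                                           ptol = 1e-10, ftol = 1e-10)))
    if (gfit$info <= 0L || gfit$info == 5L) converged <- FALSE
    full_par[free] <- gfit$par
    pk[, c("center", "amplitude", "fwhm", "skew", "eta")] <-
      as.data.frame(matrix(full_par, nrow = np, byrow = TRUE))
  }

  residual_norm <- sqrt(sum((y - peak_sum(x, pk))^2))
  out <- structure(list(peaks = pk, residual_norm = residual_norm,
                        converged = converged),
                   class = "peak_fit")
  if (!converged) {
    msg <- "peak fit did not converge within the evaluation budget"
    if (identical(ctrl$on_nonconvergence, "error")) {
      cond <- structure(
        class = c("serstax_fit_failure", "error", "condition"),
        list(message = msg, call = sys.call(-1), fit = out))
      stop(cond)
    } else if (identical(ctrl$on_nonconvergence, "warn")) {
      warning(msg, call. = FALSE)
    }
  }
  out
}

feature_attributes <- c("position", "intensity", "fwhm", "skew", "ratio")

#' The fixed 95-feature schema
#'
#' @return character vector of 95 names: `p01_position`, `p01_intensity`,
#'   `p01_fwhm`, `p01_skew`, `p01_ratio`, `p02_position`, ...
#' @export
feature_schema <- function() {
  as.vector(t(outer(sprintf("p%02d", 1:19), feature_attributes, paste,
                    sep = "_")))
}

#' Flatten fitted peaks into the 95-feature vector
#'
#' Concatenates the five attributes of each of the 19 peaks in schema order
#' (peak 1 position, intensity, fwhm, skew, ratio; peak 2 ...). The `ratio`
#' attribute is the pseudo-Voigt Lorentzian fraction `eta`. The `intensity`
#' attribute is the fitted apex amplitude referenced to the a1 1567 cm^-1
#' reporter band (peak `reference`), the internal standard used by all the
#' diagnostic peak-height ratios; this makes the intensity features
#' invariant to the per-spectrum min-max scale. Input rows may arrive in
#' any order; they are reordered by the `peak` index.
#'
#' @param peaks data.frame of fitted peaks (from [fit_peaks()]`$peaks`) or a
#'   `"peak_fit"` object.
#' @param reference index of the internal-standard peak (default 17, the
#'   1567 cm^-1 band of the default seed table); `NA` keeps raw amplitudes.
#' @return named numeric vector of length 95.
#' @export
to_features <- function(peaks, reference = 17L) {
  if (inherits(peaks, "peak_fit")) peaks <- peaks$peaks
  if (nrow(peaks) != 19L) {
    stop("arity error: expected exactly 19 peaks, got ", nrow(peaks),
         call. = FALSE)
  }
  peaks <- peaks[order(peaks$peak), , drop = FALSE]
  if (!is.na(reference)) {
    ref_amp <- max(peaks$amplitude[reference], 1e-6)
    peaks$amplitude <- peaks$amplitude / ref_amp
  }
  v <- as.numeric(t(as.matrix(
    peaks[, c("center", "amplitude", "fwhm", "skew", "eta")])))
  names(v) <- feature_schema()
  v
}

#' Featurize a single spectrum
#'
#' Preprocesses (unless already canonical), fits the 19-peak model, and
#' returns the 95-feature vector.
#'
#' @param sp a [spectrum()].
#' @param seeds seed table, see [fit_peaks()].
#' @param settings [airpls_settings()] used when preprocessing is needed.
#' @param control fit control list, see [fit_peaks()].
#' @return named numeric vector of length 95.
#' @export
featurize_spectrum <- function(sp, seeds = peak_seed_table(),
                               settings = airpls_settings(),
                               control = list()) {
  if (!identical(sp$meta$canonical, "true")) {
    sp <- preprocess_spectrum(sp, settings)
  }
  ctrl <- utils::modifyList(list(on_nonconvergence = "quiet"), control)
  to_features(fit_peaks(sp, seeds, ctrl))
}

#' Featurize every spectrum in a set
#'
#' Runs the preprocess-and-fit pipeline over a [spectrum_set()] and returns
#' a feature table aligned with the labels.
#'
#' @param set a [spectrum_set()] with loaded spectra.
#' @param seeds,settings,control passed to [featurize_spectrum()].
#' @param progress print a dot every 50 spectra.
#' @return list of class `"feature_set"`: `features` (n x 95 matrix),
#'   `labels` (list of [analyte_label()]), `analyte` (nomenclature strings),
#'   `concentration` (molar).
#' @export
featurize_set <- function(set, seeds = peak_seed_table(),
                          settings = airpls_settings(), control = list(),
                          progress = FALSE) {
  stopifnot(inherits(set, "spectrum_set"))
  n <- length(set)
  features <- matrix(NA_real_, n, 95L,
                     dimnames = list(NULL, feature_schema()))
  for (i in seq_len(n)) {
    features[i, ] <- featurize_spectrum(set$spectra[[i]], seeds, settings,
                                        control)
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(list(features = features, labels = set$labels,
                 analyte = vapply(set$labels, nomenclature, character(1)),
                 concentration = set$concentration),
            class = "feature_set")
}

#' Peak-height intensity ratio between two bands
#'
#' Ratio of the maximum intensities within `half_window` of the numerator
#' and denominator band centers, e.g. the I1330/I1567 epimer diagnostic.
#'
#' @param sp a [spectrum()].
#' @param num,den band centers in cm^-1.
#' @param half_window window half width in cm^-1 (default 8).
#' @return numeric ratio.
#' @export
intensity_ratio <- function(sp, num, den, half_window = 8) {
  stopifnot(is_spectrum(sp))
  rng <- range(sp$wavenumbers)
  for (b in c(num, den)) {
    if (b - half_window < rng[1] || b + half_window > rng[2]) {
      stop(sprintf("range error: band %.1f +/- %.1f cm-1 outside spectrum",
                   b, half_window), call. = FALSE)
    }
  }
  apex <- function(b) max(sp$intensities[abs(sp$wavenumbers - b) <= half_window])
  apex(num) / apex(den)
}

#' Sub-grid band position by parabolic apex refinement
#'
#' Finds the discrete maximum within `half_window` of `seed` and refines it
#' with a three-point parabola through the maximum and its neighbours.
#'
#' @param sp a [spectrum()].
#' @param seed band center to search around (cm^-1).
#' @param half_window search half width (cm^-1).
#' @return apex position in cm^-1.
#' @export
band_position <- function(sp, seed, half_window = 8) {
  stopifnot(is_spectrum(sp))
  idx <- which(abs(sp$wavenumbers - seed) <= half_window)
  if (length(idx) < 3L) {
    stop("range error: window contains fewer than 3 samples", call. = FALSE)
  }
  yw <- sp$intensities[idx]
  k <- which.max(yw)
  if (k == 1L || k == length(yw)) {
    stop(sprintf("no-peak error: no interior apex within %.1f +/- %.1f cm-1",
                 seed, half_window), call. = FALSE)
  }
  i <- idx[k]
  x3 <- sp$wavenumbers[(i - 1):(i + 1)]
  y3 <- sp$intensities[(i - 1):(i + 1)]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (denom >= 0) return(x3[2])  # flat top: fall back to the grid node
  h <- x3[2] - x3[1]
  x3[2] + 0.5 * h * (y3[1] - y3[3]) / denom
}
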