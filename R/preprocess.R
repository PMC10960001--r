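#' airPLS settings
#'
#' Tuning parameters for adaptive iteratively reweighted penalized least
#' squares baseline estimation.
#'
#' @param lambda smoothness penalty weight (> 0). Larger values give stiffer
#'   baselines; 1e5 is a common choice for ~1000-point Raman spectra.
#' @param max_iter maximum number of reweighting iterations (>= 1).
#' @param convergence_ratio iteration stops once the L1 norm of the negative
#'   residuals falls below this fraction of the total absolute signal
#'   (0 < ratio < 1).
#' @return list of class `"airpls_settings"`.
#' @export
airpls_settings <- function(lambda = 1e5, max_iter = 30,
                            convergence_ratio = 1e-3) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("airPLS settings error: lambda must be a positive number",
         call. = FALSE)
  }
  if (max_iter < 1) stop("airPLS settings error: max_iter >= 1", call. = FALSE)
  if (convergence_ratio <= 0 || convergence_ratio >= 1) {
    stop("airPLS settings error: convergence_ratio in (0, 1)", call. = FALSE)
  }
  structure(list(lambda = lambda, max_iter = as.integer(max_iter),
                 convergence_ratio = convergence_ratio),
            class = "airpls_settings")
}

# cache of D'D penalty matrices keyed by signal length
.penalty_cache <- new.env(parent = emptyenv())

whittaker_penalty <- function(m) {
  key <- as.character(m)
  if (!is.null(.penalty_cache[[key]])) return(.penalty_cache[[key]])
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- Matrix::crossprod(D)
  .penalty_cache[[key]] <- DtD
  DtD
}

#' Estimate a baseline with airPLS
#'
#' Adaptive iteratively reweighted penalized least squares: the baseline `z`
#' minimizes the weighted fidelity `sum(w * (y - z)^2)` plus the
#' second-difference roughness penalty `lambda * sum(diff(z, differences=2)^2)`
#' (an order-2 Whittaker smoother). After each solve the weights are updated
#' from the residuals `d = y - z`: points on or above the baseline get weight
#' zero (peaks are ignored), points below get `exp(t * |d_i| / |d_neg|_1)`
#' where `t` is the iteration number, so persistent dips are pulled in
#' progressively harder. Iteration stops at `max_iter` or once
#' `|d_neg|_1 < convergence_ratio * |y|_1`.
#'
#' @param y numeric intensity vector (finite, length >= 5).
#' @param settings an [airpls_settings()].
#' @return numeric baseline vector `z`, same length as `y`.
#' @references Zhang, Chen and Liang, Analyst 135, 1138-1146 (2010).
#' @export
airpls_baseline <- function(y, settings = airpls_settings()) {
  if (!inherits(settings, "airpls_settings")) {
    stop("settings must be created with airpls_settings()", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("airPLS input must be finite", call. = FALSE)
  m <- length(y)
  if (m < 5L) stop("airPLS input must have length >= 5", call. = FALSE)
  DtD <- settings$lambda * whittaker_penalty(m)
  w <- rep(1, m)
  abs_y <- sum(abs(y))
  z <- y
  ch <- NULL  # reuse the symbolic Cholesky across reweighting iterations
  for (t in seq_len(settings$max_iter)) {
    A <- Matrix::Diagonal(m, w) + DtD
    ch <- if (is.null(ch)) Matrix::Cholesky(A, LDL = FALSE)
          else Matrix::update(ch, A)
    z <- as.numeric(Matrix::solve(ch, w * y))
    d <- y - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn < settings$convergence_ratio * abs_y) break
    w[!neg] <- 0
    w[neg] <- exp(t * abs(d[neg]) / dssn)
    # anchor the ends so the baseline cannot drift free of the data
    w[1] <- exp(t * max(abs(d[neg])) / dssn)
    w[m] <- w[1]
  }
  z
}

#' Min-max normalize an intensity vector
#'
#' Rescales to `(y - min y) / (max y - min y)` so the maximum is exactly 1
#' and the minimum 0.
#'
#' @param y finite numeric vector with `max(y) > min(y)`.
#' @return normalized vector.
#' @export
minmax_normalize <- function(y) {
  if (any(!is.finite(y))) stop("input must be finite", call. = FALSE)
  rng <- range(y)
  if (rng[1] == rng[2]) {
    stop("degenerate input: constant vector cannot be min-max normalized",
         call. = FALSE)
  }
  (y - rng[1]) / (rng[2] - rng[1])
}

#' The canonical 1200-point wavenumber grid
#'
#' 1200 evenly spaced points spanning 400-1800 cm^-1, the analysis window
#' used throughout the package.
#'
#' @return numeric vector of length 1200.
#' @export
canonical_grid <- function() seq(400, 1800, length.out = 1200L)

#' Resample a spectrum onto the canonical grid
#'
#' Linear interpolation onto the 1200-point 400-1800 cm^-1 grid. The input
#' must cover the window (endpoints within 5 cm^-1; values beyond the
#' measured range are held at the end values rather than extrapolated).
#' Sets the meta flag `canonical`.
#'
#' @param sp a [spectrum()].
#' @return a [spectrum()] on the canonical grid.
#' @export
to_canonical_grid <- function(sp) {
  stopifnot(is_spectrum(sp))
  rng <- range(sp$wavenumbers)
  if (rng[1] > 400 + 5 || rng[2] < 1800 - 5) {
    stop(sprintf(
      "coverage error: spectrum spans %.1f-%.1f cm-1 but the canonical window is 400-1800 cm-1 (gap: %s)",
      rng[1], rng[2],
      paste(c(if (rng[1] > 405) sprintf("400-%.1f", rng[1]),
              if (rng[2] < 1795) sprintf("%.1f-1800", rng[2])),
            collapse = ", ")), call. = FALSE)
  }
  grid <- canonical_grid()
  yi <- stats::approx(sp$wavenumbers, sp$intensities, xout = grid,
                      rule = 2)$y
  meta <- sp$meta
  meta$canonical <- "true"
  spectrum(grid, yi, meta)
}

#' Full spectral preprocessing pipeline
#'
#' Applies, in order: airPLS baseline subtraction, min-max normalization
#' (max = 1), and resampling onto the canonical 1200-point 400-1800 cm^-1
#' grid. The order is fixed: the baseline is estimated on the measured
#' samples before any interpolation.
#'
#' @param sp a [spectrum()].
#' @param settings an [airpls_settings()].
#' @return a preprocessed [spectrum()] with meta flags
#'   `baseline_corrected`, `normalized`, `canonical`.
#' @export
preprocess_spectrum <- function(sp, settings = airpls_settings()) {
  stopifnot(is_spectrum(sp))
  z <- airpls_baseline(sp$intensities, settings)
  y <- minmax_normalize(sp$intensities - z)
  meta <- sp$meta
  meta$baseline_corrected <- "true"
  meta$normalized <- "true"
  out <- spectrum(sp$wavenumbers, y, meta)
  to_canonical_grid(out)
}
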