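#' Skewed pseudo-Voigt line shape
#'
#' The package's single-peak model. A pseudo-Voigt mixes a unit-apex
#' Lorentzian and Gaussian, both parameterized by full width at half
#' maximum:
#' `V(x) = amplitude * (eta * L(x) + (1 - eta) * G(x))`.
#' Asymmetry ("skew") is modeled with a side-dependent width: points above
#' the center see `fwhm * (1 + skew)`, points below see `fwhm * (1 - skew)`,
#' with skew clipped to (-0.95, 0.95). `skew = 0` is exactly symmetric, and
#' the apex value equals `amplitude` at `center` for any `eta`.
#'
#' @param x wavenumbers (cm^-1), vectorized.
#' @param center peak center (cm^-1).
#' @param amplitude apex height (>= 0).
#' @param fwhm full width at half maximum (cm^-1, > 0).
#' @param skew dimensionless asymmetry, 0 = symmetric.
#' @param eta Lorentzian fraction in [0, 1] (1 = pure Lorentzian).
#' @return intensity values at `x`.
#' @export
line_shape <- function(x, center, amplitude, fwhm, skew = 0, eta = 0.5) {
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  skew <- max(-0.95, min(0.95, skew))
  w <- ifelse(x >= center, fwhm * (1 + skew), fwhm * (1 - skew))
  u <- (x - center) / (w / 2)
  L <- 1 / (1 + u^2)
  G <- exp(-log(2) * u^2)
  amplitude * (eta * L + (1 - eta) * G)
}

# sum of peaks given a parameter data.frame with columns
# center/amplitude/fwhm/skew/eta
peak_sum <- function(x, peaks) {
  y <- numeric(length(x))
  for (i in seq_len(nrow(peaks))) {
    y <- y + line_shape(x, peaks$center[i], peaks$amplitude[i],
                        peaks$fwhm[i], peaks$skew[i], peaks$eta[i])
  }
  y
}

# value and analytic partial derivatives of one skewed pseudo-Voigt with
# respect to (center, amplitude, fwhm, skew, eta); used for the global
# Levenberg-Marquardt refinement
line_shape_grad <- function(x, center, amplitude, fwhm, skew, eta) {
  skew <- max(-0.95, min(0.95, skew))
  up <- x >= center
  w <- ifelse(up, fwhm * (1 + skew), fwhm * (1 - skew))
  u <- (x - center) / (w / 2)
  L <- 1 / (1 + u^2)
  G <- exp(-log(2) * u^2)
  shape <- eta * L + (1 - eta) * G
  dshape_du <- eta * (-2 * u * L^2) + (1 - eta) * (-2 * log(2) * u * G)
  du_dc <- -2 / w
  du_df <- -u / fwhm
  du_ds <- ifelse(up, -u / (1 + skew), u / (1 - skew))
  list(value = amplitude * shape,
       dc = amplitude * dshape_du * du_dc,
       da = shape,
       df = amplitude * dshape_du * du_df,
       ds = amplitude * dshape_du * du_ds,
       deta = amplitude * (L - G))
}

#' Default 19-band peak seed table
#'
#' Seed centers and per-peak fit bounds for the 19-peak parameterization of
#' cerebroside-MPBA SERS spectra. The table carries the eight
#' mechanistically assigned bands — 414 and 691 cm^-1 (ring
#' deformation + C-S stretch), 1023 cm^-1 (C-H bend), 1330 cm^-1 (B-OH
#' bend), 1567 cm^-1 (a1 reference), 1575 cm^-1 (b2 C-C stretch) and the
#' mobile a1 C-C stretch seeded at 1598 cm^-1 (window 1584-1603), plus a
#' low-frequency band near 480 cm^-1 — padded with eleven fixed filler bands
#' to 19 entries. Replace via the `seeds` argument of [fit_peaks()] to use a
#' different band list without code changes.
#'
#' @return data.frame with columns `peak` (index), `seed` (cm^-1),
#'   `center_lo`, `center_hi` (center window), `fwhm_lo`, `fwhm_hi`
#'   and `region` (overlap-cluster id for shared-region fitting).
#' @export
peak_seed_table <- function() {
  seed <- c(414, 480, 520, 630, 691, 760, 810, 860, 920, 1023,
            1070, 1140, 1260, 1330, 1410, 1480, 1567, 1575, 1598)
  lo <- seed - 10
  hi <- seed + 10
  # the mobile a1 nu(CC) band wanders between 1584 and 1603 cm^-1
  lo[seed == 1598] <- 1584
  hi[seed == 1598] <- 1603
  # keep the 414-419 diagnostic window open
  lo[seed == 414] <- 408
  hi[seed == 414] <- 421
  # the heavily overlapped a1/b2 pair needs tight windows or the two
  # components trade amplitude
  lo[seed == 1567] <- 1562; hi[seed == 1567] <- 1572
  lo[seed == 1575] <- 1571; hi[seed == 1575] <- 1580
  fwhm_lo <- rep(2.5, length(seed))
  fwhm_hi <- rep(40, length(seed))
  fwhm_lo[seed %in% c(1567, 1575, 1598)] <- 6
  fwhm_hi[seed %in% c(1567, 1575, 1598)] <- 16
  # the overlapped a1/b2 pair is modeled as symmetric (skew pinned to 0);
  # with per-peak skew free the 8 cm^-1 pair is not identifiable
  skew_lo <- rep(-0.6, length(seed))
  skew_hi <- rep(0.6, length(seed))
  skew_lo[seed %in% c(1567, 1575)] <- 0
  skew_hi[seed %in% c(1567, 1575)] <- 0
  # the 1567/1575/1598 bands overlap and are fitted jointly
  region <- seq_along(seed)
  region[seed %in% c(1567, 1575, 1598)] <- region[seed == 1567]
  data.frame(peak = seq_along(seed), seed = seed,
             center_lo = lo, center_hi = hi,
             fwhm_lo = fwhm_lo, fwhm_hi = fwhm_hi,
             skew_lo = skew_lo, skew_hi = skew_hi, region = region)
}
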