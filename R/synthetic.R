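#' Configuration for the synthetic SERS spectrum generator
#'
#' Bundles everything the generator needs: the base MPBA 19-band table, the
#' structure-to-spectrum rule targets, the noise model, the concentration
#' response and the replicate design.
#'
#' The five rules (all expressed in measured units, i.e. post-normalization
#' peak-height ratios and apex positions):
#' \describe{
#'   \item{R1 (epimer capture)}{I1330/I1567 target: blank 0.6,
#'     monosaccharide 0.05, cerebrosides a deterministic per-class value
#'     interleaved over \[0.07, 2.2\].}
#'   \item{R2 (saturation)}{a1 C-C stretch center: blank 1603, saturated
#'     cerebroside 1601, unsaturated GlcCer 1591 / GalCer 1595 cm^-1 with a
#'     1.35x amplitude increase.}
#'   \item{R3 (hexose)}{ring-deformation + C-S band center: blank 414,
#'     GlcCer 414.2-416.5 and GalCer 417.5-419 cm^-1, linear in chain
#'     length within each range; glucose 415, galactose 418.}
#'   \item{R4 (Glc chain length)}{I1023/I1567 rises linearly 0.42 to 0.90
#'     with X for GlcCer; 0.24 for GalCer (slightly below the 0.30 blank).}
#'   \item{R5 (Gal chain length)}{I691/I1567 rises linearly 0.35 to 0.80
#'     with X for GalCer; 0.22 for GlcCer (blank 0.28). The matching
#'     hexose band also broadens with chain length (a width channel that
#'     complements the height ratios).}
#' }
#'
#' Concentration enters through two channels. Identity rules R1-R5 are at
#' full strength for any concentration at or above the detection limit and
#' vanish below it (boronate-capture saturation: the normalized fingerprint
#' of the adduct keeps its shape down to the LOD). The analyte-loading
#' channel modulates the amplitudes and widths of the non-diagnostic
#' reporter bands by the log-linear response
#' `alpha(c) = (log10 c - log10 lod) / (log10 c_max - log10 lod)`, clipped
#' to \[0, 1\]; bands are at their base (blank) values when `alpha = 1` and
#' maximally perturbed at the LOD, which is what the concentration
#' regressors read.
#'
#' @param c_max top calibration concentration in molar (default 1e-4).
#' @param lod detection limit in molar (default 1e-10).
#' @param noise_sd additive Gaussian intensity noise, as a fraction of the
#'   unit maximum (default 0.01).
#' @param jitter_sd per-peak center jitter in cm^-1 (default 0.3).
#' @param band_noise_sd log-normal per-band enhancement noise (default
#'   0.02): each band's amplitude is multiplied by `exp(N(0, sd))` per
#'   replicate, emulating plasmonic enhancement variability.
#' @param r1330_noise_sd extra log-normal variability of the 1330 cm^-1
#'   capture band (default 0.2). Boronate-ester formation is
#'   competition-sensitive, so the capture-band ratio fluctuates strongly
#'   within a class -- the wide per-class spread of the measured
#'   I1330/I1567 boxplots -- while the class medians keep their ordering.
#' @param baseline_scale amplitude scale of the broad fluorescence-like
#'   background (offset + tilt + wide Gaussian hump, redrawn per
#'   replicate; default 0.2 of the reporter apex). The background is what
#'   the airPLS preprocessing step removes; 0 disables it.
#' @param replicates default replicate count per (analyte, concentration)
#'   cell (default 60).
#' @param master_seed default master seed for dataset generation.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(c_max = 1e-4, lod = 1e-10, noise_sd = 0.01,
                             jitter_sd = 0.3, band_noise_sd = 0.02,
                             r1330_noise_sd = 0.2, baseline_scale = 0.1,
                             replicates = 60L,
                             master_seed = 20240322L) {
  if (lod >= c_max) stop("lod must be below c_max", call. = FALSE)
  if (replicates < 2L) stop("replicate count must be >= 2", call. = FALSE)
  structure(list(c_max = c_max, lod = lod, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, band_noise_sd = band_noise_sd,
                 r1330_noise_sd = r1330_noise_sd,
                 baseline_scale = baseline_scale,
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed),
                 base = base_peak_table(), rules = rule_table()),
            class = "synthetic_config")
}

#' Base MPBA 19-band table
#'
#' Band parameters of the unreacted reporter spectrum. `k_amp` and `k_fwhm`
#' are the analyte-loading coefficients: amplitude and width of band j scale
#' by `1 + k * (alpha - 1)` so bands sit at their base values at full
#' response and drift as the analyte loading falls toward the LOD.
#' Diagnostic bands (414, 691, 1023, 1330, 1567, 1575, a1) carry no loading
#' so the identity rules are not confounded.
#'
#' @return data.frame of 19 rows.
#' @export
base_peak_table <- function() {
  data.frame(
    center = c(414, 480, 520, 630, 691, 760, 810, 860, 920, 1023,
               1070, 1140, 1260, 1330, 1410, 1480, 1567, 1575, 1598),
    amplitude = c(0.45, 0.22, 0.18, 0.25, NA, 0.20, 0.16, 0.24, 0.20, NA,
                  0.28, 0.22, 0.30, NA, 0.24, 0.26, 1.00, 0.45, 0.80),
    fwhm = c(9, 12, 11, 12, 10, 13, 11, 12, 12, 10,
             12, 13, 14, 12, 12, 12, 11, 10, 12),
    eta = c(0.5, 0.4, 0.6, 0.5, 0.5, 0.4, 0.5, 0.6, 0.5, 0.5,
            0.4, 0.5, 0.6, 0.5, 0.5, 0.4, 0.6, 0.5, 0.6),
    skew = c(0, 0.05, 0, 0, 0, 0, -0.05, 0, 0, 0,
             0, 0, 0.05, 0, 0, 0, 0, 0, 0),
    k_amp = c(0.45, -0.50, 0.55, -0.45, 0, 0.50, -0.55, 0.45, -0.50, 0,
              0.55, -0.45, 0.50, 0, -0.55, 0.45, 0, 0, 0),
    k_fwhm = c(-0.80, -0.75, -0.80, -0.75, 0, -0.80, -0.75, -0.80, -0.75, 0,
               -0.80, -0.75, -0.80, 0, -0.80, -0.75, -0.50, -0.45, 0),
    k_eta = c(0.25, -0.20, 0.25, -0.25, 0, 0.20, -0.25, 0.25, -0.20, 0,
              0.25, -0.25, 0.20, 0, 0.25, -0.20, 0, 0, 0)
  )
}

# rule targets; ratios are measured (post-normalization apex-height) values
rule_table <- function() {
  list(
    r1330 = list(blank = 0.6, mono = 0.03,
                 cer_lo = 0.07, cer_hi = 2.2),
    a1 = list(blank = 1603, mono = 1602, sat = 1601,
              unsat_glc = 1591, unsat_gal = 1595, unsat_amp_gain = 1.35,
              # the distal C=C pi-stacks with the reporter ring, so
              # unsaturation also broadens the a1 mode and perturbs the b2
              # and 1480 cm-1 ring modes
              unsat_fwhm_gain = 1.2, unsat_b2_gain = 1.2,
              unsat_1480_shift = 2.0, unsat_1480_gain = 1.25,
              # pi-pi coupling of the C=C also shifts several skeletal
              # modes; hexose-independent, so they carry pure saturation
              # information
              unsat_shifts = c("520" = 1.5, "760" = -1.5, "860" = 2.5,
                               "920" = -1.5, "1070" = 1.2, "1140" = 1.5,
                               "1260" = -2.0),
              unsat_skel_fwhm_gain = 1.15, unsat_skel_eta_shift = 0.15),
    pos414 = list(blank = 414, glucose = 415, galactose = 418,
                  glc_lo = 414.2, glc_hi = 416.5,
                  gal_lo = 417.5, gal_hi = 419.0),
    r1023 = list(blank = 0.30, glucose = 0.32, galactose = 0.30,
                 glc_lo = 0.42, glc_hi = 1.00, gal = 0.24),
    r691 = list(blank = 0.28, mono = 0.28,
                gal_lo = 0.35, gal_hi = 0.80, glc = 0.17),
    # heterogeneity of adduct configurations broadens the chain-reporting
    # band as the acyl chain grows, and the accumulating alkyl mass drags
    # its center: width- and position-based chain channels that complement
    # the height ratio
    chain_fwhm = list(slope = 0.45, center_slope = 0.18)
  )
}

# deterministic R1 target for a cerebroside label: the 11 classes take
# equally spaced values over [cer_lo, cer_hi]. The assignment interleaves
# the two hexoses across the value range (so the ratio does not encode the
# hexose) and is scrambled with respect to chain length within each hexose
# (so the ratio does not masquerade as a chain-length feature)
cerebroside_r1330 <- function(label, rules) {
  ord <- c("GlcCer16", "GalCer16", "GlcCer8", "GalCer24", "GlcCer24:1",
           "GalCer8", "GlcCer12", "GalCer24:1", "GlcCer18", "GalCer12",
           "GalCer18")
  # class values sit inside the printed [cer_lo, cer_hi] span but keep a
  # clear margin above the monosaccharide level so the lowest cerebroside
  # is not a knife-edge case at the monosaccharide/cerebroside boundary
  vals <- seq(max(rules$r1330$cer_lo, 0.35), rules$r1330$cer_hi,
              length.out = 11L)
  idx <- match(nomenclature(label), ord)
  if (is.na(idx)) stop("not a panel cerebroside: ", nomenclature(label),
                       call. = FALSE)
  vals[idx]
}

chain_fraction <- function(x) (x - 8) / 16  # maps X in [8, 24] to [0, 1]

#' Log-linear concentration response
#'
#' `alpha(c) = (log10 c - log10 lod) / (log10 c_max - log10 lod)`, clipped
#' to \[0, 1\]: 1 at the top calibration concentration, 0 at the detection
#' limit, 0.5 at the log-midpoint (1e-7 M for the defaults).
#'
#' @param conc molar concentration(s).
#' @param cfg a [synthetic_config()].
#' @return numeric in \[0, 1\].
#' @export
conc_alpha <- function(conc, cfg = synthetic_config()) {
  a <- (log10(conc) - log10(cfg$lod)) / (log10(cfg$c_max) - log10(cfg$lod))
  pmin(pmax(a, 0), 1)
}

# noise-free component table for (label, conc); the calibrated amplitudes of
# the 691/1023/1330 bands are solved so that the *measured* apex-height
# ratios hit the rule targets
signature_peaks <- function(label, conc, cfg) {
  rules <- cfg$rules
  pk <- cfg$base
  is_blank <- label$category == "blank"
  alpha <- if (is_blank) 1 else conc_alpha(conc, cfg)
  gate <- if (is_blank) 0 else as.numeric(conc >= cfg$lod)

  # analyte-loading channel on the non-diagnostic bands
  pk$amplitude <- pk$amplitude * (1 + pk$k_amp * (alpha - 1))
  pk$fwhm <- pk$fwhm * (1 + pk$k_fwhm * (alpha - 1))
  pk$eta <- pmin(pmax(pk$eta + pk$k_eta * (alpha - 1), 0.05), 0.95)

  # identity-rule targets at full response, blended toward blank by the gate
  blend <- function(value, blank) blank + gate * (value - blank)
  r1 <- rules$r1330$blank
  a1_center <- rules$a1$blank
  a1_gain <- 1
  a1_fwhm_gain <- 1
  b2_gain <- 1
  shift1480 <- 0
  gain1480 <- 1
  skel_shifts <- rules$a1$unsat_shifts * 0
  p414 <- rules$pos414$blank
  r1023 <- rules$r1023$blank
  r691 <- rules$r691$blank
  if (label$category == "monosaccharide") {
    r1 <- blend(rules$r1330$mono, r1)
    a1_center <- blend(rules$a1$mono, a1_center)
    p414 <- blend(if (label$hexose == "glc") rules$pos414$glucose
                  else rules$pos414$galactose, p414)
    r1023 <- blend(if (label$hexose == "glc") rules$r1023$glucose
                   else rules$r1023$galactose, r1023)
  } else if (label$category == "cerebroside") {
    f <- chain_fraction(label$chain_length)
    r1 <- blend(cerebroside_r1330(label, rules), r1)
    if (label$saturation > 0L) {
      a1_center <- blend(if (label$hexose == "glc") rules$a1$unsat_glc
                         else rules$a1$unsat_gal, a1_center)
      a1_gain <- blend(rules$a1$unsat_amp_gain, 1)
      a1_fwhm_gain <- blend(rules$a1$unsat_fwhm_gain, 1)
      b2_gain <- blend(rules$a1$unsat_b2_gain, 1)
      shift1480 <- blend(rules$a1$unsat_1480_shift, 0)
      gain1480 <- blend(rules$a1$unsat_1480_gain, 1)
      skel_shifts <- gate * rules$a1$unsat_shifts
    } else {
      a1_center <- blend(rules$a1$sat, a1_center)
    }
    if (label$hexose == "glc") {
      p414 <- blend(rules$pos414$glc_lo +
                      f * (rules$pos414$glc_hi - rules$pos414$glc_lo), p414)
      r1023 <- blend(rules$r1023$glc_lo +
                       f * (rules$r1023$glc_hi - rules$r1023$glc_lo), r1023)
      r691 <- blend(rules$r691$glc, r691)
      chain_band <- 1023
    } else {
      p414 <- blend(rules$pos414$gal_lo +
                      f * (rules$pos414$gal_hi - rules$pos414$gal_lo), p414)
      r691 <- blend(rules$r691$gal_lo +
                      f * (rules$r691$gal_hi - rules$r691$gal_lo), r691)
      r1023 <- blend(rules$r1023$gal, r1023)
    }
  }
  # width-based chain channel: the matching hexose band broadens with the
  # acyl chain length
  chain_widen <- 0
  if (label$category == "cerebroside") {
    chain_widen <- blend(rules$chain_fwhm$slope * (label$chain_length - 8), 0)
  }

  i414 <- which(pk$center == 414)
  i691 <- which(pk$center == 691)
  i1023 <- which(pk$center == 1023)
  i1330 <- which(pk$center == 1330)
  i1480 <- which(pk$center == 1480)
  ib2 <- which(pk$center == 1575)
  ia1 <- which(pk$center == 1598)
  pk$center[i414] <- p414
  pk$center[ia1] <- a1_center
  pk$amplitude[ia1] <- pk$amplitude[ia1] * a1_gain
  pk$fwhm[ia1] <- pk$fwhm[ia1] * a1_fwhm_gain
  if (label$category == "cerebroside") {
    ichain <- if (label$hexose == "glc") i1023 else i691
    pk$fwhm[ichain] <- pk$fwhm[ichain] + chain_widen
    pk$center[ichain] <- pk$center[ichain] +
      blend(rules$chain_fwhm$center_slope * (label$chain_length - 8), 0)
  }
  pk$amplitude[ib2] <- pk$amplitude[ib2] * b2_gain
  pk$center[i1480] <- pk$center[i1480] + shift1480
  pk$amplitude[i1480] <- pk$amplitude[i1480] * gain1480
  for (b in names(skel_shifts)) {
    ib <- which(pk$center == as.numeric(b))
    if (length(ib)) {
      pk$center[ib] <- pk$center[ib] + skel_shifts[[b]]
      skel_gain <- blend(rules$a1$unsat_skel_fwhm_gain, 1)
      eta_shift <- blend(rules$a1$unsat_skel_eta_shift, 0)
      if (label$category == "cerebroside" && label$saturation > 0L) {
        pk$fwhm[ib] <- pk$fwhm[ib] * skel_gain
        pk$eta[ib] <- pmin(pk$eta[ib] + eta_shift, 1)
      }
    }
  }

  # measured-ratio calibration: compute the reference apex from the bands
  # that are already fixed, then solve the diagnostic amplitudes
  grid <- canonical_grid()
  fixed <- pk[-c(i691, i1023, i1330), , drop = FALSE]
  near1567 <- grid[abs(grid - 1567) <= 8]
  a_ref <- max(peak_sum(near1567, fixed))
  tail_at <- function(x) peak_sum(x, fixed)
  pk$amplitude[i1330] <- max(r1 * a_ref - tail_at(1330), 0.01)
  pk$amplitude[i691] <- max(r691 * a_ref - tail_at(691), 0.01)
  pk$amplitude[i1023] <- max(r1023 * a_ref - tail_at(1023), 0.01)
  pk
}

#' Generate one synthetic SERS spectrum
#'
#' Builds the noise-free 19-band signature of the analyte at the given
#' concentration (see [synthetic_config()] for the rule set), adds per-peak
#' center jitter and additive Gaussian intensity noise, and returns the raw
#' spectrum on the canonical grid (not yet normalized; run
#' [preprocess_spectrum()] before featurization).
#'
#' @param label an [analyte_label()].
#' @param conc molar concentration (ignored for blanks; `NA` allowed there).
#' @param cfg a [synthetic_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [spectrum()]. Concentrations below the detection limit produce
#'   a blank-like spectrum, a warning, and the meta flag `below_lod`.
#' @export
generate_spectrum <- function(label, conc = NULL, cfg = synthetic_config(),
                              seed = NULL) {
  stopifnot(is_analyte_label(label))
  if (label$category != "blank") {
    if (is.null(conc) || is.na(conc)) {
      stop("non-blank analytes need a concentration", call. = FALSE)
    }
    if (conc > cfg$c_max) {
      stop("concentration above c_max is outside the calibrated range",
           call. = FALSE)
    }
  }
  below_lod <- label$category != "blank" && conc < cfg$lod
  if (below_lod) {
    warning(sprintf("concentration %g M is below the detection limit %g M; ",
                    conc, cfg$lod),
            "generating a blank-like spectrum", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  pk <- signature_peaks(label, conc, cfg)
  if (cfg$jitter_sd > 0) {
    pk$center <- pk$center + stats::rnorm(nrow(pk), 0, cfg$jitter_sd)
  }
  if (cfg$band_noise_sd > 0) {
    pk$amplitude <- pk$amplitude *
      exp(stats::rnorm(nrow(pk), 0, cfg$band_noise_sd))
  }
  if (cfg$r1330_noise_sd > 0) {
    i1330 <- which.min(abs(pk$center - 1330))
    pk$amplitude[i1330] <- pk$amplitude[i1330] *
      exp(stats::rnorm(1L, 0, cfg$r1330_noise_sd))
  }
  grid <- canonical_grid()
  baseline <- 0
  if (cfg$baseline_scale > 0) {
    # broad fluorescence-like background, redrawn per replicate: an offset,
    # a tilt and a wide Gaussian hump (removed downstream by airPLS)
    b0 <- stats::runif(1, 0.3, 1)
    b1 <- stats::runif(1, -0.5, 0.5)
    hump_a <- stats::runif(1, 0.5, 2)
    hump_mu <- stats::runif(1, 700, 1500)
    hump_w <- stats::runif(1, 300, 600)
    baseline <- cfg$baseline_scale *
      (b0 + b1 * (grid - 1100) / 700 +
         hump_a * exp(-((grid - hump_mu) / hump_w)^2))
  }
  y <- peak_sum(grid, pk) + baseline
  if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, cfg$noise_sd)
  meta <- list(analyte = nomenclature(label),
               concentration_M = if (label$category == "blank") "" else
                 format(conc, scientific = TRUE),
               synthetic = "true")
  if (below_lod) meta$below_lod <- "true"
  spectrum(grid, y, meta)
}

#' Derive a replicate seed from a master seed and counter
#'
#' Splittable-seed contract used by the dataset generators: every
#' replicate's RNG seed is a deterministic function of the master seed and
#' a running counter, so datasets of any size are reproducible and
#' extensible. The result always fits a 32-bit integer.
#'
#' @param master integer master seed.
#' @param counter non-negative integer replicate counter.
#' @return integer seed.
#' @export
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) %% 65536 * 32749 + counter * 7919) %%
               2147483647)
}

#' Generate a labeled synthetic dataset
#'
#' The default design reproduces the study layout at the top calibration
#' concentration: 14 analyte classes (blank, glucose, galactose, 11
#' cerebrosides) times 60 replicates = 840 spectra. Replicate seeds are
#' derived from the master seed by counter, so the same seed yields a
#' bit-identical dataset.
#'
#' @param cfg a [synthetic_config()].
#' @param conc molar concentration for the analyte classes (default
#'   `cfg$c_max`).
#' @param classes list of [analyte_label()] (default [analyte_panel()]).
#' @param replicates replicates per class (default `cfg$replicates`).
#' @param seed master seed (default `cfg$master_seed`).
#' @return a [spectrum_set()].
#' @export
generate_dataset <- function(cfg = synthetic_config(), conc = cfg$c_max,
                             classes = analyte_panel(),
                             replicates = cfg$replicates,
                             seed = cfg$master_seed) {
  n <- length(classes) * replicates
  spectra <- vector("list", n)
  labels <- vector("list", n)
  concs <- character(n)
  reps <- integer(n)
  counter <- 0L
  i <- 0L
  for (lab in classes) {
    for (r in seq_len(replicates)) {
      counter <- counter + 1L
      i <- i + 1L
      spectra[[i]] <- generate_spectrum(
        lab, if (lab$category == "blank") NA else conc, cfg,
        seed = derive_seed(seed, counter))
      labels[[i]] <- lab
      concs[i] <- if (lab$category == "blank") NA_character_ else
        format(conc, scientific = TRUE)
      reps[i] <- r
    }
  }
  spectrum_set(spectra, labels, concs, replicate = reps)
}

#' Generate a binary GlcCer24:1/GalCer24:1 mixture spectrum
#'
#' Convex combination of the two noise-free endmember signatures at the
#' total concentration, weighted by mol fraction, plus additive intensity
#' noise.
#'
#' @param frac_gal mol percent of GalCer24:1 in \[0, 100\].
#' @param total total molar concentration (default 1e-4, i.e. 100 uM).
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return a [spectrum()] whose meta records both component concentrations.
#' @export
generate_mixture <- function(frac_gal, total = 1e-4,
                             cfg = synthetic_config(), seed = NULL) {
  if (frac_gal < 0 || frac_gal > 100) {
    stop("frac_gal must lie in [0, 100] mol%", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  glc <- analyte_label("cerebroside", "glc", 1L, 24L)
  gal <- analyte_label("cerebroside", "gal", 1L, 24L)
  grid <- canonical_grid()
  y_glc <- peak_sum(grid, signature_peaks(glc, total, cfg))
  y_gal <- peak_sum(grid, signature_peaks(gal, total, cfg))
  f <- frac_gal / 100
  y <- (1 - f) * y_glc + f * y_gal
  if (cfg$baseline_scale > 0) {
    y <- y + cfg$baseline_scale *
      (stats::runif(1, 0.3, 1) +
         stats::runif(1, -0.5, 0.5) * (grid - 1100) / 700 +
         stats::runif(1, 0.5, 2) *
           exp(-((grid - stats::runif(1, 700, 1500)) /
                   stats::runif(1, 300, 600))^2))
  }
  if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, cfg$noise_sd)
  spectrum(grid, y, list(
    analyte = "GlcCer24:1+GalCer24:1",
    frac_gal = format(frac_gal),
    conc_gal_M = format(total * f, scientific = TRUE),
    conc_glc_M = format(total * (1 - f), scientific = TRUE),
    synthetic = "true"))
}

#' Generate a mixture calibration or blind-test set
#'
#' @param fracs vector of GalCer24:1 mol percentages.
#' @param replicates replicates per composition.
#' @param total total molar concentration (default 1e-4).
#' @param cfg a [synthetic_config()].
#' @param seed master seed.
#' @return list: `set` (a [spectrum_set()] labeled GalCer24:1 for
#'   bookkeeping), `frac_gal` (numeric vector parallel to the set).
#' @export
generate_mixture_set <- function(fracs, replicates = 60L, total = 1e-4,
                                 cfg = synthetic_config(),
                                 seed = cfg$master_seed) {
  n <- length(fracs) * replicates
  spectra <- vector("list", n)
  frac_out <- numeric(n)
  counter <- 0L
  i <- 0L
  for (f in fracs) {
    for (r in seq_len(replicates)) {
      counter <- counter + 1L
      i <- i + 1L
      spectra[[i]] <- generate_mixture(f, total, cfg,
                                       seed = derive_seed(seed, counter) + 1L)
      frac_out[i] <- f
    }
  }
  gal <- analyte_label("cerebroside", "gal", 1L, 24L)
  set <- spectrum_set(spectra, rep(list(gal), n),
                      rep(format(total, scientific = TRUE), n))
  list(set = set, frac_gal = frac_out)
}
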