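---
title: "Models and methods behind the SERS chemical taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the SERS chemical taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epimeric cerebrosides — glucosylceramides (GlcCerX:Y) and
galactosylceramides (GalCerX:Y) — differ only in the orientation of one
hydroxyl on the hexose (C4 equatorial vs axial) plus the acyl chain length
X and saturation degree Y, yet they mark very different diseases. On a
silver SERS substrate functionalized with 4-mercaptophenylboronic acid
(MPBA), each epimer forms a covalent boronate-ester adduct whose reporter
spectrum shifts in characteristic ways. `serstax` implements the full
chain from raw spectrum to identity and concentration:

1. **Preprocessing** — airPLS baseline removal, min–max normalization
   (max = 1), resampling to 1200 points over 400–1800 cm⁻¹.
2. **Featurization** — each spectrum is parameterized as 19 skewed
   pseudo-Voigt peaks × 5 attributes (position, intensity, FWHM, skew,
   Gaussian/Lorentzian ratio) = 95 features.
3. **Taxonomy** — four sequential binary random-forest classifiers
   (blank/epimer, monosaccharide/cerebroside, saturated/unsaturated,
   GlcCer/GalCer) and two hexose-specific chain-length support-vector
   regressors, with executive nomenclature assembly and majority voting.
4. **Quantification** — per-analyte log₁₀-concentration regression over
   10⁻⁴–10⁻¹⁰ M, and a binary-mixture composition model at 100 µM total.
5. **Synthetic generator** — a rule table mapping structural
   characteristics to spectral parameters, which provides the labeled
   test bed for everything above.

## Spectral model and preprocessing

The single-peak model is a *split pseudo-Voigt*: a mixture
`eta·L + (1−eta)·G` of unit-apex Lorentzian and Gaussian profiles sharing
one FWHM, with a side-dependent width `fwhm·(1±skew)` so that `skew = 0`
is exactly symmetric and the five attributes stay independent. The
`ratio` attribute of the feature schema is the mixing fraction `eta`;
`intensity` is the fitted apex amplitude (the diagnostic ratios in this
field are peak-height, not area, ratios).

airPLS estimates the baseline with an order-2 Whittaker smoother whose
fidelity weights are reweighted iteratively: points above the running
baseline get weight 0, points below get exponentially growing weight.
Defaults are `lambda = 1e5`, 30 iterations, convergence when the negative
residual mass falls below 0.1% of the signal; the smoothness penalty is
deliberately config-exposed because no instrument-specific value can be
claimed. The preprocessing order — baseline, normalize, then regrid — keeps
the baseline estimate on the measured samples.

## Peak fitting

The 95-parameter fit of 19 components against 1200 points is solved in
two phases: a block-wise warm start (each overlap region — singletons plus
the 1567/1575/mobile-a1 triplet — fitted by bounded Levenberg–Marquardt
against the spectrum minus the other regions' model), then a joint
refinement of all 19 components over the full grid using an analytic
Jacobian. The joint pass matters: the summed far tails of the Lorentzian
components form a smooth "tail sea" that a purely local fit mis-attributes,
biasing the shape parameters of weak bands. Two numerical choices prevent
well-known degeneracies: the 8 cm⁻¹-separated 1567/1575 pair is fitted with
skew pinned to zero (with per-peak skew free, the pair is not
identifiable), and the mobile a1 band (window 1584–1603 cm⁻¹) is
initialized at the apex of the data inside its window rather than at the
seed. Center windows, width bounds and the shared-region partition all
live in `peak_seed_table()`, which is replaceable without code changes —
the default 19-band list is an explicit stand-in built from the eight
mechanistically assigned bands padded with fixed filler bands.

Fitted intensities are referenced to the 1567 cm⁻¹ a1 reporter band
(the internal standard all diagnostic ratios use). This removes the
per-spectrum min–max scale, which otherwise differs between analyte
classes and would leak a class-specific global factor into every
amplitude feature.

## The synthetic generator

The generator encodes five structure→spectrum rules, in measured units
(post-normalization apex-height ratios and positions):

* **R1** I₁₃₃₀/I₁₅₆₇: blank 0.6, monosaccharide < 0.07, cerebrosides at
  class-specific values spanning the printed 0.07–2.2 range. The 11 class
  values interleave the two hexoses and are scrambled with respect to
  chain length, so the capture ratio identifies classes without
  masquerading as a hexose or chain feature.
* **R2** a1 ν(CC) center: blank 1603, saturated 1601, unsaturated 1591
  (Glc) / 1595 (Gal) cm⁻¹ with intensity gain. Because the distal C=C
  interacts with the reporter ring, unsaturation also broadens the a1
  mode, perturbs the b2 and 1480 cm⁻¹ modes and shifts several skeletal
  bands — a multi-band signature rather than a single-band one.
* **R3** ring-deformation + C–S position: blank 414, GlcCer 414.2–416.5,
  GalCer 417.5–419 cm⁻¹, linear in chain length within each range.
* **R4/R5** chain-length channels: I₁₀₂₃/I₁₅₆₇ (Glc) and I₆₉₁/I₁₅₆₇
  (Gal) rise linearly with X; the matching band additionally broadens and
  drifts slightly with X (heterogeneous adduct configurations), giving
  the regressors redundant height-, width- and position-based readouts.

**Concentration** enters through two channels. The identity rules above
are at full strength at any concentration at or above the detection limit
(10⁻¹⁰ M) and vanish below it: boronate capture saturates the reporter,
so the *shape* of the normalized fingerprint holds down to the LOD — which
is precisely why classification of an epimer measured at trace levels
against a model trained at 10⁻⁴ M can work at all. The *analyte-loading*
channel modulates amplitudes, widths and mixing fractions of the
non-diagnostic reporter bands by the log-linear response
`alpha(c) = (log10 c − log10 LOD)/(log10 c_max − log10 LOD)` clipped to
[0, 1]; bands sit at their blank values at full loading and drift as
loading decreases, and this is what the concentration regressors read.
Loading-induced widths *increase* toward the LOD; narrowing them instead
runs the fitted widths into the resolution of the 1.17 cm⁻¹ grid and
biases the bottom decade.

**Noise model.** Four stochastic terms, each with a physical reading:
additive intensity noise (σ = 0.01 of the unit maximum), per-peak center
jitter (σ = 0.3 cm⁻¹), per-band log-normal enhancement noise (σ = 0.02;
plasmonic hot-spot variability), and a stronger log-normal term on the
1330 cm⁻¹ capture band alone (σ = 0.2; boronate-ester formation is
competition-sensitive, and measured capture-ratio boxplots are wide).
Each replicate also receives a broad fluorescence-like background (offset
+ tilt + wide Gaussian hump, scale 0.1) which the airPLS step removes.
These last two terms are essential for honest machine-learning behaviour,
not decoration: without within-class variance in the quirk directions, a
deterministic pipeline produces class-constant artifact features that a
deep forest memorizes and a few-class regressor interpolates — both
destroy generalization to held-out classes, which is the entire point of
forward prediction.

Mixtures are convex combinations of the two noise-free endmember
signatures weighted by mol fraction, plus the noise terms, matching the
linear calibration behaviour of the study design.

What the generator does *not* emulate: real hot-spot spatial statistics,
cosmic rays, detector nonlinearity, matrix effects from biofluids, or
any deviation from log-linear concentration response. Passing tests on
this test bed demonstrate the pipeline's correctness and the internal
consistency of the published behaviour, not performance on new
instrument data.

## Taxonomy design

Each stage answers a conditional question along the routing path, so
stage training sets are label-filtered: stage 2 never sees blanks,
stages 3–4 and the regressors see cerebrosides only. Random forests use
1000 trees, √p candidate features per split, depth ≤ 10 and no splitting
of nodes below 5 samples; determinism comes from a per-model seed
recorded in the metadata. A stage whose winning probability is ≤ 0.5 is
flagged low-confidence but never halts routing. Majority voting takes the
modal routed class per stage and the mean raw chain estimate
(mean ± SD, then rounded to the nearest integer — deliberately *not*
snapped to the panel's chain set, since consensus values like 13 ± 2 are
meaningful outputs).

The chain-length regressors are ε-SVRs on PCA-compressed features.
Three regression choices were genuinely open and are settled as follows:

* **Kernel: linear.** Forward prediction must extrapolate to chain
  lengths absent from training (the X = 8 and X = 24 hold-outs). An RBF
  machine's prediction far from its support collapses to the bias term,
  which makes extrapolation structurally impossible; the linear machine
  extends the calibration line. The kernel is config-exposed.
* **Scaling: fixed unit-aware scales** (1 cm⁻¹ for positions and widths,
  0.1 for the dimensionless attributes) instead of training-SD
  standardization. SD-standardization inflates near-constant nuisance
  features to unit variance, and a regressor interpolating only four or
  five class means will happily spend weight on them.
* **Compression: components explaining 99% of variance, capped at 15.**
  With the fixed scaling, the top components carry the class structure
  and the cap bounds the interpolation ambiguity.
* **ε = 0.01.** The SVR's tolerance tube is in units of the scaled
  target; the default 0.1 corresponds to ±3.5 mol% for the mixture model
  and ±0.2 decades for the concentration model, which caps calibration
  quality far above the noise floor.

The split protocol for forward prediction defaults to stratified 80/20
resampling of the training pool per iteration; a rotating stratified
5-fold variant is available (`protocol = "cv5"`). The mini protocol used
in the automated experiments runs 10 iterations; the study-scale setting
is 100.

## Quantification

The regression target is log₁₀ molarity — linearity over seven orders of
magnitude is only meaningful on a log scale. Calibration statistics
follow chemometric convention: R² is the squared Pearson correlation
between predicted and true values on the evaluation split, RMSEP its
root-mean-square error. Blind-test errors are reported on the replicate
set's mean predicted concentration (the log-space mean of a 10-sample
blind set), the convention of the study's blind-test tables; per-spectrum
RMSEP is reported alongside. The mixture model predicts the GalCer24:1
mol% and derives GlcCer24:1 by complement, so predicted pairs always sum
to the fixed 100 µM total.

## Problem sizes and reproducibility

The automated experiments run at the design scale of the study: 14
classes × 60 replicates at 10⁻⁴ M (840 spectra) for classification,
7 decades × 60 replicates per dilution series, 5 × 60 mixture
calibration spectra plus 3 × 10 blind mixtures, and 10 probe replicates
per decade for concentration transfer; forward prediction uses the mini
protocol (10 iterations per hold-out). Every random draw derives from a
master seed through a splittable counter scheme (`derive_seed()`), so
datasets of any size are bit-reproducible and extensible.

## Known limitations

* The identities of all 19 study peaks are not public; the default seed
  table is an explicit stand-in and is replaceable.
* The generator's rule magnitudes inside the printed ranges (R1 class
  values, chain-channel slopes, unsaturation side-effects, noise scales)
  are design choices; only the ranges and endpoints are anchored.
* The two-channel concentration model makes identity transfer at trace
  concentrations possible *by construction*; it encodes the published
  behaviour rather than deriving it from adsorption physics.
* `embed_2d()` provides the PCA view only; no t-SNE backend is bundled.
* Binary mixtures only, at a fixed total concentration.
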