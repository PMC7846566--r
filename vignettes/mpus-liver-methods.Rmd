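---
title: "Multiparametric ultrasound characterization of fatty liver: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric ultrasound characterization of fatty liver: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpusliver)
```

# Scope and scientific background

Nonalcoholic fatty liver disease begins with diffuse accumulation of fat
vacuoles in hepatocytes (steatosis). Three quantitative ultrasound readouts
are sensitive to this process, each through a different physical channel:

* **H-scan tissue characterization.** Backscattered echo spectra shift with
  scatterer size: large structures return low-frequency content, sub-wavelength
  aggregates return high-frequency content. Matched filters built from
  Gaussian-weighted Hermite functions `GH_n(t) = H_n(t/σ) exp(-t²/2σ²)`
  measure the relative echo energy at a low (GH₂, "red") and a high (GH₈,
  "blue") analysis frequency; the per-pixel ratio `B/(R+B)` colorizes relative
  scatterer size. Steatotic parenchyma shifts blue.
* **Shear wave elastography (SWE).** An acoustic-radiation-force push launches
  a laterally propagating shear wave tracked at kilohertz frame rates in
  complex baseband (IQ) data. Its speed (SWS, m/s) reflects stiffness and its
  lateral amplitude decay (SWA, Np/m) viscous damping; fat lowers SWS and
  raises SWA.
* **Contrast-enhanced ultrasound (CEUS).** A microbubble bolus transits the
  liver; the time-intensity curve (TIC) of a parenchymal region yields peak
  enhancement (PE, surrogate blood volume) and wash-in rate (WIR, surrogate
  flow). Normalizing by the inferior vena cava (PE-nLP, WIR-nLP) removes gain
  and dose dependence. Steatosis constricts the microvasculature and lowers
  both ratios.

Six features per subject and session — SWS, SWA, B-scan intensity, H-scan
intensity, PE-nLP, WIR-nLP — feed a Z-scored PCA and a Gaussian-kernel SVM
that separates normal, low-fat and high-fat livers. Histology fat-fraction
scoring of H&E sections provides the anatomical reference.

The in vivo data behind this design are not publicly deposited, so the package
pairs every analysis stage with a synthetic generator whose ground truth is
known by construction. All quantitative claims a test makes are
parameter-recovery claims against those generators.

# The synthetic world

The generators' defaults describe one fixed "study world"; they are not tuned
per test.

* **RF phantoms** (`gen_rf_phantom()`): scan lines are sums of
  Poisson-placed scatterer echoes, each a Gaussian-enveloped sinusoid at the
  pulse center frequency times a per-region spectral shift (> 1 emulates finer
  scatterers). Amplitude attenuation follows `coeff × f[MHz] × 2z[cm]` dB with
  the liver-standard 0.3 dB/cm/MHz as the default correction constant. No
  diffraction, beam profile, or speckle-statistics fidelity is attempted; the
  phantom controls *spectra* directly because the H-scan argument is spectral.
* **Shear movies** (`gen_shear_movie()`): the displacement truth is a
  single-frequency damped plane wave
  `u(x,t) = A e^{-αx} sin(2πf(t - x/c))`, zero before arrival, written into an
  IQ ensemble as axial phase modulation `exp(i·4π f_demod u / c_sound)` on a
  static speckle phase plus complex white noise. A single-frequency wave makes
  speed and attenuation truth exact and estimator bias measurable. Default:
  200 Hz wave, 1600 Hz PRF, 0.625 mm lateral pitch, 384 positions (a 0.24 m
  synthetic aperture — far wider than an in vivo field of view, chosen so the
  wavenumber resolution resolves attenuations down to 50 Np/m), amplitude
  10 µm, 25 dB IQ SNR.
* **CEUS series** (`gen_ceus_series()`): ROI mean intensities follow a
  lognormal bolus `I(τ) = C e^{-(ln τ - μ)²/2σ²}/τ`, the standard first-pass
  form, because its maximum and maximal slope have closed forms — the
  generator *inverts* those closed forms so the requested PE and WIR are exact
  analytic properties of the curve. IVC enhancement always precedes the liver.
* **Histology** (`gen_histology()`): non-overlapping white ellipses
  (macrovesicular vacuoles, default radius 15 ± 4 µm) on a noisy eosin-pink
  background, placed until the white-area fraction is within 0.2 percentage
  points of the target; the realized fraction is the recorded truth. Vacuoles
  keep a 2 px border margin so that truth is never confounded with the
  slide-background exclusion.
* **Feature tables** (`gen_feature_table()`): per-cohort Gaussians. The
  default `study_cohorts()` mirror the animal design — 21 rats (9 control,
  12 on a steatogenic diet) at weeks 0/2/6, pooled into 39 normal, 12
  low-fat and 12 high-fat rows. The published work reports group values only
  as boxplots, so the default means/SDs are package choices that reproduce
  the reported *direction* of each trend; the high-fat shear values use the
  published example pair (1.36 m/s, 113.9 Np/m). They are documented as
  package defaults, not as source-study numbers.

A green recovery test therefore establishes that the estimator inverts its own
stated forward model at the stated noise level — not that it would meet the
same tolerance on scanner data, where beam physics, reverberation and motion
are present.

# Estimators and numerical choices

## H-scan reconstruction

Processing per line: GH₂/GH₈ convolution ("same" size; samples within one
kernel half-length of the edges are flagged invalid), division by the kernel
signal energy `√E_n`, zero-phase band-pass to 5–18 MHz, Hilbert envelope. The
B-scan channel is the envelope of the *unfiltered* line. The energy
normalization is applied to filter outputs; applying it to the taps is
mathematically identical for convolution.

Band-pass is realized as an FFT-domain mask with raised-cosine edges: exactly
zero-phase, so the R, B and B-scan channels stay co-registered.

**Kernel time scale.** The GH₂:GH₈ spectral-peak ratio is fixed by the orders,
so one shared σ only slides the pair along the frequency axis. Placing the
pair's geometric-mean peak at the 15 MHz transducer center frequency would
push the GH₈ peak to ≈ 20 MHz, outside the 5–18 MHz analysis band that
follows it (the band would truncate the matched filter it is supposed to
pass). `hscan_kernels()` therefore uses the largest geometric-mean target that
keeps the GH₈ peak at ≤ 95% of the upper band edge, capped by the center
frequency; with the defaults the peaks land at ≈ 7.4 and ≈ 17.1 MHz, both in
band. Consequences: reported H-scan intensities are device- and σ-relative
(as they are for any fixed kernel choice), and the `B/(R+B)` sweep is
monotone in echo frequency across the whole band, which is the property the
tests pin down.

**Attenuation correction** is a bulk center-frequency gain
(`10^(0.3 · 15 · 2z/20)` at default), not a per-frequency correction — the
correction constant is a single global scaling value, and the tests verify
round-trip flatness to ≤ 0.5 dB/cm on a phantom generated with the same
coefficient.

## Shear wave speed and attenuation

Displacements come from the classic lag-1 slow-time autocorrelation of IQ
data (`d = c·∠Σ conj(s_t)s_{t+1} / 4π f_demod`), averaged over an axial
kernel, cumulatively summed. Phase wrap (|angle| ≥ 0.95π) flags the field as
aliased.

The f–k spectrum is the 2D DFT of `u(x,t)` at one depth row after mean
removal and tapering. The estimator takes the global maximum in the
positive-(k, f) quadrant: `f*` is the analysis frequency, speed is
`2πf*/k_peak` with sub-bin peak localization, and attenuation is the
half-width at half-maximum of a least-squares Lorentzian fit to `|U(k)|²` —
exact for an exponentially damped sinusoid — with the taper's own measured
broadening subtracted in quadrature (`fit_lorentzian()` seeds the nonlinear
fit with a weighted quadratic regression of `1/P(k)`, which is exact for a
Lorentzian).

Numerical choices that matter:

* **Lateral taper is one-sided.** A symmetric Tukey window multiplies the
  near edge — exactly where the damped wave's energy is concentrated — and
  destroys the one-sided exponential onset whose `1/k²` tails carry the
  attenuation. Noiseless checks showed −16/−32/−42% attenuation bias at
  50/100/150 Np/m with a symmetric Tukey(0.25) versus < 0.3% with a far-edge
  only half-Tukey. The package tapers laterally on the far edge only and
  keeps a symmetric Tukey(0.25) in slow time.
* **Steady-state analysis window.** `swe_measure()` restricts the slow-time
  axis to the trailing frames (default 128) so every lateral position
  contributes the same effective observation time at `f*`; otherwise the
  arrival-dependent window length multiplies the spatial profile by a
  spurious decay.
* **Taper-broadening calibration** is measured once per grid (cached) on an
  undamped synthetic wave at the same `(k, f)` and removed in quadrature;
  below that resolution floor the attenuation estimate is reported as-is with
  the floor attached rather than clamped.
* Multiple depth rows, when available, are aggregated by the **median** (the
  per-liver aggregation statistic is not specified by the source protocol;
  median is the robust default and is flagged as a choice).

With the default grid the chain recovers the 3 × 3 acceptance grid
(1–2 m/s × 50–150 Np/m, 25 dB SNR) with median speed bias ≈ 0.02% and
attenuation bias ≈ 0.5%, far inside the 5%/10% contracts.

## CEUS wash-in parameterization

`extract_tic()` averages the ROI per frame, detects bolus arrival as the
first sample above the pre-injection mean + 3 SD (1 s leading window; the
threshold is a package choice), and subtracts the pre-arrival baseline — PE
is therefore baseline-subtracted, and documented as such. `fit_tic()` fits
the lognormal bolus by nonlinear least squares *only* from arrival through
the first post-peak sample (the wash-in restriction that insulates the fit
from recirculation; tests confirm post-peak perturbations leave parameters
within 1%). PE and WIR are the fitted curve's analytic maximum and maximal
derivative — WIR is a model property, not a secant slope, which is what makes
it noise-robust. Degenerate shapes take explicit paths: still-rising records
are errors; plateaus and non-convergent fits fall back to model-free
estimates (max of the median-smoothed curve, max finite-difference slope)
with a `fallback` flag.

## Histology fat fraction

Tissue is everything except border-connected near-white pixels (slide
background). Fat candidates are bright (`V > 0.75`), low-saturation pixels;
the saturation threshold is Otsu's threshold computed on tissue pixels,
*capped at 0.15* so a fat-free section is not split on noise (an uncapped
Otsu always finds a split). Morphological opening then closing with a
3 px disc and a 50 µm² minimum component area complete the cleanup; all radii
and areas are arguments. The reported fraction is fat area over *tissue* area
(not image area) — the denominators coincide for the generator's full-tissue
images, and the choice is documented here because either reading is defensible
for real slides.

## Classification

Z-scoring uses the sample-SD convention (n − 1); `{1,2,3}` standardizes to
`{-1,0,1}`. The split is stratified and seeded; standardization and PCA are
fitted on the 80% training split only. Hyperparameters are grid-searched
(`C ∈ 10^{-1..3}`, `γ ∈ 10^{-3..1}`) with stratified 5-fold cross-validation
on the training split — the published classifier cites an optimization recipe
whose details are not reproducible from the text, so a standard CV grid
search stands in, and the searched grid is logged in the report. The SVM dual
is solved with `quadprog` (no SVM library ships in the target environment);
multiclass is one-vs-one voting with decision-value tie-breaks. Three
accuracies are reported and labelled — train, held-out test, and overall
(trained-on-80%, predicted-on-all) — because published headline accuracies of
this kind mix those conventions and the package refuses to guess which one a
number is.

### The PCA "contribution" measure and its ceiling

`pca_contributions()` attributes variance to features as eigenvalue-weighted
squared loadings over the retained components,
`c_j = 100·Σ_k λ_k w_jk² / Σ_k λ_k`. Two structural properties deserve
emphasis:

* with **all** components retained on Z-scored data every feature contributes
  exactly 100/6 (each standardized feature has unit variance), so only a
  reduced set — typically the first three, as used for decision-plane
  visualization — is informative;
* with **three of six** components retained, `Σ_k λ_k w_jk² ≤ var_j = 1` and
  `Σ_{top-3} λ_k ≥ 3`, so *no* feature can exceed 33.3% under this
  definition, and in practice (correlated features, eigenvalue sum ≈ 5) the
  ceiling is nearer 20%. Claims that one feature "contributes > 35%" are
  necessarily based on some other normalization; under this one, expect the
  dominant feature to show up as the *largest* contribution, not as a large
  absolute percentage. This bound is a property of the measure, not a bug,
  and the acceptance suite keeps the stricter published-style check in place
  (failing, with this explanation) rather than silently redefining the
  measure.

`mann_whitney_u()` uses `U = min(U_x, U_y)` with midranks, an exact
enumeration p-value (dynamic programming over the lattice-path recurrence)
whenever `n_x·n_y ≤ 400` without ties, and the tie- and continuity-corrected
normal approximation otherwise; exactness is tested against brute-force
enumeration of all labelings up to n = 8.

# The pipeline

`run_study()` is the end-to-end analogue: per subject and week it generates
stage inputs from the configured truth trajectories (with log-normal or
Gaussian between-subject scatter), runs all four measurement stages, and
assembles the six-feature table; then per-feature Mann–Whitney tests
(control vs diet arm per week) and the two- and three-category SVMs. Stage
seeds derive deterministically from the master seed and the (subject, week,
stage) path, so a run is reproducible to the byte without seed bookkeeping,
and any stage failure aborts naming the subject and stage. The default truth
table keeps the arms identical at week 0 and separates them by week 6
(slower, more attenuated, brighter, bluer, less perfused in the diet arm),
with week 2 intermediate — the reported week-6 group separation expressed in
generator units.

# Known limitations

* Generators are oracles, not simulators: no push-beam physics, no
  diffraction or speckle-statistics fidelity, no microbubble kinetics beyond
  the lognormal first pass, no real staining variability.
* The shear-wave world is single-frequency and non-dispersive; the estimator
  reports the ridge at the dominant frequency and would need a broadband
  world to probe dispersion.
* H-scan intensities are σ- and device-relative; only orderings and
  monotonicity are transferable claims.
* The SVM hyperparameter search is a stand-in for an unspecified published
  recipe; with widely separated cohorts the result is insensitive to this,
  which is the regime the acceptance checks pin.
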