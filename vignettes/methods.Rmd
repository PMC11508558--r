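---
title: "Methods: focus measures, the PCA reference, and the ranking framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focus measures, the PCA reference, and the ranking framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsfocus)
```

## Scope and model

`hsfocus` evaluates image-based autofocus for through-focus stacks: an
ordered series of frames of one field of view, captured at strictly
increasing focal positions, each frame either spatial×spatial
(conventional video) or spatial×spectral (an instantaneous pushbroom
hyperspectral frame).  The package covers the *evaluation* methodology
only — focus measures, the PCA reference, curve criteria, ranking, and
a synthetic data generator.  It deliberately contains no focus *search*
strategy (hill climbing, golden section), no instrument control, no
spectral calibration, and no speed benchmarking: stacks are assumed to
be exhaustively sampled, and wall-clock time is never a ranking input.

## Conventions shared by the focus measures

* **Axis semantics.** The first (row) index of a frame is the spatial
  axis of a hyperspectral frame.  All direction-selective operators
  (ABG, SAG, BRE, BOD, and the autocorrelation lags of ACF/VOL5)
  difference along that axis, consistent with the printed forms
  `I(i+k, j)` of their definitions; `fm_options(axis = 2)` flips this
  for data stored the other way around.
* **Boundary policy.** Every kernel operator uses the "valid" region
  only.  Padded boundaries would contribute artificial gradients that
  scale with frame content, which matters precisely in the blurred
  frames where measures are smallest.
* **Thresholds.** TEN1/TEN2 gate on the gradient magnitude, ABG/SAG/BRE
  on the absolute difference, with a single θ in intensity units.  The
  default is θ = 0 (deterministic, reproducible); `threshold = "auto"`
  sets θ to twice a robust noise scale — the MAD of the dark frame if
  the stack carries one, otherwise a median-absolute-difference
  estimate from the frame itself.  Thresholding suppresses the noise
  floor in the curve tails but does not move the peak on the synthetic
  scenes, which is why the deterministic default is safe for testing.
* **Histograms.** ENT, LOG and WHS use exact integer gray levels up to
  `2^bit_depth` when the frame holds integer counts, and equal-width
  256-level binning otherwise.  WHS keeps the empirically published
  exponents (power 5, fifth root) as defaults.
* **Signed measures.** LOG as printed multiplies squared deviations by
  `log(p_l) ≤ 0` and is therefore non-positive; VOL5 can change sign.
  `normalize_curve()` maps an all-non-positive curve to its magnitude
  before the min-shift-and-scale, so "peak = best focus" semantics hold
  uniformly.  Normalization itself always shifts the minimum to 0 and
  scales the maximum to 1, making curves from stacks of different
  dynamic range comparable.
* **DCT scalarization.** The blockwise DCT measure reduces each
  orthonormal 8×8 DCT-II block to its squared AC energy (all squared
  coefficients minus the DC term).  This matches the measure's
  high-frequency-energy interpretation, is offset-invariant, and by
  Parseval equals the within-block pixel energy around the block mean.
  The mid-frequency DCT operator is the printed 4×4 ±1 mask.
* **Diagonal Laplacian.** The DLF diagonal masks are the standard
  `1/sqrt(2)`-weighted diagonal Laplacians; the typographically garbled
  printed matrices were replaced by the forms in the method's cited
  source.
* **Wavelets.** One decomposition level of the Daubechies-6 filter with
  periodic extension.  Periodization keeps the transform orthonormal on
  even-sized frames, which gives two exact test anchors: detail bands
  vanish on constant input, and coefficient energy equals pixel energy.

## The PCA focus reference

For each frame the package standardizes with the global scalar mean and
population standard deviation (a per-pixel mean/sd image is not defined
for a single frame), forms the column covariance
`C = ImᵀIm/(WH)` over the smaller frame axis, symmetrizes, clamps
eigenvalues below `1e-10·λ_max` to zero, and counts the components
needed to reach the variance fraction (default 0.99, from the 98–99 %
range the method prescribes).  The reference focus is the global
minimum of the count curve; exact ties resolve to the index nearest the
stack centre, which is deterministic and unbiased for the symmetric
curves the generator produces.

Why the count has its minimum at focus is worth stating precisely,
because it drove the design of the synthetic scene.  The mechanism is
signal-to-noise: defocus blur destroys signal variance while detector
noise is constant, so standardized defocused frames are progressively
noise-dominated, and white noise spreads variance uniformly over the
whole spectrum — the count climbs toward the frame dimension.  For the
mechanism to identify the *sharpest* frame, the in-focus scene itself
must concentrate its variance in few components.  A real pushbroom
frame does: it is approximately a sum of a few (spatial abundance
profile) × (spectral signature) outer products, i.e. low-rank.  A
full-rank broadband texture would invert the near-focus behaviour (the
sharp frame would need *more* components than a mildly blurred one,
giving a W-shaped curve), which is why the generator's soil-like scene
is an explicitly low-rank mixture — see below.

## Curve criteria and ranking

* `d_acc`: |peak − reference| in steps.  Peak plateaus resolve to the
  plateau midpoint; when a reference is supplied the plateau member
  nearest the reference wins (the two published tie rules, combined so
  both are deterministic).
* `d_uni`: number of secondary local maxima with topographic prominence
  ≥ 0.05 of the normalized height.  The published criterion does not
  state a per-curve rule (only averaged values like 0.02 appear), so a
  prominence-filtered *count* is used: it degrades gradually with noise
  and reduces to a binary indicator on clean curves.  The threshold is
  configurable.
* `d_50`, `d_90`: widths of the contiguous super-level set around the
  global peak at 50 %/90 % of maximum, linearly interpolated between
  samples and reported as a fraction of the scanned span so stacks of
  different lengths aggregate sensibly.  A curve that never drops below
  the level on one side is clipped at the span and flagged.
* `d_smo`: total variation of the normalized curve; exactly 2 for any
  noiseless unimodal normalized curve, strictly larger under jitter.

Mean criteria are computed per stack, averaged over stacks, *then*
normalized — each criterion divided by its maximum within the operator
family — and combined as the Euclidean norm `D`.  Normalize-after-
averaging (rather than per stack) matches how the published tables are
described; per-family rather than global normalization is used because
every published family block carries 1.00 entries in (nearly) every
criterion column, which only per-family scaling produces.  Both scopes
are available (`normalize_distances(scope = "global")`).  Ranks are
ascending in `D` with lexicographic tie-breaking.  One caveat the
package documents rather than hides: in the bundled NIR-hyperspectral
reference table the frequency-family printed rank column contradicts
its own printed scores; ranking by ascending score is taken as the
definition.

## The synthetic generator

The generator's defaults are the package's study conditions; they are
fixed once and the tests run against them.

* **Scene** (`synthetic_scene`): 96×96, 12-bit, offset 300 counts,
  texture sd 200 counts.  The `soil_like` texture is a rank-8 sum of
  outer products of band-pass-filtered 1D profiles (granule scale 3–10
  px, weights `0.75^(q-1)`): granular like a sieved soil sample,
  spectrally broadband along both axes, and low-rank — the property the
  PCA reference requires of a pushbroom frame (see above).  `edges` is
  an 8 px bar target; `mixed` blends the two.
* **Optics** (`optics_spec`): λ = 0.55 µm, air, NA = 0.28, giving a
  depth of field `ΔZ = λ/(4n(1−√(1−(NA/n)²))) ≈ 3.44 µm` and a Nyquist
  scan step of `ΔZ/2 ≈ 1.72 µm`.  The printed form of the
  depth-of-field expression is ambiguous in its parenthesization; the
  axial-resolution form above is adopted as the physically standard
  reading.  Blur follows a Gaussian PSF with σ = 0.29 px per µm of
  defocus (0.5 px per scan step) — the true optical PSF of any given
  instrument is unknowable from first principles here, and only the
  monotone, symmetric growth of blur with defocus distance matters for
  ranking focus measures.
* **Detector**: Gaussian read noise, then rounding to integer counts
  and clamping to the sensor range.  Two presets: `hsi` (sd 20 counts,
  SNR ≈ 10 — a weak-signal NIR detector, the regime where the PCA
  reference is needed) and `video` (sd 2 counts, a well-exposed
  visible-range imager).  The Poisson robustness protocol runs on the
  `video` preset, because injected noise at rates 10–100 (sd 3.2–10
  counts) must dominate the baseline to produce a measurable trend —
  matching the protocol's use of visible-range stacks.
* **Robustness protocols**: `add_poisson_noise` adds an independent
  Poisson variate with mean `level` per pixel (the semantics of the
  cited usage; a signal-scaled shot-noise mode is available behind
  `mode = "scaled"`).  `apply_illumination_gradient` multiplies every
  frame by a quadratic ramp with maximum `peak` at one edge of the
  spatial axis falling to 0 at the other; the orientation is
  configurable since none is prescribed.
* **Accuracy under noise** is scored against the PCA reference of the
  clean parent stack: the ideal position is a property of the
  acquisition geometry, not of noise injected afterwards.

What the generator does *not* emulate: diffraction rings and
aberrations of a real PSF, slit/spectrograph smile and keystone,
stage positioning error, sample drift, and spectrally varying blur.
Passing tests therefore demonstrate the internal consistency of the
methodology and its behaviour under the modelled degradations — not
that any particular operator will win on a given real instrument.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (scene, render
noise, Poisson injection); generators save and restore the caller's RNG
state.  The test suite exercises 96×96 frames in 81-frame stacks (20
seeds for ground-truth recovery; 3 seeds × 4 noise levels for the
robustness trend) and 64×64 frames in shorter stacks for unit-level
checks — sizes chosen so the full PCA eigenproblem and all 22 operators
run comfortably on one core while preserving every qualitative regime
(deep PCA minimum, sub-step accuracy, monotone noise response).

## Known limitations

* The LOG measure is implemented verbatim from its printed definition,
  whose `E = Σ l·log(p_l)` term is not a normalized expectation; its
  absolute values are therefore scale-dependent across bit depths.
  Ranking is unaffected because curves are normalized per stack.
* The unimodality count and its prominence threshold are a package
  definition (documented above), not a published per-curve rule.
* ENVI support covers the uint16 BIL dialect the package writes;
  other interleaves or data types are rejected rather than guessed.
* The PCA reference assumes non-constant frames; fully saturated or
  dark frames are flagged and excluded from the argmin.
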