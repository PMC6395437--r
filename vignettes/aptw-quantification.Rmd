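---
title: "APT-weighted CEST quantification: models, methods and design choices"
author: "aptwcest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APT-weighted CEST quantification: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptwcest)
```

# The measurement

Amide proton transfer weighted (APTW) imaging is a chemical exchange
saturation transfer (CEST) technique: a long off-resonance RF pulse
saturates the backbone amide protons of mobile proteins and peptides,
which resonate about +3.5 ppm downfield of water, and chemical exchange
carries that saturation into the water pool, where it is detected as a
signal loss. Because amide exchange is base-catalyzed, the effect is
pH-sensitive: intracellular acidosis in an ischemic lesion slows the
exchange and lowers the APTW signal, which is why the quantity is used
to track stroke severity and treatment response.

The normalized water signal as a function of saturation offset is the
z-spectrum, $Z(\Delta\omega) = S_\mathrm{sat}/S_0$. The APTW signal is
the magnetization-transfer-ratio asymmetry at 3.5 ppm,

$$\mathrm{MTR_{asym}}(3.5\,\mathrm{ppm}) =
  \frac{S_\mathrm{sat}(-3.5\,\mathrm{ppm}) -
        S_\mathrm{sat}(+3.5\,\mathrm{ppm})}{S_0},$$

reported in percent of the bulk water signal. It decomposes as
$\mathrm{MTR_{asym}}(3.5) = \mathrm{APTR} + \mathrm{MTR}'_\mathrm{asym}(3.5)$,
the amide proton transfer ratio proper plus a residual asymmetry from
nuclear Overhauser enhancement (NOE) of upfield aliphatic protons and
the intrinsic asymmetry of the semisolid magnetization-transfer (MT)
pool. The residual term is negative in tissue, which is why healthy
white matter shows a small APTW value and acidotic lesions go clearly
negative. The simulator reports this decomposition exactly by
construction: `groundTruthDecomposition()` simulates the full pool set
and the same set with the amide pool removed, and defines APTR as the
difference, so `aptw = aptr + mtr_prime_asym` holds to machine
precision.

# The acquisition model

The simulated protocol matches the clinical acquisition the pipeline is
designed for: a 2D single-slice series with continuous-wave saturation
of 800 ms at 2 μT and 31 offsets expanding to 61 frames — 0, ±0.25,
±0.5, ±0.75, ±1 (2), ±1.5 (2), ±2 (2), ±2.5 (2), ±3 (2), ±3.25 (2),
±3.5 (8), ±3.75 (2), ±4 (2), ±4.5, ±5, ±6 ppm, acquisition counts in
parentheses — plus one unsaturated image for normalization
(`defaultOffsetTable()`). Repeats are stored as separate frames and
averaged by the pipeline after registration; since normalization is
linear, averaging before or after dividing by $S_0$ is immaterial in
the noise-free limit, and per-frame storage is what registration needs.

The saturation is called pseudo-continuous on clinical hardware; the
duty-cycle details are not modeled and true CW is assumed. The readout
is modeled as an ideal snapshot: any turbo-spin-echo weighting
multiplies all offsets equally and cancels in $S_\mathrm{sat}/S_0$.

# The Bloch–McConnell simulator

`simulateZSpectrum()` solves the coupled Bloch–McConnell equations for
an arbitrary set of exchanging pools. Under CW irradiation the system
is linear and time-invariant, so the default propagator is a single
matrix exponential of the $(3n{+}1)$-dimensional coefficient matrix
over the full saturation time — exact up to the matrix-exponential
algorithm — with a stiff-ODE time-stepping mode (`method = "timestep"`,
via deSolve) retained for cross-validation. The two agree to better
than $10^{-6}$ on two- and four-pool problems, and both agree with an
independently written right-hand side integrated in the test suite.

The default tissue model has four pools with literature-typical
white-matter-like values at 3 T, all configurable and none fitted to
any particular dataset: water (T1 1.2 s, T2 70 ms), a semisolid MT pool
at −2.3 ppm (fraction 0.10, T2 10 μs, k 25 s⁻¹; the Bloch treatment
gives it a Lorentzian lineshape — a super-Lorentzian is a known
refinement that is deliberately out of scope), an amide pool at
+3.5 ppm (fraction 0.0015, T2 30 ms), and an aliphatic NOE pool at
−3.5 ppm (fraction 0.005, T2 1 ms, k 20 s⁻¹). Exchange is a star
topology with water, reverse rates fixed by detailed balance.

pH enters through the amide exchange rate with the base-catalyzed law
$k(\mathrm{pH}) = k_\mathrm{ref}\,10^{\mathrm{pH}-\mathrm{pH_{ref}}}$,
defaulting to $k_\mathrm{ref} = 5.57\,\mathrm{s^{-1}}$ at pH 6.4 —
literature-typical values, not estimated from any cohort. Tissue
defaults are pH 7.0 for background and 6.4 for an acute lesion, chosen
so the lesion-minus-background APTW difference is negative at baseline,
matching the sign of pre-treatment lesion contrast in stroke.

At 2 μT the APTW response rises monotonically with the amide exchange
rate up to a saturation-efficiency peak near $k \approx 520$ s⁻¹.
`calibrateAmideExchange()` inverts this rising branch by root finding,
which is how a phantom is given an exact ground-truth APTW value. The
achievable range runs from the asymmetry floor (amide exchange off;
−2.0 % with the default pools) up to the peak (+8.1 %). When embedding
whole cohorts drawn from a normal distribution with SD ≈ 0.9 % around
−1 %, the −2 % floor would truncate the lower tail, so cohort-embedding
simulations raise the NOE fraction to 0.012, deepening the floor to
−4.5 %; this is a property of the configurable pool template, set once
and used for all cohort embeddings.

# The phantom

`buildPhantom()` renders a circular lesion in a uniform background on a
64×64 grid by default. Per-voxel spectra follow the voxel's tissue
class; a voxel with B0 shift $\delta$ has its apparent spectrum
displaced, implemented by sampling the class spectrum at
$(\mathrm{offset} - \delta)$ from a dense (0.02 ppm) simulated grid.
The B0 field is a smooth second-order 2D polynomial scaled to a peak
amplitude (default ±0.3 ppm). Noise is Rician by default (magnitude
MRI), with a Gaussian mode for linear-regime checks, applied
independently per acquisition. Optional per-frame rigid jitter emulates
patient motion.

Two phantom features deserve comment because they exist for the
pipeline's sake:

* **Anatomy texture.** $S_\mathrm{sat}$ and $S_0$ share a smooth
  multiplicative intensity pattern (Gaussian lumps, amplitude 0.3).
  It cancels exactly in the normalized z-spectrum, but it is what gives
  the registration stage anatomical contrast to lock onto — a
  perfectly flat phantom is an adversarial input no intensity-based
  registration can handle, and real brains are not flat.
* **Ground truth.** The returned truth maps (APTW, APTR, B0) are
  computed from the class pool sets directly, never through the
  pipeline, so pipeline validation is a genuine two-route comparison.

What the phantom does **not** emulate: realistic anatomy and partial
volume at tissue boundaries, coil-profile inhomogeneity of the receive
chain, spatially varying B1, multi-slice geometry, and physiological
drift. Passing tests therefore demonstrate correctness of the
quantification chain under its stated assumptions, not clinical
performance on patient data.

# The processing pipeline

`processSeries()` chains the stages; each is exported separately.

**Registration.** Every frame is aligned to the first acquisition at
+3.5 ppm with a 3-degree-of-freedom rigid transform (`registerSeries()`).
The metric is the mean-squared difference of intensity-standardized,
Gaussian high-pass-filtered images (σ = 6 px), optimized by a coarse
grid search plus Nelder–Mead refinement with bilinear resampling and
edge-value fill, the metric evaluated on the interior to keep edge fill
out of the fit. The high-pass filter exists because B0-induced shading
varies smoothly across the image differently at every offset; without
it the optimizer absorbs that contrast difference into spurious
transforms. Three guard rails apply: frames within 1 ppm of water are
never fitted directly (direct saturation destroys their contrast) and
inherit the nearest-in-offset successful transform; fits that fail to
improve the metric or land outside twice the expected motion range are
rejected the same way; and sub-0.15 px/deg estimates snap to the exact
identity so motion-free data are not needlessly resampled. The S0
image is registered with its own transform. Residual contrast-driven
bias on small synthetic images is below ~0.3 px / 1.5°; known-transform
recovery on smooth images is accurate to ~0.01 px.

**B0 correction.** For each voxel the z-spectrum within ±1 ppm of water
(9 samples) is interpolated with a cubic spline and the argmin taken as
the apparent water center. A single pass of this classic estimator is
accurate to only ~0.012 ppm against a known shift — and the APTW value
responds to residual shift at ~21 pp/ppm, so that error alone would be
~0.25 pp. `estimateB0()` therefore refines in two ways. First, the
argmin is iterated (default two passes): the spectrum is re-centred on
the current estimate by cubic re-interpolation and the residual argmin
accumulated, reaching ~0.004 ppm worst-case. Second, a
symmetric-matching step re-estimates the center as the point about
which the spline-interpolated window spectrum is most mirror-symmetric,
probed at ±0.05–0.6 ppm on the steep dip walls. This exploits the fact
that direct water saturation — which dominates the window — is
symmetric about the true water frequency, whereas the dip bottom, where
the argmin lives, is so flat that even the ~10⁻⁵ background asymmetry
from the upfield pools displaces the minimum. The refined estimator is
accurate to better than 0.001 ppm on the protocol's sampling (~0.02 pp
of APTW). The search grid is 5e-4 ppm (hierarchical coarse-to-fine
argmin, so cost is unaffected); `grid = 0.01, passes = 1,
symmetric = FALSE` reproduces the plain single-pass estimator.
Voxels whose window minimum is not interior are flagged invalid and
propagate as `NA` — never silently zeroed — and are excluded from maps
and ROI statistics. Correction re-interpolates each voxel's spectrum
onto the nominal offsets after subtracting its shift, clamping queries
past the sampled ends.

**Quantification.** `mtrAsym()` implements the asymmetry definition
exactly, requiring both ±offset to be sampled (no silent
interpolation); `computeAPTWMap()` reports percent of bulk water
signal; `mtrAsymSpectrum()` gives ROI mean ± SE per positive offset,
the layout used for group MTR-asymmetry spectra.

**ROI rules.** Several small lesion ROIs (conventionally 100–125 px;
the bound is advisory and violations warn rather than error) are
reduced by the lowest-mean rule — the lowest APTW plausibly marks the
most acidic part of the lesion — with ties broken to the lowest index.
The contralateral reference (CNAWM) is an explicit mask or, by
default, the selected lesion ROI mirrored across the vertical image
midline; the mirror axis is a parameter because a fixture cannot know
the anatomical midline. APTW contrast is lesion minus CNAWM, an exact
identity in `measureLesion()`. The deterministic square-tiling ROI
generator (`autoLesionROIs()`) replaces manual placement in synthetic
work; lesions too small for a conventional ROI fall back to a single
whole-lesion ROI.

# The cohort layer

Scans are binned by the clinical convention ≤96 h, 4–7 d, 8–21 d,
≥22 d, with edges [0, 96), [96, 168], (168, 504], (504, ∞) hours so a
recorded "4 days" falls in the second bin — the edge resolution that
reproduces the reference cohort's printed pre-treatment onset-bin sizes
(30 and 13), which the test suite recomputes from the bundled
per-patient table. The same edge rule serves onset and post-treatment
times.

The statistics are deliberately plain: Pearson correlation with the t
transform; one-way ANOVA followed by the least-significant-difference
post-hoc test — per-pair pooled-MSE t-tests with **no** multiplicity
adjustment, which is the definition of LSD and is intentionally
uncorrected; and the pooled-variance independent-samples t-test (a
Welch variant sits behind `var_equal = FALSE`). Degenerate inputs are
defined rather than accidental: identical samples give t = 0, p = 1;
zero variance with unequal means is an error; groups with n < 2 are
reported but excluded from models. `buildCohortTables()` assembles the
by-post-treatment-bin and by-onset-bin summary tables and the
time-correlation report, excluding post-treatment scans of patients
flagged treatment-ineffective, as the clinical analysis does.

`simulateCohort()` draws ground-truth lesion and CNAWM APTW from
normal distributions and couples NIHSS to lesion APTW through a
bivariate-normal linkage that attains a target correlation in
expectation. The stored integer NIHSS is rounded and clamped to
[0, 42], which attenuates the realized correlation by about 0.01–0.015
at the default parameters; the continuous score is kept in `nihss_raw`
for exact-linkage checks. The NIHSS severity bands overlap in common
clinical shorthand; where labels are needed they are resolved as
[0,1], [2,4], [5,15], [16,20], [21,42], and they are never used in
computation.

# Problem sizes and numerical choices

Phantoms are 64×64 with the 61-frame protocol (unit tests use 16–48 px
variants); embedding studies use 20 cohorts of 43 subjects; correlation
studies 100–200 replicate cohorts. These sizes were chosen so every
simulation remains comfortably reproducible on a single CPU while
keeping Monte-Carlo error well under the decision thresholds (for 200
cohorts of 43, the SE of the mean sample correlation is ≈ 0.008).

Other numerical conventions: offsets in ppm with positive downfield of
water; pixel indexing is R's 1-based row/column with the midline at
$(n_\mathrm{col}+1)/2$; APTW maps are percent of $S_0$; matrix
exponentials use the Padé scaling-and-squaring of the Matrix package;
ties in argmins and minima break deterministically to the first/lowest
index; all phantom randomness (field coefficients, texture, noise,
motion) derives from the single integer seed in the spec, so identical
specs are bit-reproducible.

# Known limitations

* MTR-asymmetry at 3.5 ppm is a weighted, contaminated measure — NOE
  and MT asymmetry sit inside it. The decomposition is available in
  simulation truth, but the pipeline quantifies what the clinical
  method quantifies. Lorentzian multi-pool fitting and extrapolated
  semisolid-MT reference methods are explicitly out of scope.
* The Lorentzian MT lineshape slightly misstates the far-from-water MT
  background compared with a super-Lorentzian; none of the package's
  conclusions depend on that tail.
* Registration is same-modality 2D rigid only, and on structure-poor
  frames it is best-effort by design.
* The B0 estimator assumes the water dip minimum marks the voxel
  frequency; very large shifts (beyond ±1 ppm) or spectra without an
  interior minimum are flagged invalid rather than extrapolated.
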