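---
title: "Methods: quantitative DWI validation with dwiqa"
author: "dwiqa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative DWI validation with dwiqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiqa)
```

# Scope

`dwiqa` implements the quantitative analyses used to validate
diffusion-weighted EPI on low-field MR-guided radiotherapy systems
against conventional high-field scanners: apparent diffusion coefficient
(ADC) mapping with a background noise-floor correction and b-value
subsetting, grid-phantom geometric distortion quantification, a
reversed phase-encode off-resonance estimator with EPI unwarping,
off-resonance field metrics, and volume-of-interest (VOI) statistics.
Because no public scanner data accompany these analyses, the package
ships a first-class synthetic-data module that generates every input the
pipeline consumes — a calibrated vial phantom, a 3D grid phantom and a
brain-like scene — with the statistical structure the analysis assumes.
All results quoted below are computed by the package's own test suite
and acceptance script; nothing is transcribed from external data.

# Signal model and ADC estimation

## Model

Voxelwise signal follows the intravoxel-incoherent-motion (IVIM)
bi-exponential

$$S(b) = S_0\left[f\,e^{-b D^* 10^{-6}} + (1-f)\,e^{-b D\,10^{-6}}\right],$$

with $b$ in s/mm², diffusion coefficients in µm²/s (the factor $10^{-6}$
converts µm² to mm², making the exponent dimensionless), perfusion
fraction $f \in [0,1)$ and pseudo-diffusion $D^* \ge D$. Setting $f = 0$
recovers the mono-exponential ADC model $S_0 e^{-b\,\mathrm{ADC}\cdot
10^{-6}}$ that the estimator fits.

## Noise floor and its correction

Magnitude MRI noise is Rician: with per-channel noise $\sigma$, a
signal-free voxel follows a Rayleigh law with mean
$\sigma\sqrt{\pi/2}$ and second moment $2\sigma^2$. At low SNR the floor
biases measured magnitudes upward and hence ADC downward.
`estimateBackgroundNoise()` measures the second moment
$\hat\eta^2 = \overline{S^2}$ over a user-chosen background cuboid
(pooled over all volumes); `correctNoiseFloor()` applies the power
subtraction $S' = \sqrt{\max(S^2 - \hat\eta^2, 0)}$. Since
$E[S^2] = \nu^2 + 2\sigma^2$ for true signal $\nu$, $S'^2$ is an
unbiased estimate of $\nu^2$. Voxel samples with $S^2 \le \hat\eta^2$
are flagged and *dropped* from that voxel's regression rather than
clamped, because a clamped zero would otherwise dominate the log-domain
fit.

## Fit

`fitADC()` is an unweighted ordinary-least-squares fit of $\ln S'$ on
$b$ over the selected b-values (slope $= -\mathrm{ADC}\times 10^{-6}$,
intercept $= \ln S_0$). The estimator is closed-form, exactly testable
(noise-free data is recovered to $10^{-9}$ relative), and matches common
scanner-side practice. Replicate acquisitions at the same b-value — the
two phase-encode polarities — are averaged *after* noise-floor
correction and *before* the logarithm, which halves the variance
entering the log-domain bias. Voxels with fewer than two usable points,
or with no spread in $b$ among them, are marked invalid and excluded
from VOI statistics. A weighted or nonlinear (Rician likelihood) fit is
a possible extension; it was not adopted because the closed form keeps
every oracle test exact.

Two standard variants are exposed: the all-b fit (five b-values
0–800 s/mm² in the default low-field protocol) and the two-point
$b=\{0,800\}$ fit; a two-point $b=\{0,1000\}$ protocol mirrors
high-field practice.

### When the correction helps — and when it does not

The correction targets the regime where the high-b signal approaches
the floor ($bD$ large, e.g. CSF-like $D \approx 3000$ µm²/s at
$b = 800$ with baseline SNR 20), where it reduces the magnitude of the
mean ADC bias several-fold; the test suite pins this regime. For
mid-range diffusivities at moderate SNR the *uncorrected* log-fit can
happen to profit from a partial cancellation between the floor-induced
downward bias and the log-concavity (Jensen) upward bias, so the
corrected estimator is not uniformly closer to truth — a property of
any power-subtraction + log-OLS pipeline worth knowing when choosing
protocols.

## Temperature correction and VOI statistics

Calibrated vial ADCs are specified at a reference temperature;
`temperatureCorrectReference()` interpolates a user-supplied
calibration table linearly between bracketing temperatures (tables are
vendor-specific, so the package does not hard-code one). VOI statistics
(`voiSummary()`) report mean, median, sample SD ($n-1$; the convention
is documented because either choice is defensible) and the
nonparametric skew $(\text{mean}-\text{median})/\text{SD}$, a bounded
($|\cdot|\le 1$) asymmetry measure, defined as 0 for degenerate
(zero-SD) samples. Agreement between estimates is expressed as the
relative difference $(\mathrm{ADC}_1-\mathrm{ADC}_2)/\mathrm{ADC}_{ref}$,
and per-subject method comparisons use the two-tailed paired Wilcoxon
signed-rank test (`pairedWilcoxon()`): zero differences dropped, exact
null distribution for $n \le 25$ without ties, tie-corrected normal
approximation otherwise, and no multiplicity correction (flags at
$p<0.05$ are descriptive).

# Geometric distortion quantification

The grid phantom is a cubic lattice of orthogonal beams (6 mm thick,
25 mm apart, 10×10×10 cm³ ⇒ 5 lines per axis, 125 intersection
markers). Markers are detected by normalized cross-correlation (NCC)
against a cross-shaped template matching the beam geometry
(`makeCrossTemplate()`, `detectMarkers()`): the NCC map is computed
once per image (FFT numerator, exact windowed sums for the local mean
and variance), each expected marker is searched within half a grid
spacing of its theoretical position, and the peak is refined to
subvoxel precision by separable quadratic interpolation of the
three-point peak neighbourhood. Peaks below an NCC of 0.5 (a
configurable threshold; no canonical value exists) are reported
*missing* and excluded — but counted — downstream.

Both the grid and the template are rasterized with exact per-axis
partial-volume coverage rather than binary centre-in-voxel tests;
binary rasterization leaves a quantization bias of a quarter voxel that
would dominate the sub-0.1 mm accuracy budget at CT-like resolution.

Distortion is the per-marker Euclidean distance to the theoretical
position *after* removing global rigid motion: a rotation+translation
fitted by the SVD-based orthogonal Procrustes construction (reflection
corrected, scaling deliberately disabled) on the central 3×3×3 block of
27 markers only (`rigidProcrustes()`, `markerDistortion()`). Central
markers are chosen because distortion grows with distance from
isocentre, so the centre anchors the reference frame with minimal
contamination. On an even lattice no canonical central block exists and
an explicit selection is required. Scenario summaries
(`scenarioSummary()`) average the per-acquisition mean distortions and,
separately, the per-acquisition maxima. The same pipeline applied to a
high-resolution (CT-like) image (`gridManufacturingQC()`) quantifies
how accurately the physical grid realizes its lattice.

# Reversed-PE field estimation and unwarping

Off-resonance $\Delta f$ (Hz) displaces EPI signal along the
phase-encode (PE) axis by $d = \Delta f / \mathrm{bw}_{PE}$ pixels,
with opposite sign for the two PE polarities. `applyEpiWarp()`
implements the forward model as exact mass transport: pixel *edges*
are moved by the displacement field and the cumulative intensity
profile is resampled at the original edges, so PE line integrals are
conserved by construction (a constant field is exactly a rigid shift)
and the Jacobian intensity modulation is implicit. The warp refuses
fold-over (displacement gradients $\le -1$ px/px).

`estimateFieldReversedPE()` inverts this model from a reversed-PE pair
by cumulative-profile (CDF) matching per PE line: after normalizing
both lines to equal total intensity, common mass levels locate pairs
$(y_{up}, y_{down})$; the midpoint is the undistorted position and the
half-difference the displacement there. The field is interpolated to
pixel centres and smoothed across lines with a Gaussian kernel
(default 6 mm). This integral-matching estimator is a deliberately
simple stand-in for full spline-regularized field optimizers: it is
deterministic, testable against known fields (RMS error well below
0.1 px for smooth 2-px warps on synthetic objects), and antisymmetric
in its inputs; externally computed Hz field maps can be ingested
instead (`ingestFieldmapHz()`). Its known limitations: displacement is
only constrained where the object has intensity gradients along PE, it
assumes pure PE-axis displacement (no eddy currents or motion), and a
background-intensity threshold (10% of the maximum in the workflow
default) is needed on noisy data because the noise floor's spurious
mass perturbs the profiles. `unwarpPair()` resamples the up image by
$-d$, the down image by $+d$ and averages.

Field metrics convert Hz to ppm ($\times 10^6 / f_0$, with $f_0$ =
14.707 MHz at 0.35 T and 123.152 MHz at 3 T) and to millimetres
($/\mathrm{bw}_{PE} \times$ PE voxel size); `p95AbsInMask()` reports
the 95th percentile of the absolute value within the brain mask
(linear-interpolation quantile; the convention is documented since
none is canonical) as a robust measure of high, locally occurring
values. Printed per-pixel bandwidths are treated as the PE-direction
values; the protocol object keeps the field explicit so users with
readout-direction figures can convert.

# The synthetic module: what it emulates, and what not

All generators are seeded and bit-reproducible; every workflow's
randomness flows from one master seed via fixed sub-seed derivation.

* **Vial phantom** (`makeVialPhantom()`): four cylindrical vials with
  true ADCs 400/1000/1600/2020 µm²/s (the calibrated values at 20 °C)
  in a 3×3×6 mm acquisition, evaluated in cylindrical VOIs of radius
  6 mm and height 39 mm (≈ 91 voxels per VOI). The default study
  (`simulateVialPhantomStudy()`) uses $b=\{0,200,400,600,800\}$ s/mm²,
  baseline SNR 40, both PE polarities under a gentle (≤ 300 Hz,
  ≈ 0.2 px) smooth field — large vials with interior VOIs make the
  ADC statistics insensitive to the residual edge warp.
* **Grid phantom** (`makeGridPhantom()`): the full 125-marker lattice.
  The distortion study (`simulateGridStudy()`) warps it with a radial
  smootherstep displacement profile that is flat over the central
  markers (so rigid referencing is uncontaminated) and attains its
  known maximum on a locally uniform patch at the lattice corners (so
  "maximum displacement" is well-defined against template
  deformation); default 2.5 mm voxels, SNR 40.
* **Brain scene** (`makeBrainScene()`): nested ellipsoids — CSF rim
  ($D=3000$), GM shell ($D=900$), WM core ($D=700$ µm²/s), literature-
  typical values — with an optional CSF IVIM compartment ($f=0.3$,
  $D^*=10^4$ µm²/s) and a susceptibility-like field (smoothed Gaussian
  random field plus a focal positive blob at the inferior brain,
  emulating the off-resonance above air cavities). Default baseline
  SNR 20 reflects low-field brain imaging — the regime in which the
  noise floor materially biases high-b CSF signal and in which
  including low b-values inflates the all-b ADC relative to the
  two-point fit, the direction observed in vivo.

Passing tests on these scenes demonstrate the *pipeline's* correctness
and the stated statistical behaviours; they do not certify scanner
performance. Real data add coil shading, eddy currents, subject
motion, partial-volume mixtures at tissue boundaries, non-Rician
multi-channel noise statistics, and perfusion/motion effects beyond
the two-compartment model — none of which are emulated.

# Numerical choices and degenerate inputs

* Voxel indices are 0-based in all external interfaces (CLI, JSON,
  TSV) and world coordinates come from the image affine; internally R
  arrays are 1-based and accessors hide the difference.
* Warp interpolation is linear in the cumulative profile (mass
  conserving); field-estimate inversion adds an infinitesimal ramp to
  the CDF so flat (zero-intensity) segments invert deterministically;
  all-zero lines yield zero displacement.
* Subvoxel NCC refinement clamps the quadratic offset to ±0.5 voxel
  and falls back to the integer peak for non-concave neighbourhoods or
  peaks at the search-volume boundary; zero-variance neighbourhoods
  make a marker missing.
* np-skew is 0 when the VOI standard deviation is 0; single-voxel VOIs
  are legal and degenerate-but-defined.
* With ~91 voxels per vial VOI, the np-skew estimator itself has a
  sampling standard deviation of ≈ 0.08 under zero true skew
  ($\approx 0.76/\sqrt{n}$), so per-seed values up to ≈ 0.2 occur even
  though the expected skew is near zero — a desk-scale sampling
  property of the prescribed VOI geometry, visible in the acceptance
  output across seeds.
* Problem sizes were chosen so the complete validation (unit suite
  plus acceptance) runs in well under two minutes: 32³-scale phantoms,
  a 57³ grid image at 2.5 mm, seven 40×40×18 brain subjects. All
  scale up by argument.

# Design decisions that were genuinely open

* **Noise statistic**: the *second moment* of the background (not the
  mean), because $E[S^2]=2\sigma^2$ under Rayleigh makes the power
  subtraction unbiased; a mean-based rule would need the
  $\sqrt{\pi/2}$ factor and would not linearize as cleanly.
* **Procrustes without scaling**: the reference is a manufactured
  grid; a scale factor would silently absorb real distortion.
* **Missing markers** are excluded from the mean/max and reported as
  counts, rather than imputed — imputation would understate distortion
  exactly where detection fails.
* **CDF matching** over re-implementing a regularized spline
  optimizer: the bridge to production field estimators is the Hz
  field-map ingestion path, not a re-implementation.
* The b-value sets are configurable; the five-point low-field protocol
  and the two-point schemes are defaults, not assumptions baked into
  the estimator.
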