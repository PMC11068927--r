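# dwiqa — quantitative QA for diffusion-weighted MRI

`dwiqa` is an R package for validating quantitative diffusion-weighted
EPI (DWI), built for the commissioning question that low-field
MR-guided radiotherapy systems pose: *are ADC values and image geometry
on a 0.35 T MR-Linac good enough to compare against a 3 T diagnostic
scanner?* It implements the complete analysis chain used in such
validations — on phantoms and brain-like volumes — and, because no
scanner data ship with it, a seeded synthetic-data module that
generates every input the pipeline needs, so the whole chain is
testable end to end.

Intended users: medical physicists and imaging scientists doing DWI
commissioning/QA, and methodologists who want a reference
implementation of the component algorithms.

## What it computes

**ADC mapping with noise-floor correction.** Voxelwise apparent
diffusion coefficient from the mono-exponential model
S(b) = S₀·exp(−b·ADC·10⁻⁶) (b in s/mm², ADC in µm²/s), fitted by OLS
on log-signal. Magnitude background noise is Rician; its floor is
estimated as the second moment η² of a signal-free cuboid (E[S²] = 2σ²
under Rayleigh) and removed by power subtraction
S′ = √max(S² − η², 0), with sub-floor samples dropped from the fit.
B-value subsetting (ADCall vs ADC₀,₈₀₀), replicate (reversed
phase-encode) averaging, temperature-corrected calibrated references,
and IVIM bi-exponential simulation
S = S₀[f·e^(−b·D*·10⁻⁶) + (1−f)·e^(−b·D·10⁻⁶)] are included.

**Grid-phantom distortion.** Marker detection on a 3D printed-grid
image by FFT-based normalized cross-correlation with a cross template
and subvoxel quadratic peak refinement; rigid (no-scale) Procrustes
registration on the central 27 markers; distortion = per-marker
Euclidean distance to the theoretical lattice; mean/max summaries and
scenario averaging; the same pipeline doubles as a CT-resolution
manufacturing-accuracy check.

**Reversed-PE unwarping.** Off-resonance Δf displaces EPI signal by
Δf/bw_PE pixels along the phase-encode axis, with opposite sign for
the two polarities. A mass-conserving warp (cumulative-profile
transport) simulates the distortion; a CDF-matching estimator recovers
the displacement field from a blip-up/blip-down pair and corrects the
images; externally computed Hz field maps can be ingested instead.

**Field metrics and statistics.** Hz → ppm (×10⁶/f₀) and Hz → mm
(/bw_PE × voxel) conversions, 95th-percentile-of-|·| summaries in a
brain mask, VOI statistics (mean, median, sample SD, nonparametric
skew (mean−median)/SD), relative differences, and exact paired
Wilcoxon signed-rank comparisons between ADC variants.

See `vignettes/dwiqa-methods.Rmd` for the full model descriptions,
parameter defaults and design rationale.

## Worked example

Simulate the calibrated four-vial phantom study (true ADCs
400/1000/1600/2020 µm²/s, b = 0…800 s/mm², SNR 40, both phase-encode
polarities) and run the ADC validation workflow:

```r
library(dwiqa)
sim <- simulateVialPhantomStudy(seed = 42)
report <- runPhantom1Workflow(sim$dwi, sim$voiMasks,
                              sim$noiseCuboid$start, sim$noiseCuboid$size,
                              referenceAdcs = sim$trueAdcs)
report$table[, c("vial","method","mean","median","sd","np_skew","n","rel_diff_mean")]
#>    vial   method mean median    sd np_skew  n rel_diff_mean
#> 1 vial1   ADCall  404    406  37.3 -0.0516 91       0.01100
#> 2 vial1 ADC0_800  406    409  40.6 -0.0875 91       0.01377
#> 3 vial2   ADCall 1007   1009  43.6 -0.0410 91       0.00724
#> 4 vial2 ADC0_800 1007   1000  51.7  0.1490 91       0.00722
#> 5 vial3   ADCall 1606   1608  67.3 -0.0274 91       0.00374
#> 6 vial3 ADC0_800 1604   1613  82.9 -0.1155 91       0.00243
#> 7 vial4   ADCall 2034   2025 110.7  0.0830 91       0.00696
#> 8 vial4 ADC0_800 2040   2015 129.2  0.1904 91       0.00987
```

Each row is one vial × one ADC variant: the VOI mean/median/SD of the
voxelwise ADC (µm²/s) over the 91-voxel evaluation cylinder, the
nonparametric skew of that distribution, and the relative deviation of
the VOI mean from the calibrated value — here ≤ 1.4% on every vial,
i.e. within the few-percent agreement a commissioning measurement
targets.

Distortion: warp the grid phantom with a smooth 2 mm field, quantify,
and correct from the reversed-PE pair:

```r
gsim <- simulateGridStudy(seed = 42, dMaxMm = 2)
wf <- runPhantom2Workflow(gsim$imgUp, gsim$imgDown, gsim$affine,
                          gsim$protocol, gsim$markers)
wf$table
#>       image metric distortion_mm n_detected n_reference
#> 1        up   mean        1.0141        125         125
#> 2        up    max        2.0875        125         125
#> 3      down   mean        1.0162        125         125
#> 4      down    max        2.1005        125         125
#> 5 corrected   mean        0.0252        125         125
#> 6 corrected    max        0.0735        125         125
```

The pipeline recovers the known 2 mm maximum displacement (2.09 mm
measured) and the reversed-PE correction removes ~98% of the mean
distortion.

A thin command-line front end over these functions is installed at
`inst/cli/dwiqa.R` (`simulate`, `adc`, `unwarp`, `fieldmetrics`,
`distortion-grid`).

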