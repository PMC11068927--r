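Package: dwiqa
Title: Quantitative Quality Assurance for Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis tools for quantitative quality
    assurance of echo-planar diffusion-weighted MRI (DWI) on low- and
    high-field scanners. Provides voxelwise apparent diffusion
    coefficient (ADC) mapping with Rician background noise-floor
    correction and b-value subsetting, grid-phantom geometric
    distortion quantification via normalized cross-correlation marker
    detection and rigid Procrustes referencing, a reversed
    phase-encode off-resonance field estimator with mass-conserving
    EPI unwarping, off-resonance field metrics (ppm and millimetre
    displacement), and volume-of-interest statistics including the
    nonparametric skew and paired Wilcoxon signed-rank comparisons.
    A synthetic-data module generates calibrated vial phantoms, 3D
    grid phantoms and brain-like scenes with mono- and bi-exponential
    (IVIM) signal decay, Rician noise and opposite-phase-encode EPI
    warps, so every pipeline stage can be exercised and validated
    end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
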