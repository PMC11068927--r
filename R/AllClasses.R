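#' @import methods
NULL

#' Acquisition protocol for a diffusion-weighted EPI series
#'
#' Bundles the acquisition parameters the analysis needs: the diffusion
#' b-values, the phase-encode (PE) axis and polarity, the per-pixel receiver
#' bandwidth along PE, the voxel size and the scanner resonance frequency.
#'
#' @slot bValues numeric, b-values in s/mm^2; non-negative, ascending,
#'   must contain 0 and have length >= 2.
#' @slot peAxis integer, phase-encode axis as an R array dimension (1, 2
#'   or 3). External JSON/CLI representations use 0-based axes; the readers
#'   convert.
#' @slot peSign integer, +1 or -1, polarity of the PE traversal.
#' @slot bwPePx numeric, receiver bandwidth per pixel along PE in Hz/px
#'   (> 0). Off-resonance of \code{bwPePx} Hz displaces signal by one pixel.
#' @slot voxelSize numeric(3), voxel edge lengths in mm, all > 0.
#' @slot resonanceHz numeric, scanner resonance frequency in Hz (> 0),
#'   e.g. 14.707e6 at 0.35 T and 123.152e6 at 3 T.
#'
#' @seealso [acquisitionProtocol()], [mrLinacProtocol()], [threeTeslaProtocol()]
#' @export
setClass("AcquisitionProtocol",
  representation(
    bValues = "numeric",
    peAxis = "integer",
    peSign = "integer",
    bwPePx = "numeric",
    voxelSize = "numeric",
    resonanceHz = "numeric"
  )
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  b <- object@bValues
  if (length(b) < 2L) msg <- c(msg, "bValues must have length >= 2")
  if (any(b < 0)) msg <- c(msg, "bValues must be non-negative")
  if (!any(b == 0)) msg <- c(msg, "bValues must contain b = 0")
  if (is.unsorted(b)) msg <- c(msg, "bValues must be ascending")
  if (!(object@peAxis %in% 1:3)) msg <- c(msg, "peAxis must be 1, 2 or 3")
  if (!(object@peSign %in% c(-1L, 1L))) msg <- c(msg, "peSign must be +1 or -1")
  if (length(object@bwPePx) != 1L || object@bwPePx <= 0)
    msg <- c(msg, "bwPePx must be a single value > 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths (mm)")
  if (length(object@resonanceHz) != 1L || object@resonanceHz <= 0)
    msg <- c(msg, "resonanceHz must be a single value > 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic imaging scene: label map plus per-tissue signal parameters
#'
#' A `Scene` is the ground truth a simulated acquisition is generated from:
#' an integer label map (0 = background), a table of per-label signal
#' parameters for the (bi-)exponential diffusion model, and a voxel-to-world
#' affine. `tissueParams` columns: `label`, `S0` (baseline signal, a.u.),
#' `D` (diffusion coefficient, um^2/s), `f` (perfusion fraction in [0,1)),
#' `Dstar` (pseudo-diffusion coefficient, um^2/s; must be >= D when f > 0).
#'
#' @slot labelMap 3D integer array of tissue labels.
#' @slot tissueParams data.frame with one row per nonzero label.
#' @slot affine 4x4 voxel-to-world matrix (0-based voxel indices, mm).
#' @slot meta list of generator-specific extras (e.g. vial centres).
#' @export
setClass("Scene",
  representation(
    labelMap = "array",
    tissueParams = "data.frame",
    affine = "matrix",
    meta = "list"
  )
)

setValidity("Scene", function(object) {
  msg <- character()
  if (length(dim(object@labelMap)) != 3L) msg <- c(msg, "labelMap must be 3D")
  tp <- object@tissueParams
  need <- c("label", "S0", "D", "f", "Dstar")
  if (!all(need %in% names(tp)))
    msg <- c(msg, sprintf("tissueParams must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    labs <- sort(unique(as.vector(object@labelMap)))
    labs <- labs[labs != 0]
    if (!all(labs %in% tp$label))
      msg <- c(msg, "every nonzero label needs a tissueParams row")
    if (any(tp$D < 0)) msg <- c(msg, "D must be >= 0")
    if (any(tp$f < 0 | tp$f >= 1)) msg <- c(msg, "f must lie in [0, 1)")
    if (any(tp$f > 0 & tp$Dstar < tp$D))
      msg <- c(msg, "Dstar must be >= D wherever f > 0")
  }
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  if (length(msg)) msg else TRUE
})

#' Off-resonance field map in Hz
#'
#' @slot values 3D array of off-resonance values in Hz; finite everywhere.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("FieldMap",
  representation(values = "array", affine = "matrix")
)

setValidity("FieldMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be 3D")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (!all(dim(object@affine) == c(4L, 4L))) msg <- c(msg, "affine must be 4x4")
  if (length(msg)) msg else TRUE
})

#' Signed displacement field along the phase-encode axis, in pixels
#'
#' Holds the voxelwise displacement (in pixels, for the `peSign = +1`
#' acquisition) that an off-resonance field induces along the PE axis;
#' related to a [FieldMap] in Hz by `values = field / bwPePx`.
#'
#' @slot values 3D array, displacement in pixels (finite).
#' @slot peAxis integer, the PE axis (1, 2 or 3).
#' @export
setClass("DisplacementField1D",
  representation(values = "array", peAxis = "integer")
)

setValidity("DisplacementField1D", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be 3D")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (!(object@peAxis %in% 1:3)) msg <- c(msg, "peAxis must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' Four-dimensional diffusion-weighted series
#'
#' A stack of 3D magnitude volumes, one per diffusion weighting (repeated
#' b-values are allowed, e.g. the two phase-encode polarities of the same
#' weighting), together with the per-volume b-values and the acquisition
#' protocol.
#'
#' @slot data 4D numeric array (x, y, z, volume).
#' @slot bValues numeric, one b-value (s/mm^2) per volume.
#' @slot peSigns integer, one PE polarity (+1/-1) per volume.
#' @slot protocol an [AcquisitionProtocol-class].
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("DWISeries",
  representation(
    data = "array",
    bValues = "numeric",
    peSigns = "integer",
    protocol = "AcquisitionProtocol",
    affine = "matrix"
  )
)

setValidity("DWISeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be 4D")
  else {
    if (length(object@bValues) != d[4L])
      msg <- c(msg, "length(bValues) must equal the 4th data dimension")
    if (length(object@peSigns) != d[4L])
      msg <- c(msg, "length(peSigns) must equal the 4th data dimension")
  }
  if (!any(object@bValues == 0)) msg <- c(msg, "series must include b = 0")
  if (!all(dim(object@affine) == c(4L, 4L))) msg <- c(msg, "affine must be 4x4")
  if (length(msg)) msg else TRUE
})

#' Background noise estimate from a signal-free cuboid
#'
#' `etaSq` is the second moment of the background magnitude signal,
#' averaged over the cuboid and all volumes. Under a Rayleigh background
#' (pure noise in a magnitude image) `E[S^2] = 2*sigma^2`, so subtracting
#' `etaSq` from squared intensities removes the noise floor without bias at
#' high SNR.
#'
#' @slot etaSq numeric, mean squared background intensity (a.u.^2).
#' @slot nVoxels integer, voxels in the cuboid (per volume).
#' @slot cuboid list with `start` (0-based index triple) and `size`.
#' @export
setClass("NoiseEstimate",
  representation(etaSq = "numeric", nVoxels = "integer", cuboid = "list")
)

setValidity("NoiseEstimate", function(object) {
  msg <- character()
  if (object@etaSq < 0) msg <- c(msg, "etaSq must be >= 0")
  if (object@nVoxels < 1L) msg <- c(msg, "nVoxels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Voxelwise ADC map with fit diagnostics
#'
#' @slot adc 3D array, apparent diffusion coefficient in um^2/s.
#' @slot s0 3D array, fitted baseline signal (a.u.).
#' @slot nUsed 3D integer array, number of b-value points used per voxel.
#' @slot validMask 3D logical array; ADC is finite wherever TRUE and at
#'   least two usable points entered the fit.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot meta list: b-subset, noise floor `etaSq`, number of flagged points.
#' @export
setClass("ADCMap",
  representation(
    adc = "array", s0 = "array", nUsed = "array",
    validMask = "array", affine = "matrix", meta = "list"
  )
)

setValidity("ADCMap", function(object) {
  msg <- character()
  d <- dim(object@adc)
  same <- function(x) identical(dim(x), d)
  if (!same(object@s0) || !same(object@nUsed) || !same(object@validMask))
    msg <- c(msg, "adc, s0, nUsed and validMask must share dimensions")
  v <- object@validMask
  if (any(v) && !all(is.finite(object@adc[v])))
    msg <- c(msg, "adc must be finite wherever validMask is TRUE")
  if (any(v) && any(object@nUsed[v] < 2L))
    msg <- c(msg, "nUsed must be >= 2 wherever validMask is TRUE")
  if (length(msg)) msg else TRUE
})

#' Labelled 3D marker set
#'
#' Marker positions of a grid phantom, either theoretical (reference) or
#' detected. Detected sets carry a normalized cross-correlation score per
#' marker and a missing flag for markers whose correlation peak fell below
#' the detection threshold.
#'
#' @slot ids character, unique marker labels.
#' @slot gridIndex integer matrix (n x 3), lattice indices (0-based).
#' @slot posMm numeric matrix (n x 3), world coordinates in mm (may be NA
#'   for missing detected markers).
#' @slot score numeric, NCC peak value in [-1, 1]; NA for reference sets.
#' @slot missing logical, TRUE where detection failed.
#' @export
setClass("MarkerSet",
  representation(
    ids = "character", gridIndex = "matrix", posMm = "matrix",
    score = "numeric", missing = "logical"
  )
)

setValidity("MarkerSet", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (!all(dim(object@gridIndex) == c(n, 3L)))
    msg <- c(msg, "gridIndex must be n x 3")
  if (!all(dim(object@posMm) == c(n, 3L))) msg <- c(msg, "posMm must be n x 3")
  if (length(object@score) != n) msg <- c(msg, "score must have length n")
  if (length(object@missing) != n) msg <- c(msg, "missing must have length n")
  ok <- !object@missing
  if (any(ok) && !all(is.finite(object@posMm[ok, , drop = FALSE])))
    msg <- c(msg, "posMm must be finite for non-missing markers")
  if (length(msg)) msg else TRUE
})

#' Rigid (rotation + translation) spatial transform
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("RigidTransform", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be orthonormal (R'R = I within 1e-8)")
    if (abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rotation must have determinant +1 within 1e-8")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' Geometric distortion report for a marker set
#'
#' Per-marker Euclidean distances (mm) between detected markers, after
#' removing global rigid motion fitted on the central markers, and their
#' theoretical reference positions; with the mean and maximum over matched
#' (non-missing) markers.
#'
#' @slot perMarker data.frame: id, grid index, reference mm, detected
#'   (rigid-aligned) mm, distance mm, detection score.
#' @slot meanMm,maxMm numeric summary distances (mm).
#' @slot nDetected,nReference integer marker counts.
#' @slot transform the fitted [RigidTransform-class].
#' @export
setClass("DistortionReport",
  representation(
    perMarker = "data.frame", meanMm = "numeric", maxMm = "numeric",
    nDetected = "integer", nReference = "integer",
    transform = "RigidTransform"
  )
)

setValidity("DistortionReport", function(object) {
  msg <- character()
  if (object@meanMm < 0 || object@maxMm < object@meanMm)
    msg <- c(msg, "must satisfy 0 <= meanMm <= maxMm")
  if (nrow(object@perMarker) != object@nDetected)
    msg <- c(msg, "perMarker rows must equal nDetected")
  if (length(msg)) msg else TRUE
})

#' Volume-of-interest summary statistics of an ADC map
#'
#' Mean, median, sample standard deviation (n - 1 denominator) and
#' nonparametric skew `(mean - median) / sd` of the voxelwise ADC values in
#' a mask, restricted to voxels with a valid fit.
#'
#' @slot mean,median,sd numeric, um^2/s.
#' @slot npSkew numeric, dimensionless; defined as 0 when sd = 0.
#' @slot n integer, number of voxels summarised.
#' @export
setClass("VOISummary",
  representation(
    mean = "numeric", median = "numeric", sd = "numeric",
    npSkew = "numeric", n = "integer"
  )
)

setValidity("VOISummary", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
  if (object@sd > 0 && !is.finite(object@npSkew))
    msg <- c(msg, "npSkew must be finite when sd > 0")
  if (length(msg)) msg else TRUE
})
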