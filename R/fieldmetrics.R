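# Off-resonance field metrics: conversion to ppm and to millimetre
# displacement along the phase-encode direction, and masked percentile
# summaries.

#' Convert an off-resonance field from Hz to ppm
#'
#' `ppm = field_hz / resonance_hz * 1e6`. Parts-per-million off-resonance
#' is independent of field strength, making inhomogeneity comparable
#' between scanners (resonance 14.707 MHz at 0.35 T vs 123.152 MHz at 3 T).
#'
#' @param fieldHz numeric array or [FieldMap-class], Hz.
#' @param resonanceHz scanner resonance frequency, Hz (> 0); an
#'   [AcquisitionProtocol-class] may be given instead.
#' @return array of ppm values (same shape).
#' @export
fieldToPpm <- function(fieldHz, resonanceHz) {
  if (is(resonanceHz, "AcquisitionProtocol"))
    resonanceHz <- resonanceHz@resonanceHz
  if (resonanceHz <= 0) stop("resonanceHz must be > 0")
  hz <- if (is(fieldHz, "FieldMap")) fieldValues(fieldHz) else fieldHz
  hz / resonanceHz * 1e6
}

#' Convert an off-resonance field from Hz to mm displacement along PE
#'
#' `d_mm = field_hz / bw_pe_px * voxel_mm_pe`: off-resonance of one
#' per-pixel bandwidth displaces signal by one pixel along the
#' phase-encode direction.
#'
#' @param fieldHz numeric array or [FieldMap-class], Hz.
#' @param bwPePx per-pixel PE bandwidth, Hz/px (> 0).
#' @param voxelMmPe voxel size along the PE axis, mm (> 0). Alternatively
#'   pass an [AcquisitionProtocol-class] as `bwPePx` and omit `voxelMmPe`.
#' @return array of displacements in mm (same shape, signed).
#' @export
fieldToDisplacementMm <- function(fieldHz, bwPePx, voxelMmPe = NULL) {
  if (is(bwPePx, "AcquisitionProtocol")) {
    p <- bwPePx
    voxelMmPe <- voxelSize(p)[peAxis(p)]
    bwPePx <- p@bwPePx
  }
  if (bwPePx <= 0) stop("bwPePx must be > 0")
  if (is.null(voxelMmPe) || voxelMmPe <= 0) stop("voxelMmPe must be > 0")
  hz <- if (is(fieldHz, "FieldMap")) fieldValues(fieldHz) else fieldHz
  hz / bwPePx * voxelMmPe
}

#' 95th percentile of the absolute value within a mask
#'
#' Reported as a measure of high, locally occurring off-resonance or
#' displacement values: the 95th percentile (linear interpolation between
#' order statistics) of `|map|` over the mask voxels. Robust to isolated
#' extreme outliers, unlike the maximum.
#'
#' @param map numeric array (or [FieldMap-class]).
#' @param mask logical array of the same shape; must select at least one
#'   voxel.
#' @param prob percentile level (default 0.95).
#' @return single numeric value.
#' @export
p95AbsInMask <- function(map, mask, prob = 0.95) {
  vals <- if (is(map, "FieldMap")) fieldValues(map) else map
  stopifnot(identical(dim(vals), dim(mask)))
  v <- abs(vals[mask])
  if (length(v) == 0L) stop("mask selects no voxels")
  unname(stats::quantile(v, prob, type = 7, names = FALSE))
}
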