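# Reversed phase-encode off-resonance estimation and EPI unwarping: a
# simplified integral-matching estimator standing in for a full spline
# regularized field optimizer, plus ingestion of externally computed Hz
# field maps.

#' Estimate the PE displacement field from a reversed phase-encode pair
#'
#' The two images are the same object acquired with opposite PE polarity:
#' material at (undistorted) position u appears at `u + d(u)` in the "up"
#' image and at `u - d(u)` in the "down" image. Per PE line, both
#' cumulative-intensity profiles are matched at common mass levels
#' (monotone CDF inversion after normalizing the lines to equal total
#' intensity): each level locates a pair `(y_up, y_down)` whose midpoint
#' is the undistorted position and whose half-difference is the
#' displacement there. The resulting field is interpolated to pixel
#' centres and smoothed with a Gaussian kernel across lines.
#'
#' @param imgUp,imgDown 3D arrays on the same grid (up = `peSign = +1`).
#' @param protocol an [AcquisitionProtocol-class].
#' @param smoothMm across-line Gaussian smoothing sigma, mm.
#' @param backgroundThreshold intensities below this fraction of the image
#'   maximum are zeroed before matching (suppresses the noise floor's
#'   spurious mass); 0 disables.
#' @return a [DisplacementField1D-class] (pixels, for the up acquisition).
#'   All-zero lines get zero displacement.
#' @export
estimateFieldReversedPE <- function(imgUp, imgDown, protocol, smoothMm = 6,
                                    backgroundThreshold = 0) {
  if (!identical(dim(imgUp), dim(imgDown)))
    stop("images must share a grid")
  d <- dim(imgUp)
  ax <- peAxis(protocol)
  if (backgroundThreshold > 0) {
    thr <- backgroundThreshold * max(imgUp, imgDown)
    imgUp <- ifelse(imgUp < thr, 0, imgUp)
    imgDown <- ifelse(imgDown < thr, 0, imgDown)
  }
  perm <- c(ax, setdiff(1:3, ax))
  U <- matrix(aperm(imgUp, perm), nrow = d[ax])
  D <- matrix(aperm(imgDown, perm), nrow = d[ax])
  n <- nrow(U)
  centers <- 0:(n - 1L)
  edges <- (0:n) - 0.5
  ramp <- (0:n) * 1e-9
  levels_ <- (seq_len(2L * n) - 0.5) / (2L * n)
  out <- matrix(0, n, ncol(U))
  eps <- 1e-12 * max(imgUp, imgDown, 1)
  for (j in seq_len(ncol(U))) {
    tu <- sum(U[, j]); td <- sum(D[, j])
    if (tu <= eps || td <= eps) next
    Cu <- c(0, cumsum(U[, j])) / tu + ramp
    Cd <- c(0, cumsum(D[, j])) / td + ramp
    yU <- stats::approx(Cu, edges, xout = levels_, rule = 2, ties = "ordered")$y
    yD <- stats::approx(Cd, edges, xout = levels_, rule = 2, ties = "ordered")$y
    u <- (yU + yD) / 2
    disp <- (yU - yD) / 2
    # u is monotone; collapse duplicates before interpolating to centres
    out[, j] <- stats::approx(u, disp, xout = centers, rule = 2,
                              ties = "mean")$y
  }
  field <- aperm(array(out, d[perm]), order(perm))
  voxPe <- voxelSize(protocol)
  sigmaVox <- smoothMm / voxPe
  sigmaVox[ax] <- 0   # smooth across lines only
  field <- gaussSmooth3D(field, sigmaVox)
  new("DisplacementField1D", values = field, peAxis = as.integer(ax))
}

#' Distortion-correct a reversed phase-encode pair
#'
#' Resamples the up image by `-d` and the down image by `+d` with the
#' mass-conserving line resampler (see [applyEpiWarp()]) and averages the
#' two corrected images. With the true field this recovers the undistorted
#' object; with a zero field it reduces to the voxelwise mean of the
#' inputs.
#'
#' @param imgUp,imgDown 3D arrays on the same grid.
#' @param field a [DisplacementField1D-class] (pixels, up-acquisition
#'   convention), e.g. from [estimateFieldReversedPE()] or
#'   [ingestFieldmapHz()].
#' @return corrected 3D array.
#' @export
unwarpPair <- function(imgUp, imgDown, field) {
  stopifnot(is(field, "DisplacementField1D"))
  v <- fieldValues(field)
  if (!identical(dim(v), dim(imgUp)) || !identical(dim(imgUp), dim(imgDown)))
    stop("images and field must share a grid")
  ax <- peAxis(field)
  corrUp <- applyDisplacementVolume(imgUp, -v, ax)
  corrDown <- applyDisplacementVolume(imgDown, v, ax)
  (corrUp + corrDown) / 2
}

#' Ingest an externally computed off-resonance field map (Hz)
#'
#' Converts a Hz-valued field map (e.g. the output of an external reversed
#' phase-encode field estimator) to a pixel displacement field using the
#' protocol's per-pixel PE bandwidth: `d_px = Hz / bwPePx`.
#'
#' @param field path to a NIfTI file, a [FieldMap-class], or a 3D array
#'   of Hz values.
#' @param protocol an [AcquisitionProtocol-class].
#' @param referenceDim optional integer(3); when given, the field grid is
#'   checked against it.
#' @return a [DisplacementField1D-class].
#' @export
ingestFieldmapHz <- function(field, protocol, referenceDim = NULL) {
  hz <- if (is.character(field)) readVolumeNifti(field)$data
        else if (is(field, "FieldMap")) fieldValues(field)
        else field
  if (length(dim(hz)) != 3L) stop("field map must be 3D")
  if (!is.null(referenceDim) && !identical(dim(hz), as.integer(referenceDim)))
    stop("field map grid does not match the image grid")
  if (!all(is.finite(hz))) stop("field map contains non-finite values")
  new("DisplacementField1D", values = hz / bwPePx(protocol),
      peAxis = peAxis(protocol))
}
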