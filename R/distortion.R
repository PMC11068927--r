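# Grid-phantom geometric distortion: cross-template construction,
# FFT-based normalized cross-correlation marker detection with subvoxel
# refinement, rigid Procrustes referencing on the central markers, and
# per-scenario distortion summaries.

#' Cross-shaped template matching the grid-beam geometry
#'
#' Rasterizes the union of three orthogonal boxes (one per axis) of the
#' beam thickness, with arms of the given length, at the image resolution.
#' Used as the matched filter for beam-intersection (marker) detection.
#'
#' @param beamThicknessMm beam thickness, mm.
#' @param voxelSize numeric(3), mm.
#' @param armLengthMm half-length of each cross arm, mm; must exceed the
#'   beam thickness.
#' @return binary 3D array with odd dimensions; the cross centre is the
#'   centre voxel.
#' @export
makeCrossTemplate <- function(beamThicknessMm, voxelSize, armLengthMm = 9) {
  stopifnot(length(voxelSize) == 3L)
  if (armLengthMm <= beamThicknessMm)
    stop("armLengthMm must exceed the beam thickness")
  r <- floor(armLengthMm / voxelSize)
  dims <- as.integer(2L * r + 1L)
  ctr <- r * voxelSize
  coords <- lapply(1:3, function(ax) (0:(dims[ax] - 1L)) * voxelSize[ax] - ctr[ax])
  # partial-volume coverage, matching the grid rasterization
  onBeam <- lapply(1:3, function(ax)
    slabCoverage1D(coords[[ax]], voxelSize[ax], 0, beamThicknessMm))
  within <- lapply(1:3, function(ax)
    slabCoverage1D(coords[[ax]], voxelSize[ax], 0, 2 * armLengthMm))
  tpl <- array(0, dims)
  for (a in 1:3) {
    axCov <- lapply(1:3, function(ax) if (ax == a) within[[ax]] else onBeam[[ax]])
    beam <- outer(outer(axCov[[1L]], axCov[[2L]], "*"), axCov[[3L]], "*")
    tpl <- pmax(tpl, beam)
  }
  tpl
}

#' Normalized cross-correlation map of a template over an image
#'
#' Computes the full NCC map for all placements of `template` inside
#' `image` (FFT-based numerator, exact windowed sums for the local image
#' mean and variance). Placements whose local image variance is (near)
#' zero get an NCC of `NA`.
#'
#' @param image,template 3D numeric arrays; the template must fit inside
#'   the image.
#' @return list with `ncc` (array of dimension `dim(image) - dim(template)
#'   + 1`, indexed by the 0-based placement corner) and `centerOffset`
#'   (numeric(3): placement corner to template centre, voxels).
#' @export
matchTemplateNCC <- function(image, template) {
  dI <- dim(image); dT <- dim(template)
  stopifnot(length(dI) == 3L, length(dT) == 3L)
  if (any(dT > dI)) stop("template must be smaller than the image")
  nT <- prod(dT)
  tMean <- mean(template)
  t0 <- template - tMean
  tNorm <- sqrt(sum(t0^2))
  # raw cross-correlation via FFT, zero-padded to 2/3/5-smooth sizes so
  # prime image dimensions do not degrade the transform
  dP <- vapply(dI + dT - 1L, function(n) stats::nextn(n, c(2L, 3L, 5L)),
               integer(1))
  iPad <- array(0, dP)
  iPad[seq_len(dI[1L]), seq_len(dI[2L]), seq_len(dI[3L])] <- image
  tPad <- array(0, dP)
  tPad[seq_len(dT[1L]), seq_len(dT[2L]), seq_len(dT[3L])] <- t0
  cc <- Re(stats::fft(stats::fft(iPad) * Conj(stats::fft(tPad)),
                      inverse = TRUE)) / prod(dP)
  valid <- dI - dT + 1L
  cc <- cc[seq_len(valid[1L]), seq_len(valid[2L]), seq_len(valid[3L]),
           drop = FALSE]
  s1 <- boxSumValid(image, dT)
  s2 <- boxSumValid(image^2, dT)
  varLocal <- pmax(s2 - s1^2 / nT, 0)
  den <- tNorm * sqrt(varLocal)
  ncc <- cc / den
  ncc[den <= max(den, 1e-300) * 1e-8] <- NA_real_
  list(ncc = array(ncc, valid), centerOffset = (dT - 1) / 2)
}

# quadratic subvoxel peak refinement along one axis; values c(m, c0, p)
quadPeakOffset <- function(m, c0, p) {
  den <- m - 2 * c0 + p
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (m - p) / den
  max(-0.5, min(0.5, off))
}

#' Detect grid markers by template matching
#'
#' For each expected marker, searches the normalized cross-correlation
#' map within a neighbourhood (default: half the grid spacing) of the
#' marker's approximate position, takes the NCC peak, and refines the
#' position to subvoxel precision by separable quadratic interpolation of
#' the 3-point peak neighbourhood per axis. Markers whose peak NCC falls
#' below `minScore` (or whose neighbourhood has no image variance) are
#' reported missing.
#'
#' @param image 3D numeric array.
#' @param imageAffine 4x4 voxel-to-world matrix of `image`.
#' @param template binary template from [makeCrossTemplate()].
#' @param approx a [MarkerSet-class] giving one approximate position per
#'   expected marker (typically the theoretical reference set).
#' @param minScore NCC detection threshold in [-1, 1].
#' @param searchRadiusMm search neighbourhood half-width, mm.
#' @return a [MarkerSet-class] with detected positions, NCC scores and
#'   missing flags, sharing ids and grid indices with `approx`.
#' @export
detectMarkers <- function(image, imageAffine, template, approx,
                          minScore = 0.5, searchRadiusMm = 12.5) {
  stopifnot(is(approx, "MarkerSet"))
  mt <- matchTemplateNCC(image, template)
  ncc <- mt$ncc
  off <- mt$centerOffset
  dN <- dim(ncc)
  vox <- abs(diag(imageAffine)[1:3])
  radVox <- pmax(1, searchRadiusMm / vox)
  n <- length(markerIds(approx))
  pos <- matrix(NA_real_, n, 3L)
  score <- rep(NA_real_, n)
  miss <- rep(TRUE, n)
  expVox <- worldToVoxel(imageAffine, markerPositions(approx))
  for (m in seq_len(n)) {
    # neighbourhood in placement-corner coordinates (0-based)
    ctr <- expVox[m, ] - off
    lo <- pmax(0, floor(ctr - radVox))
    hi <- pmin(dN - 1L, ceiling(ctr + radVox))
    if (any(hi < lo)) next
    sub <- ncc[(lo[1L] + 1L):(hi[1L] + 1L),
               (lo[2L] + 1L):(hi[2L] + 1L),
               (lo[3L] + 1L):(hi[3L] + 1L), drop = FALSE]
    if (all(is.na(sub))) next
    best <- which(sub == max(sub, na.rm = TRUE))[1L]
    bi <- arrayInd(best, dim(sub))[1L, ] - 1L + lo   # 0-based corner index
    sc <- ncc[bi[1L] + 1L, bi[2L] + 1L, bi[3L] + 1L]
    if (!is.finite(sc) || sc < minScore) {
      score[m] <- if (is.finite(sc)) sc else NA_real_
      next
    }
    delta <- numeric(3L)
    for (ax in 1:3) {
      if (bi[ax] >= 1L && bi[ax] <= dN[ax] - 2L) {
        im_ <- bi; im_[ax] <- im_[ax] - 1L
        ip_ <- bi; ip_[ax] <- ip_[ax] + 1L
        vm <- ncc[im_[1L] + 1L, im_[2L] + 1L, im_[3L] + 1L]
        vp <- ncc[ip_[1L] + 1L, ip_[2L] + 1L, ip_[3L] + 1L]
        if (is.finite(vm) && is.finite(vp))
          delta[ax] <- quadPeakOffset(vm, sc, vp)
      }
    }
    pos[m, ] <- voxelToWorld(imageAffine, bi + off + delta)
    score[m] <- sc
    miss[m] <- FALSE
  }
  new("MarkerSet", ids = markerIds(approx), gridIndex = gridIndex(approx),
      posMm = pos, score = score, missing = miss)
}

#' Rigid (rotation + translation) Procrustes registration
#'
#' Least-squares rigid alignment of matched point sets: finds the rotation
#' R (det = +1, reflection-corrected) and translation t minimizing
#' `sum(|| R m_i + t - f_i ||^2)` via the SVD of the cross-covariance of
#' the centred sets. No scaling is estimated: the transform is strictly
#' rigid.
#'
#' @param moving,fixed n x 3 matrices of matched coordinates (n >= 3,
#'   non-collinear).
#' @return a [RigidTransform-class] mapping `moving` onto `fixed`.
#' @export
rigidProcrustes <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(ncol(moving) == 3L, ncol(fixed) == 3L)
  n <- nrow(moving)
  if (n != nrow(fixed)) stop("point sets must be matched (equal size)")
  if (n < 3L) stop("rigid registration needs at least 3 point pairs")
  mBar <- colMeans(moving); fBar <- colMeans(fixed)
  Mc <- sweep(moving, 2L, mBar); Fc <- sweep(fixed, 2L, fBar)
  svM <- svd(Mc)$d
  if (svM[2L] <= max(svM[1L], 1) * 1e-10)
    stop("points are collinear; the rotation is not identifiable")
  H <- crossprod(Mc, Fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_ <- fBar - as.vector(R %*% mBar)
  new("RigidTransform", rotation = R, translation = t_)
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param points n x 3 matrix (mm).
#' @return n x 3 matrix of transformed points.
#' @export
applyRigid <- function(transform, points) {
  points <- rbind2mat(points)
  sweep(points %*% t(rotation(transform)), 2L, translation(transform), "+")
}

#' Select the central 3 x 3 x 3 block of a marker lattice
#'
#' Returns the ids of the 27 markers occupying the middle three lattice
#' positions along each axis. Requires an odd number of lattice positions
#' per axis (on an even lattice no canonical centre exists and an explicit
#' selection must be supplied instead).
#'
#' @param markers a [MarkerSet-class].
#' @return character vector of marker ids.
#' @export
centralMarkers <- function(markers) {
  gi <- gridIndex(markers)
  keep <- rep(TRUE, nrow(gi))
  for (ax in 1:3) {
    u <- sort(unique(gi[, ax]))
    if (length(u) %% 2L == 0L)
      stop("even lattice: no canonical central block; supply a selection")
    mid <- u[((length(u) + 1L) %/% 2L) + (-1L:1L)]
    mid <- mid[!is.na(mid)]
    keep <- keep & gi[, ax] %in% mid
  }
  markerIds(markers)[keep]
}

#' Marker-based geometric distortion report
#'
#' Fits a rigid transform on the central markers only (detected vs
#' theoretical positions), applies it to all detected markers, and reports
#' the per-marker Euclidean distance to the reference positions together
#' with the mean and maximum over matched (non-missing) markers. Removing
#' the global rigid motion first ensures the report measures deformation,
#' not positioning.
#'
#' @param detected,reference [MarkerSet-class] objects sharing ids/grid
#'   indices (`detected` may have missing markers).
#' @param centralIds marker ids used for the rigid fit; defaults to the
#'   central 3 x 3 x 3 block of `reference`.
#' @return a [DistortionReport-class].
#' @export
markerDistortion <- function(detected, reference,
                             centralIds = centralMarkers(reference)) {
  ids <- markerIds(reference)
  det_ <- match(ids, markerIds(detected))
  if (anyNA(det_)) stop("detected and reference sets must share marker ids")
  ok <- !isMissing(detected)[det_]
  cen <- ids %in% centralIds & ok
  if (sum(cen) < 3L)
    stop("fewer than 3 central markers detected; cannot register")
  tf <- rigidProcrustes(markerPositions(detected)[det_[cen], , drop = FALSE],
                        markerPositions(reference)[cen, , drop = FALSE])
  aligned <- applyRigid(tf, markerPositions(detected)[det_[ok], , drop = FALSE])
  ref <- markerPositions(reference)[ok, , drop = FALSE]
  dist <- sqrt(rowSums((aligned - ref)^2))
  per <- data.frame(
    id = ids[ok],
    i = gridIndex(reference)[ok, 1L],
    j = gridIndex(reference)[ok, 2L],
    k = gridIndex(reference)[ok, 3L],
    ref_x_mm = ref[, 1L], ref_y_mm = ref[, 2L], ref_z_mm = ref[, 3L],
    det_x_mm = aligned[, 1L], det_y_mm = aligned[, 2L],
    det_z_mm = aligned[, 3L],
    distance_mm = dist,
    score = detectionScores(detected)[det_[ok]],
    stringsAsFactors = FALSE
  )
  new("DistortionReport", perMarker = per,
      meanMm = mean(dist), maxMm = max(dist),
      nDetected = as.integer(sum(ok)), nReference = length(ids),
      transform = tf)
}

#' Average distortion reports into a scenario summary
#'
#' A scenario (e.g. one bandwidth / orientation setting) is acquired as
#' several b-value / diffusion-direction images; each yields its own
#' distortion report. The scenario summary is the arithmetic mean of the
#' per-report mean distortions and the arithmetic mean of the per-report
#' maximum distortions.
#'
#' @param reports non-empty list of [DistortionReport-class] objects.
#' @return named numeric: `mean_mm`, `max_mm`.
#' @export
scenarioSummary <- function(reports) {
  if (length(reports) == 0L) stop("at least one report is required")
  c(mean_mm = mean(vapply(reports, meanDistortion, numeric(1))),
    max_mm = mean(vapply(reports, maxDistortion, numeric(1))))
}

#' Manufacturing-accuracy check of a grid phantom from a high-resolution scan
#'
#' Runs the same marker pipeline (template matching, rigid referencing,
#' per-marker distances) on a high-resolution (CT-like) image of the grid,
#' quantifying how accurately the physical grid realizes its theoretical
#' lattice before it is used as a distortion reference.
#'
#' @param image high-resolution 3D grid image.
#' @param imageAffine its 4x4 voxel-to-world matrix.
#' @param reference theoretical [MarkerSet-class].
#' @param beamThicknessMm beam thickness, mm.
#' @param armLengthMm template arm half-length, mm.
#' @param minScore NCC detection threshold.
#' @return a [DistortionReport-class].
#' @export
gridManufacturingQC <- function(image, imageAffine, reference,
                                beamThicknessMm = 6, armLengthMm = 9,
                                minScore = 0.5) {
  vox <- abs(diag(imageAffine)[1:3])
  tpl <- makeCrossTemplate(beamThicknessMm, vox, armLengthMm)
  det_ <- detectMarkers(image, imageAffine, tpl, reference,
                        minScore = minScore)
  markerDistortion(det_, reference)
}
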