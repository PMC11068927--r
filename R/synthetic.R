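# Synthetic phantom and brain-like scene generators, DWI signal simulation,
# Rician noise, susceptibility-like off-resonance fields and EPI warping.
# These generators define the study conditions the analysis pipeline is
# validated under; defaults mirror the calibrated-vial and grid-phantom
# geometries and typical low-field brain acquisition settings.

#' Construct an acquisition protocol
#'
#' @param bValues numeric, b-values in s/mm^2 (ascending, containing 0).
#' @param peAxis phase-encode axis as R array dimension (1, 2 or 3).
#' @param peSign +1 or -1.
#' @param bwPePx per-pixel receiver bandwidth along PE, Hz/px.
#' @param voxelSize numeric(3), mm.
#' @param resonanceHz scanner resonance frequency, Hz.
#' @return an [AcquisitionProtocol-class].
#' @examples
#' acquisitionProtocol(c(0, 800), bwPePx = 1352, voxelSize = c(3, 3, 6),
#'                     resonanceHz = 14.707e6)
#' @export
acquisitionProtocol <- function(bValues, peAxis = 2L, peSign = 1L,
                                bwPePx, voxelSize, resonanceHz) {
  new("AcquisitionProtocol",
      bValues = as.numeric(bValues), peAxis = as.integer(peAxis),
      peSign = as.integer(peSign), bwPePx = as.numeric(bwPePx),
      voxelSize = as.numeric(voxelSize), resonanceHz = as.numeric(resonanceHz))
}

#' Default protocols for a 0.35 T MR-Linac and a 3 T scanner
#'
#' The MR-Linac default uses five b-values 0--800 s/mm^2, the "normal"
#' 1352 Hz/px per-pixel PE bandwidth, 3 x 3 x 6 mm voxels and the 14.707 MHz
#' resonance of a 0.35 T system. The 3 T default uses the two-point
#' b = \{0, 1000\} s/mm^2 scheme and the 123.152 MHz resonance. All
#' parameters are overridable.
#'
#' @param bValues,bwPePx,voxelSize,resonanceHz,peAxis,peSign see
#'   [acquisitionProtocol()].
#' @return an [AcquisitionProtocol-class].
#' @export
mrLinacProtocol <- function(bValues = c(0, 200, 400, 600, 800),
                            bwPePx = 1352, voxelSize = c(3, 3, 6),
                            resonanceHz = 14.707e6,
                            peAxis = 2L, peSign = 1L) {
  acquisitionProtocol(bValues, peAxis, peSign, bwPePx, voxelSize, resonanceHz)
}

#' @rdname mrLinacProtocol
#' @export
threeTeslaProtocol <- function(bValues = c(0, 1000),
                               bwPePx = 1352, voxelSize = c(2, 2, 4),
                               resonanceHz = 123.152e6,
                               peAxis = 2L, peSign = 1L) {
  acquisitionProtocol(bValues, peAxis, peSign, bwPePx, voxelSize, resonanceHz)
}

newScene <- function(labelMap, tissueParams, affine, meta = list()) {
  storage.mode(labelMap) <- "integer"
  new("Scene", labelMap = labelMap, tissueParams = tissueParams,
      affine = affine, meta = meta)
}

#' Synthetic multi-vial ADC calibration phantom
#'
#' Builds a scene of parallel cylindrical vials (long axis along z) with
#' known diffusion coefficients, emulating a calibrated diffusion phantom.
#' Vial centres are laid out on a centred square lattice in-plane. The
#' default ADC values are the four calibrated vials 400, 1000, 1600 and
#' 2020 um^2/s (valid at 20 degrees C).
#'
#' @param gridShape integer(3), image dimensions in voxels.
#' @param voxelSize numeric(3), mm.
#' @param vialAdcs numeric, one true ADC (um^2/s) per vial; 1 to 8 vials.
#' @param vialRadiusMm,vialHeightMm cylinder geometry, mm.
#' @param s0 baseline signal inside the vials (a.u.); background S0 is 0.
#' @return a [Scene-class] with one label per vial; `sceneMeta(x)$vialCentersMm`
#'   holds the cylinder centres.
#' @examples
#' sc <- makeVialPhantom(c(32, 32, 10), c(3, 3, 6))
#' tissueParams(sc)$D
#' @export
makeVialPhantom <- function(gridShape, voxelSize,
                            vialAdcs = c(400, 1000, 1600, 2020),
                            vialRadiusMm = 12, vialHeightMm = 48,
                            s0 = 1000) {
  stopifnot(length(gridShape) == 3L, length(voxelSize) == 3L)
  nv <- length(vialAdcs)
  if (nv < 1L || nv > 8L) stop("between 1 and 8 vials are supported")
  fov <- gridShape * voxelSize
  ncol_ <- ceiling(sqrt(nv))
  nrow_ <- ceiling(nv / ncol_)
  pitch <- c(fov[1L] / ncol_, fov[2L] / nrow_)
  if (any(pitch / 2 < vialRadiusMm + max(voxelSize[1:2])))
    stop("vials overlap or do not fit inside the grid; reduce radius or count")
  if (vialHeightMm > fov[3L])
    stop("vial height exceeds the field of view")
  centers <- matrix(0, nv, 3L)
  for (v in seq_len(nv)) {
    cc <- (v - 1L) %% ncol_
    rr <- (v - 1L) %/% ncol_
    centers[v, ] <- c((cc + 0.5) * pitch[1L], (rr + 0.5) * pitch[2L],
                      fov[3L] / 2)
  }
  affine <- diagAffine(voxelSize)
  lab <- array(0L, gridShape)
  xs <- axisCoordsMm(affine, gridShape, 1L)
  ys <- axisCoordsMm(affine, gridShape, 2L)
  zs <- axisCoordsMm(affine, gridShape, 3L)
  for (v in seq_len(nv)) {
    inxy <- outer((xs - centers[v, 1L])^2, (ys - centers[v, 2L])^2, "+") <=
      vialRadiusMm^2
    inz <- abs(zs - centers[v, 3L]) <= vialHeightMm / 2
    m <- array(outer(as.vector(inxy), inz, "&"), gridShape)
    if (any(lab[m] != 0L)) stop("vial geometry overlaps a previous vial")
    lab[m] <- v
  }
  tp <- data.frame(label = seq_len(nv), S0 = s0, D = as.numeric(vialAdcs),
                   f = 0, Dstar = 0)
  newScene(lab, tp, affine,
           meta = list(vialCentersMm = centers,
                       vialRadiusMm = vialRadiusMm,
                       vialHeightMm = vialHeightMm))
}

#' Cylindrical analysis VOIs for a vial phantom
#'
#' One mask per vial, centred on the vial axis: radius 6 mm and height
#' 39 mm by default (the standard evaluation cylinder for calibrated
#' vials), strictly interior to the default vial geometry.
#'
#' @param scene a vial-phantom [Scene-class].
#' @param radiusMm,heightMm VOI cylinder geometry, mm.
#' @return named list of logical 3D masks.
#' @export
vialVOIMasks <- function(scene, radiusMm = 6, heightMm = 39) {
  centers <- sceneMeta(scene)$vialCentersMm
  if (is.null(centers)) stop("scene does not carry vial centres")
  d <- dim(labelMap(scene))
  A <- affine(scene)
  xs <- axisCoordsMm(A, d, 1L); ys <- axisCoordsMm(A, d, 2L)
  zs <- axisCoordsMm(A, d, 3L)
  out <- vector("list", nrow(centers))
  for (v in seq_len(nrow(centers))) {
    inxy <- outer((xs - centers[v, 1L])^2, (ys - centers[v, 2L])^2, "+") <=
      radiusMm^2
    inz <- abs(zs - centers[v, 3L]) <= heightMm / 2
    out[[v]] <- array(outer(as.vector(inxy), inz, "&"), d)
  }
  names(out) <- paste0("vial", seq_len(nrow(centers)))
  out
}

#' Synthetic 3D grid phantom and its theoretical marker lattice
#'
#' Rasterizes a cubic lattice of orthogonal beams (default 6 mm thick,
#' 25 mm apart, 10 x 10 x 10 cm^3 grid) at a given voxel size, and returns
#' the theoretical marker set: the beam intersection points, indexed by
#' their lattice position and sorted lexicographically by grid index.
#' Marker world coordinates are exact multiples of the spacing relative to
#' the grid origin.
#'
#' @param spacingMm beam centre-to-centre spacing, mm.
#' @param beamThicknessMm beam thickness, mm; must be < spacing and
#'   > voxel size.
#' @param fovMm numeric(3), grid extent per axis, mm.
#' @param voxelSize numeric(3), image resolution, mm.
#' @param marginMm padding added around the grid, mm; must be generous
#'   enough that a warped corner marker plus the matching template stays
#'   interior to the image.
#' @return list with `image` (binary 3D array), `markers` (a
#'   [MarkerSet-class]) and `affine`.
#' @export
makeGridPhantom <- function(spacingMm = 25, beamThicknessMm = 6,
                            fovMm = c(100, 100, 100), voxelSize,
                            marginMm = 20) {
  stopifnot(length(voxelSize) == 3L)
  if (spacingMm <= beamThicknessMm)
    stop("spacing must exceed the beam thickness")
  if (any(voxelSize >= beamThicknessMm))
    stop("voxel size must be smaller than the beam thickness")
  nLines <- floor(fovMm / spacingMm) + 1L
  if (any(nLines < 3L)) stop("need at least 3 grid lines per axis")
  gridExtent <- (nLines - 1L) * spacingMm
  dims <- as.integer(ceiling((gridExtent + 2 * marginMm) / voxelSize)) + 1L
  affine <- diagAffine(voxelSize)
  fovCenter <- (dims - 1L) * voxelSize / 2
  origin <- fovCenter - gridExtent / 2   # world mm of lattice index (0,0,0)
  coords <- lapply(1:3, function(ax) axisCoordsMm(affine, dims, ax))
  # per-axis partial-volume coverage: fraction of each voxel overlapped by
  # the nearest lattice slab (exact area weighting, so marker positions
  # are preserved to well below the voxel size)
  cover <- lapply(1:3, function(ax) {
    pos <- origin[ax] + (seq_len(nLines[ax]) - 1L) * spacingMm
    slabCoverage1D(coords[[ax]], voxelSize[ax], pos, beamThicknessMm)
  })
  img <- array(0, dims)
  # a beam along axis a covers the full axis and a slab in both others
  for (a in 1:3) {
    axCov <- lapply(1:3, function(ax) if (ax == a) rep(1, dims[ax])
                    else cover[[ax]])
    beam <- outer(outer(axCov[[1L]], axCov[[2L]], "*"), axCov[[3L]], "*")
    img <- pmax(img, beam)
  }
  gi <- as.matrix(expand.grid(i = 0:(nLines[1L] - 1L),
                              j = 0:(nLines[2L] - 1L),
                              k = 0:(nLines[3L] - 1L)))
  ord <- order(gi[, 1L], gi[, 2L], gi[, 3L])
  gi <- gi[ord, , drop = FALSE]
  pos <- sweep(gi * spacingMm, 2L, origin, "+")
  markers <- new("MarkerSet",
                 ids = sprintf("m%d_%d_%d", gi[, 1L], gi[, 2L], gi[, 3L]),
                 gridIndex = unname(gi), posMm = unname(pos),
                 score = rep(NA_real_, nrow(gi)),
                 missing = rep(FALSE, nrow(gi)))
  list(image = img, markers = markers, affine = affine,
       spacingMm = spacingMm, beamThicknessMm = beamThicknessMm)
}

#' Default diffusion parameters for a three-compartment brain scene
#'
#' Literature-typical values: WM D = 700, GM D = 900, CSF D = 3000 um^2/s.
#' CSF optionally carries an intravoxel-incoherent-motion (IVIM) perfusion
#' compartment (`csfF`, `csfDstar`) producing bi-exponential decay; WM and
#' GM are mono-exponential.
#'
#' @param csfF CSF perfusion fraction in [0, 1).
#' @param csfDstar CSF pseudo-diffusion coefficient, um^2/s.
#' @return data.frame usable as `tissueParams` (labels 1 = CSF, 2 = GM,
#'   3 = WM).
#' @export
brainTissueParams <- function(csfF = 0.3, csfDstar = 10000) {
  data.frame(
    label = 1:3,
    tissue = c("CSF", "GM", "WM"),
    S0 = c(1000, 800, 700),
    D = c(3000, 900, 700),
    f = c(csfF, 0, 0),
    Dstar = c(csfDstar, 0, 0)
  )
}

#' Synthetic brain-like scene of nested ellipsoids
#'
#' Three mutually exclusive compartments: a WM core ellipsoid, a GM shell
#' and a CSF rim, centred in the volume. The label map doubles as the VOI
#' label map for per-tissue statistics (1 = CSF, 2 = GM, 3 = WM).
#'
#' @param gridShape integer(3), voxels.
#' @param voxelSize numeric(3), mm.
#' @param tissueParams data.frame as from [brainTissueParams()].
#' @param csfRimMm,gmShellMm shell thicknesses, mm.
#' @return a [Scene-class].
#' @export
makeBrainScene <- function(gridShape, voxelSize,
                           tissueParams = brainTissueParams(),
                           csfRimMm = 8, gmShellMm = 10) {
  stopifnot(length(gridShape) == 3L, length(voxelSize) == 3L)
  fov <- gridShape * voxelSize
  outer_ <- 0.44 * fov          # CSF outer semi-axes
  if (any(outer_ + voxelSize / 2 > fov / 2))
    stop("ellipsoids exceed the grid; enlarge gridShape")
  gmOuter <- outer_ - csfRimMm
  wmOuter <- gmOuter - gmShellMm
  if (any(wmOuter <= 0)) stop("shells leave no room for the WM core")
  affine <- diagAffine(voxelSize)
  ctr <- (gridShape - 1L) * voxelSize / 2
  xs <- axisCoordsMm(affine, gridShape, 1L) - ctr[1L]
  ys <- axisCoordsMm(affine, gridShape, 2L) - ctr[2L]
  zs <- axisCoordsMm(affine, gridShape, 3L) - ctr[3L]
  rad2 <- function(semi) {
    x2 <- (xs / semi[1L])^2; y2 <- (ys / semi[2L])^2; z2 <- (zs / semi[3L])^2
    array(outer(outer(x2, y2, "+"), z2, "+"), gridShape)
  }
  lab <- array(0L, gridShape)
  lab[rad2(outer_) <= 1] <- 1L   # CSF rim (filled, then overwritten inward)
  lab[rad2(gmOuter) <= 1] <- 2L  # GM shell
  lab[rad2(wmOuter) <= 1] <- 3L  # WM core
  newScene(lab, tissueParams, affine)
}

#' Noise-free diffusion-weighted signal of a scene
#'
#' Evaluates the bi-exponential (IVIM) signal model per voxel,
#' `S(b) = S0 * (f * exp(-b * Dstar * 1e-6) + (1 - f) * exp(-b * D * 1e-6))`,
#' with b in s/mm^2 and diffusion coefficients in um^2/s (the factor 1e-6
#' converts um^2 to mm^2, making the exponent dimensionless). Tissues with
#' `f = 0` reduce to the mono-exponential model `S0 * exp(-b * D * 1e-6)`.
#'
#' @param scene a [Scene-class].
#' @param b a single b-value, s/mm^2 (>= 0).
#' @return 3D numeric array; background voxels are 0.
#' @examples
#' sc <- makeVialPhantom(c(32, 32, 10), c(3, 3, 6), vialAdcs = 1000)
#' max(simulateSignal(sc, 800))  # 1000 * exp(-0.8)
#' @export
simulateSignal <- function(scene, b) {
  stopifnot(length(b) == 1L, b >= 0)
  tp <- tissueParams(scene)
  lab <- labelMap(scene)
  lut <- numeric(max(tp$label) + 1L)   # index = label + 1
  lut[1L] <- 0
  lut[tp$label + 1L] <- tp$S0 *
    (tp$f * exp(-b * tp$Dstar * 1e-6) + (1 - tp$f) * exp(-b * tp$D * 1e-6))
  array(lut[lab + 1L], dim(lab))
}

#' Add Rician noise to a magnitude volume
#'
#' Magnitude-image noise: `out = sqrt((v + g1)^2 + g2^2)` with g1, g2
#' i.i.d. Normal(0, sigma^2), the standard two-channel model whose
#' signal-free background follows a Rayleigh distribution (mean
#' `sigma * sqrt(pi/2)`, second moment `2 * sigma^2`) -- the uniform noise
#' floor the ADC fit corrects for.
#'
#' @param volume numeric array.
#' @param sigma noise standard deviation per channel (>= 0); 0 returns the
#'   input unchanged.
#' @param seed integer seed (required; the generator is bit-reproducible).
#' @return array of the same shape.
#' @export
addRicianNoise <- function(volume, sigma, seed) {
  if (missing(seed)) stop("a seed is required")
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  set.seed(as.integer(seed))
  n <- length(volume)
  g1 <- stats::rnorm(n, 0, sigma)
  g2 <- stats::rnorm(n, 0, sigma)
  out <- sqrt((as.vector(volume) + g1)^2 + g2^2)
  array(out, dim(volume))
}

#' Smooth susceptibility-like off-resonance field
#'
#' A Gaussian random field (white noise smoothed with an isotropic Gaussian
#' kernel of scale `smoothScaleMm`), demeaned over the support mask and
#' scaled so its maximum magnitude equals `amplitudeHz`, plus an optional
#' localized positive Gaussian blob (emulating e.g. the focal off-resonance
#' above air cavities).
#'
#' @param gridShape integer(3), voxels.
#' @param voxelSize numeric(3), mm.
#' @param smoothScaleMm smoothing kernel sigma, mm.
#' @param amplitudeHz maximum magnitude of the random component, Hz (>= 0).
#' @param blobSpec optional list(`centerMm`, `sigmaMm`, `amplitudeHz`) for
#'   the positive blob.
#' @param seed integer seed.
#' @param mask optional logical array; the field is demeaned over it and
#'   zeroed outside (defaults to the whole volume).
#' @return a [FieldMap-class].
#' @export
makeSusceptibilityField <- function(gridShape, voxelSize, smoothScaleMm = 20,
                                    amplitudeHz, blobSpec = NULL, seed,
                                    mask = NULL) {
  if (amplitudeHz < 0) stop("amplitudeHz must be >= 0")
  if (missing(seed)) stop("a seed is required")
  affine <- diagAffine(voxelSize)
  vals <- array(0, gridShape)
  if (amplitudeHz > 0) {
    set.seed(as.integer(seed))
    vals <- array(stats::rnorm(prod(gridShape)), gridShape)
    vals <- gaussSmooth3D(vals, smoothScaleMm / voxelSize)
    if (!is.null(mask)) {
      vals[!mask] <- 0
      vals[mask] <- vals[mask] - mean(vals[mask])
    } else {
      vals <- vals - mean(vals)
    }
    m <- max(abs(vals))
    if (m > 0) vals <- vals * (amplitudeHz / m)
  }
  if (!is.null(blobSpec)) {
    ctr <- blobSpec$centerMm
    sg <- rep_len(blobSpec$sigmaMm, 3L)
    xs <- axisCoordsMm(affine, gridShape, 1L)
    ys <- axisCoordsMm(affine, gridShape, 2L)
    zs <- axisCoordsMm(affine, gridShape, 3L)
    q <- outer(outer(((xs - ctr[1L]) / sg[1L])^2,
                     ((ys - ctr[2L]) / sg[2L])^2, "+"),
               ((zs - ctr[3L]) / sg[3L])^2, "+")
    vals <- vals + blobSpec$amplitudeHz * exp(-0.5 * array(q, gridShape))
  }
  new("FieldMap", values = vals, affine = affine)
}

#' Apply an EPI susceptibility warp along the phase-encode axis
#'
#' Displaces image content along the PE axis by
#' `d_px = peSign * field / bwPePx` pixels and modulates intensity so that
#' line integrals along PE are conserved: pixel edges are transported by the
#' displacement field and the cumulative intensity profile is resampled at
#' the original edges (an exactly mass-conserving scheme; for a constant
#' field this is a rigid `d_px` shift with unit Jacobian).
#'
#' @param volume 3D numeric array.
#' @param field a [FieldMap-class] (Hz) on the same grid, or a 3D array
#'   of Hz values.
#' @param protocol an [AcquisitionProtocol-class] (supplies the PE axis and
#'   the per-pixel bandwidth).
#' @param peSign +1 or -1, PE polarity of this acquisition (defaults to the
#'   protocol's).
#' @return warped array of the same shape.
#' @export
applyEpiWarp <- function(volume, field, protocol, peSign = NULL) {
  hz <- if (is(field, "FieldMap")) fieldValues(field) else field
  if (!identical(dim(hz), dim(volume)))
    stop("field and volume must share a grid")
  s <- if (is.null(peSign)) protocol@peSign else as.integer(peSign)
  if (!(s %in% c(-1L, 1L))) stop("peSign must be +1 or -1")
  dpx <- s * hz / bwPePx(protocol)
  applyDisplacementVolume(volume, dpx, peAxis(protocol))
}

#' Simulate a full DWI acquisition of a scene
#'
#' For each requested PE polarity and each protocol b-value: evaluate the
#' noise-free signal, apply the off-resonance EPI warp for that polarity
#' (if a field is given), then add Rician noise. All volumes are stacked
#' into one [DWISeries-class] (replicate b-values from the two polarities
#' are averaged later by the ADC fit, after noise-floor correction).
#'
#' @param scene a [Scene-class].
#' @param protocol an [AcquisitionProtocol-class].
#' @param seed integer master seed; per-volume noise seeds are derived
#'   deterministically from it.
#' @param sigma Rician noise sigma (a.u.); e.g. `S0 / 40` for SNR 40 at
#'   b = 0.
#' @param field optional [FieldMap-class] driving the EPI distortion.
#' @param peSignList integer vector of polarities to acquire.
#' @return a [DWISeries-class] with `length(bValues) * length(peSignList)`
#'   volumes.
#' @export
simulateAcquisition <- function(scene, protocol, seed, sigma,
                                field = NULL, peSignList = c(1L, -1L)) {
  bv <- bValues(protocol)
  d <- dim(labelMap(scene))
  nvol <- length(bv) * length(peSignList)
  data <- array(0, c(d, nvol))
  bOut <- numeric(nvol)
  sOut <- integer(nvol)
  v <- 0L
  for (s in peSignList) {
    for (b in bv) {
      v <- v + 1L
      img <- simulateSignal(scene, b)
      if (!is.null(field))
        img <- applyEpiWarp(img, field, protocol, peSign = s)
      data[, , , v] <- addRicianNoise(img, sigma, deriveSeed(seed, v))
      bOut[v] <- b
      sOut[v] <- as.integer(s)
    }
  }
  new("DWISeries", data = data, bValues = bOut, peSigns = sOut,
      protocol = protocol, affine = affine(scene))
}
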