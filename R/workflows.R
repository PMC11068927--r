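# Study simulators and end-to-end workflows: calibrated-vial ADC
# validation, grid-phantom distortion quantification, and brain-like ADC +
# off-resonance evaluation. Simulator defaults define the study
# conditions; every source of randomness flows from the single `seed`.

#' Simulate a complete vial-phantom DWI study
#'
#' Four calibrated vials (400/1000/1600/2020 um^2/s) in a 3 x 3 x 6 mm
#' acquisition at b = 0--800 s/mm^2, acquired twice with opposite PE
#' polarity under a gentle smooth off-resonance field, with Rician noise
#' at the requested baseline SNR. Also returns the cylindrical analysis
#' VOIs (radius 6 mm, height 39 mm) and a signal-free background cuboid
#' for the noise-floor estimate.
#'
#' @param seed integer master seed.
#' @param snr baseline (b = 0) signal-to-noise ratio; noise sigma is
#'   `s0 / snr`.
#' @param protocol an [AcquisitionProtocol-class].
#' @param vialAdcs true vial ADCs, um^2/s.
#' @param gridShape image dimensions, voxels.
#' @param fieldAmplitudeHz maximum magnitude of the off-resonance field
#'   (0 disables the EPI warp).
#' @param s0 baseline vial signal, a.u.
#' @return list: `dwi` ([DWISeries-class]), `scene`, `voiMasks`,
#'   `noiseCuboid` (start/size, 0-based), `trueAdcs`, `manifest`.
#' @export
simulateVialPhantomStudy <- function(seed, snr = 40,
                                     protocol = mrLinacProtocol(),
                                     vialAdcs = c(400, 1000, 1600, 2020),
                                     gridShape = c(32L, 32L, 10L),
                                     fieldAmplitudeHz = 300,
                                     s0 = 1000) {
  scene <- makeVialPhantom(gridShape, voxelSize(protocol),
                           vialAdcs = vialAdcs, s0 = s0)
  field <- if (fieldAmplitudeHz > 0)
    makeSusceptibilityField(gridShape, voxelSize(protocol),
                            smoothScaleMm = 25,
                            amplitudeHz = fieldAmplitudeHz,
                            seed = deriveSeed(seed, 101L))
  else NULL
  sigma <- s0 / snr
  dwi <- simulateAcquisition(scene, protocol, seed = seed, sigma = sigma,
                             field = field)
  list(dwi = dwi, scene = scene,
       voiMasks = vialVOIMasks(scene),
       noiseCuboid = list(start = c(0L, 0L, 0L),
                          size = c(6L, 6L, gridShape[3L])),
       trueAdcs = vialAdcs,
       field = field,
       manifest = list(stage = "simulate-vials", seed = seed, snr = snr,
                       b_values = bValues(protocol), vial_adcs = vialAdcs,
                       grid_shape = gridShape,
                       field_amplitude_hz = fieldAmplitudeHz, s0 = s0))
}

#' Calibrated-vial ADC validation workflow
#'
#' Estimates the background noise floor from the cuboid, fits the ADC map
#' twice (all b-values; the b = \{0, 800\} pair), summarises each vial VOI,
#' and reports relative differences of the VOI mean/median against the
#' (optionally temperature-corrected) calibrated references.
#'
#' @param dwi a [DWISeries-class] containing both PE polarities.
#' @param voiMasks named list of logical VOI masks, one per vial.
#' @param noiseCuboidStart,noiseCuboidSize background cuboid (0-based).
#' @param referenceAdcs numeric, calibrated reference ADC per vial
#'   (um^2/s); ignored when a calibration table is given.
#' @param calibrationTable optional data.frame (`vial`, `temp_c`, `adc`)
#'   for temperature correction; vial ids must match `names(voiMasks)`.
#' @param temperatureC acquisition temperature, degrees C (required with
#'   `calibrationTable`).
#' @param bSubsetTwo the two-point subset (default b = \{0, 800\}).
#' @return list: `table` (one row per vial x method), `adcAll`, `adcTwo`,
#'   `noise`.
#' @export
runPhantom1Workflow <- function(dwi, voiMasks, noiseCuboidStart,
                                noiseCuboidSize, referenceAdcs = NULL,
                                calibrationTable = NULL, temperatureC = NULL,
                                bSubsetTwo = c(0, 800)) {
  noise <- estimateBackgroundNoise(dwi, noiseCuboidStart, noiseCuboidSize)
  adcAll <- fitADC(dwi, noise = noise)
  adcTwo <- fitADC(dwi, bSubset = bSubsetTwo, noise = noise)
  vials <- names(voiMasks)
  if (is.null(vials)) vials <- paste0("vial", seq_along(voiMasks))
  refs <- if (!is.null(calibrationTable)) {
    if (is.null(temperatureC))
      stop("temperatureC is required with a calibration table")
    vapply(vials, temperatureCorrectReference, numeric(1),
           tempC = temperatureC, calibrationTable = calibrationTable)
  } else referenceAdcs
  methods_ <- list(ADCall = adcAll,
                   ADC0_800 = adcTwo)
  rows <- list()
  for (v in seq_along(voiMasks)) {
    for (m in names(methods_)) {
      s <- voiSummary(methods_[[m]], voiMasks[[v]])
      ref <- if (is.null(refs)) NA_real_ else refs[[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        vial = vials[v], method = m,
        mean = s@mean, median = s@median, sd = s@sd, np_skew = s@npSkew,
        n = s@n, reference = ref,
        rel_diff_mean = if (is.na(ref)) NA_real_
                        else relativeDifference(s@mean, ref, ref),
        rel_diff_median = if (is.na(ref)) NA_real_
                          else relativeDifference(s@median, ref, ref),
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), adcAll = adcAll, adcTwo = adcTwo,
       noise = noise)
}

# radially increasing PE displacement (mm) with a flat centre, used for
# end-to-end distortion recovery studies: zero inside rInner, rising with
# a smootherstep profile (zero radial gradient at both ends) to dMax at
# the lattice corner radius, so the maximum displacement is attained on a
# locally uniform patch of the field.
radialPeDisplacementField <- function(gridShape, voxelSize, centerMm,
                                      dMaxMm, rInnerMm, rOuterMm,
                                      protocol) {
  affine <- diagAffine(voxelSize)
  xs <- axisCoordsMm(affine, gridShape, 1L) - centerMm[1L]
  ys <- axisCoordsMm(affine, gridShape, 2L) - centerMm[2L]
  zs <- axisCoordsMm(affine, gridShape, 3L) - centerMm[3L]
  r <- sqrt(array(outer(outer(xs^2, ys^2, "+"), zs^2, "+"), gridShape))
  t_ <- pmin(1, pmax(0, (r - rInnerMm) / (rOuterMm - rInnerMm)))
  g <- t_^2 * (3 - 2 * t_)
  dMm <- array(dMaxMm * g, gridShape)
  ax <- peAxis(protocol)
  hz <- dMm / voxelSize[ax] * bwPePx(protocol)
  new("FieldMap", values = hz, affine = affine)
}

#' Simulate a grid-phantom distortion study
#'
#' Rasterizes the 3D grid phantom, warps it with a smooth off-resonance
#' field whose maximum PE displacement at the marker lattice is exactly
#' `dMaxMm` (a radial profile, flat over the central markers so the rigid
#' referencing is not contaminated), acquires both PE polarities and adds
#' Rician noise.
#'
#' @param seed integer master seed.
#' @param dMaxMm maximum true displacement at the lattice, mm.
#' @param snr signal-to-noise ratio of the beam signal.
#' @param voxelSize image resolution, mm.
#' @param protocol acquisition protocol (PE axis/bandwidth); b-values are
#'   not used here.
#' @param s0 beam signal, a.u.
#' @return list: `imgUp`, `imgDown`, `truth` (noise-free unwarped image),
#'   `markers` (reference [MarkerSet-class]), `fieldHz`
#'   ([FieldMap-class]), `affine`, `grid`, `manifest`.
#' @export
simulateGridStudy <- function(seed, dMaxMm = 2, snr = 40,
                              voxelSize = c(2.5, 2.5, 2.5),
                              protocol = mrLinacProtocol(voxelSize = voxelSize),
                              s0 = 1000) {
  grid <- makeGridPhantom(voxelSize = voxelSize)
  img <- grid$image * s0
  d <- dim(img)
  markers <- grid$markers
  ctrMm <- colMeans(markerPositions(markers))
  rOuter <- max(sqrt(rowSums(sweep(markerPositions(markers), 2L, ctrMm)^2)))
  fieldHz <- radialPeDisplacementField(d, voxelSize, ctrMm, dMaxMm,
                                       rInnerMm = 30, rOuterMm = rOuter,
                                       protocol = protocol)
  up <- applyEpiWarp(img, fieldHz, protocol, peSign = 1L)
  dn <- applyEpiWarp(img, fieldHz, protocol, peSign = -1L)
  sigma <- s0 / snr
  if (sigma > 0) {
    up <- addRicianNoise(up, sigma, deriveSeed(seed, 11L))
    dn <- addRicianNoise(dn, sigma, deriveSeed(seed, 12L))
  }
  list(imgUp = up, imgDown = dn, truth = img, markers = markers,
       fieldHz = fieldHz, affine = grid$affine, grid = grid,
       protocol = protocol,
       manifest = list(stage = "simulate-grid", seed = seed,
                       d_max_mm = dMaxMm, snr = snr,
                       voxel_size = voxelSize, s0 = s0))
}

#' Grid-phantom distortion quantification workflow
#'
#' Detects markers on the up, down and distortion-corrected images
#' (template matching + rigid referencing on the central 27 markers),
#' where the corrected image comes from the reversed-PE field estimate.
#' Returns the three distortion reports and a six-row summary table
#' (mean/max distortion for each image).
#'
#' @param imgUp,imgDown reversed-PE grid images (3D arrays).
#' @param imageAffine 4x4 voxel-to-world matrix.
#' @param protocol an [AcquisitionProtocol-class].
#' @param reference theoretical [MarkerSet-class].
#' @param beamThicknessMm,armLengthMm template geometry, mm.
#' @param minScore NCC detection threshold.
#' @param smoothMm field-estimate smoothing, mm.
#' @param backgroundThreshold background suppression fraction for the
#'   field estimate.
#' @return list: `reports` (up/down/corrected [DistortionReport-class]),
#'   `table`, `field` ([DisplacementField1D-class]), `corrected`.
#' @export
runPhantom2Workflow <- function(imgUp, imgDown, imageAffine, protocol,
                                reference, beamThicknessMm = 6,
                                armLengthMm = 9, minScore = 0.5,
                                smoothMm = 6, backgroundThreshold = 0.1) {
  vox <- abs(diag(imageAffine)[1:3])
  tpl <- makeCrossTemplate(beamThicknessMm, vox, armLengthMm)
  field <- estimateFieldReversedPE(imgUp, imgDown, protocol,
                                   smoothMm = smoothMm,
                                   backgroundThreshold = backgroundThreshold)
  corrected <- unwarpPair(imgUp, imgDown, field)
  images <- list(up = imgUp, down = imgDown, corrected = corrected)
  reports <- lapply(images, function(im) {
    det_ <- detectMarkers(im, imageAffine, tpl, reference,
                          minScore = minScore)
    markerDistortion(det_, reference)
  })
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    data.frame(image = nm, metric = c("mean", "max"),
               distortion_mm = c(meanDistortion(reports[[nm]]),
                                 maxDistortion(reports[[nm]])),
               n_detected = reports[[nm]]@nDetected,
               n_reference = reports[[nm]]@nReference,
               stringsAsFactors = FALSE)
  }))
  list(reports = reports, table = tab, field = field, corrected = corrected)
}

#' Simulate a brain-like DWI study
#'
#' Nested-ellipsoid brain scene (CSF rim / GM shell / WM core), a
#' susceptibility-like off-resonance field with a focal positive blob at
#' the inferior brain (emulating the field above air cavities), opposite
#' PE acquisitions and Rician noise. The default baseline SNR of 20
#' reflects low-field brain imaging, where the noise floor materially
#' biases high-b signal -- the regime the noise-floor correction is for.
#'
#' @param seed integer master seed.
#' @param snr baseline SNR (sigma = max tissue S0 / snr).
#' @param csfF,csfDstar CSF IVIM perfusion parameters (`csfF = 0` gives a
#'   purely mono-exponential brain).
#' @param protocol an [AcquisitionProtocol-class].
#' @param gridShape image dimensions, voxels.
#' @param fieldAmplitudeHz random field component magnitude, Hz.
#' @param blobAmplitudeHz focal blob magnitude, Hz.
#' @return list: `dwi`, `scene`, `labels`, `fieldHz`, `noiseCuboid`,
#'   `manifest`.
#' @export
simulateBrainStudy <- function(seed, snr = 20, csfF = 0.3, csfDstar = 10000,
                               protocol = mrLinacProtocol(),
                               gridShape = c(40L, 40L, 14L),
                               fieldAmplitudeHz = 400,
                               blobAmplitudeHz = 500) {
  tp <- brainTissueParams(csfF = csfF, csfDstar = csfDstar)
  scene <- makeBrainScene(gridShape, voxelSize(protocol), tissueParams = tp)
  lab <- labelMap(scene)
  fov <- gridShape * voxelSize(protocol)
  blob <- if (blobAmplitudeHz > 0)
    list(centerMm = c(fov[1L] / 2, fov[2L] / 2, 0.15 * fov[3L]),
         sigmaMm = c(15, 15, 12), amplitudeHz = blobAmplitudeHz)
  else NULL
  fieldHz <- makeSusceptibilityField(gridShape, voxelSize(protocol),
                                     smoothScaleMm = 25,
                                     amplitudeHz = fieldAmplitudeHz,
                                     blobSpec = blob,
                                     seed = deriveSeed(seed, 201L),
                                     mask = lab > 0L)
  sigma <- max(tp$S0) / snr
  dwi <- simulateAcquisition(scene, protocol, seed = seed, sigma = sigma,
                             field = fieldHz)
  list(dwi = dwi, scene = scene, labels = lab, fieldHz = fieldHz,
       noiseCuboid = list(start = c(0L, 0L, 0L),
                          size = c(6L, 6L, gridShape[3L])),
       manifest = list(stage = "simulate-brain", seed = seed, snr = snr,
                       csf_f = csfF, csf_dstar = csfDstar,
                       grid_shape = gridShape,
                       field_amplitude_hz = fieldAmplitudeHz,
                       blob_amplitude_hz = blobAmplitudeHz))
}

#' Brain ADC and off-resonance evaluation workflow
#'
#' Fits ADC over all b-values and over the b = \{0, 800\} pair (noise-floor
#' corrected), summarises each tissue VOI, and -- when an off-resonance
#' field is supplied -- reports the 95th-percentile absolute off-resonance
#' within the brain in Hz, ppm and mm of PE displacement.
#'
#' @param dwi a [DWISeries-class].
#' @param labels integer 3D label map (1 = CSF, 2 = GM, 3 = WM by the
#'   synthetic convention; any nonzero labelling works).
#' @param noiseCuboidStart,noiseCuboidSize background cuboid (0-based).
#' @param fieldHz optional [FieldMap-class] or Hz array for the
#'   distortion metrics.
#' @param tissueNames optional names for the labels (in label order).
#' @param bSubsetTwo two-point subset, default b = \{0, 800\}.
#' @return list: `table` (tissue x method VOI summaries), `adcAll`,
#'   `adcTwo`, `fieldMetrics` (p95 Hz/ppm/mm or NULL).
#' @export
runBrainWorkflow <- function(dwi, labels, noiseCuboidStart, noiseCuboidSize,
                             fieldHz = NULL, tissueNames = NULL,
                             bSubsetTwo = c(0, 800)) {
  noise <- estimateBackgroundNoise(dwi, noiseCuboidStart, noiseCuboidSize)
  adcAll <- fitADC(dwi, noise = noise)
  adcTwo <- fitADC(dwi, bSubset = bSubsetTwo, noise = noise)
  labs <- sort(unique(as.vector(labels)))
  labs <- labs[labs != 0]
  if (is.null(tissueNames)) tissueNames <- paste0("tissue", labs)
  methods_ <- list(ADCall = adcAll, ADC0_800 = adcTwo)
  rows <- list()
  for (i in seq_along(labs)) {
    for (m in names(methods_)) {
      s <- voiSummary(methods_[[m]], labels == labs[i])
      rows[[length(rows) + 1L]] <- data.frame(
        voi = tissueNames[i], method = m,
        mean = s@mean, median = s@median, sd = s@sd, np_skew = s@npSkew,
        n = s@n, stringsAsFactors = FALSE)
    }
  }
  fm <- NULL
  if (!is.null(fieldHz)) {
    hz <- if (is(fieldHz, "FieldMap")) fieldValues(fieldHz) else fieldHz
    brain <- labels > 0L
    p <- protocol(dwi)
    fm <- c(p95_hz = p95AbsInMask(hz, brain),
            p95_ppm = p95AbsInMask(fieldToPpm(hz, resonanceHz(p)), brain),
            p95_mm = p95AbsInMask(fieldToDisplacementMm(hz, p), brain))
  }
  list(table = do.call(rbind, rows), adcAll = adcAll, adcTwo = adcTwo,
       fieldMetrics = fm, noise = noise)
}

#' Write a workflow report to TSV + JSON
#'
#' Writes the tabular part of a workflow result as a tab-separated file
#' and any scalar metrics plus the run manifest as JSON.
#'
#' @param table data.frame to write.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param metrics optional named numeric vector or list.
#' @param manifest optional manifest list (inputs, parameters, seed).
#' @return invisibly, the written paths.
#' @export
writeReport <- function(table, dir, name, metrics = NULL, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- tsv
  if (!is.null(metrics) || !is.null(manifest)) {
    js <- file.path(dir, paste0(name, ".json"))
    jsonlite::write_json(list(metrics = as.list(metrics),
                              manifest = manifest),
                         js, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, js)
  }
  invisible(paths)
}
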