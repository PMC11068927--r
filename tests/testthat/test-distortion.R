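# Template construction, NCC marker detection, Procrustes registration
# and distortion reporting.

test_that("cross template geometry follows inclusion-exclusion", {
  vox <- c(2, 2, 2)
  tpl <- makeCrossTemplate(6, vox, armLengthMm = 9)
  d <- dim(tpl)
  expect_true(all(d %% 2L == 1L))
  ctr <- (d + 1L) %/% 2L
  expect_equal(tpl[ctr[1L], ctr[2L], ctr[3L]], 1)
  # symmetric under axis permutation for isotropic voxels
  expect_equal(tpl, aperm(tpl, c(2, 3, 1)))
  # template volume: union of three orthogonal boxes by inclusion-
  # exclusion (pairwise and triple intersections are the central cube)
  analytic <- 3 * (2 * 9 * 6 * 6) - 3 * 6^3 + 6^3
  expect_lt(abs(sum(tpl) * prod(vox) - analytic) / analytic, 0.03)
  expect_error(makeCrossTemplate(6, vox, armLengthMm = 5), "exceed")
})

test_that("markers of an undistorted grid are found to subvoxel accuracy", {
  vox <- c(2.5, 2.5, 2.5)
  grid <- makeGridPhantom(voxelSize = vox)
  tpl <- makeCrossTemplate(6, vox, 9)
  det <- detectMarkers(grid$image, grid$affine, tpl, grid$markers)
  expect_false(any(isMissing(det)))
  err <- sqrt(rowSums((markerPositions(det) -
                       markerPositions(grid$markers))^2))
  expect_lt(max(err), 0.5 * max(vox))
  expect_true(all(detectionScores(det) > 0.9))
})

test_that("detection is equivariant under integer-voxel shifts", {
  vox <- c(2.5, 2.5, 2.5)
  grid <- makeGridPhantom(voxelSize = vox)
  img <- grid$image
  shifted <- array(0, dim(img))
  shifted[, 3:dim(img)[2L], ] <- img[, 1:(dim(img)[2L] - 2L), ]
  tpl <- makeCrossTemplate(6, vox, 9)
  d0 <- detectMarkers(img, grid$affine, tpl, grid$markers)
  d1 <- detectMarkers(shifted, grid$affine, tpl, grid$markers)
  delta <- markerPositions(d1) - markerPositions(d0)
  expect_equal(delta[, 2L], rep(2 * vox[2L], 125), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(delta[, c(1L, 3L)], matrix(0, 125, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("pure noise yields no detections at the default threshold", {
  vox <- c(2.5, 2.5, 2.5)
  grid <- makeGridPhantom(voxelSize = vox)
  set.seed(31)
  noiseImg <- array(rnorm(prod(dim(grid$image))), dim(grid$image))
  tpl <- makeCrossTemplate(6, vox, 9)
  det <- detectMarkers(noiseImg, grid$affine, tpl, grid$markers)
  expect_true(all(isMissing(det)))
})

test_that("rigid Procrustes recovers known motions", {
  set.seed(41)
  fx <- matrix(rnorm(30, sd = 25), 10, 3)
  # identity
  tf0 <- rigidProcrustes(fx, fx)
  expect_equal(rotation(tf0), diag(3), tolerance = 1e-10)
  expect_equal(translation(tf0), c(0, 0, 0), tolerance = 1e-10)
  # pure translation: moving = fixed + (5, 0, 0) is undone by (-5, 0, 0)
  tfT <- rigidProcrustes(sweep(fx, 2L, c(-5, 0, 0)), fx)
  expect_equal(translation(tfT), c(-5, 0, 0), tolerance = 1e-10)
  expect_lt(max(abs(applyRigid(tfT, sweep(fx, 2L, c(-5, 0, 0))) - fx)), 1e-10)
  # known rotation about z: residual at machine precision
  mv <- fx %*% t(rotZ(10))
  tfR <- rigidProcrustes(mv, fx)
  expect_lt(max(abs(rotation(tfR) %*% rotZ(10) - diag(3))), 1e-6)
  res <- applyRigid(tfR, mv) - fx
  expect_lt(max(abs(res)), 1e-9)
})

test_that("degenerate point sets are rejected", {
  fx <- matrix(rnorm(30), 10, 3)
  expect_error(rigidProcrustes(fx[1:2, ], fx[1:2, ]), "3 point")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(rigidProcrustes(line, line), "collinear")
})

test_that("marker distortion isolates deformation from rigid motion", {
  grid <- makeGridPhantom(voxelSize = c(2.5, 2.5, 2.5))
  ref <- grid$markers
  # detected = reference: zero everywhere
  rep0 <- markerDistortion(ref, ref)
  expect_equal(meanDistortion(rep0), 0, tolerance = 1e-12)
  expect_equal(maxDistortion(rep0), 0, tolerance = 1e-12)
  # one peripheral marker displaced 2 mm
  pos <- markerPositions(ref)
  pos[1L, 1L] <- pos[1L, 1L] + 2
  det <- new("MarkerSet", ids = markerIds(ref), gridIndex = gridIndex(ref),
             posMm = pos, score = rep(0.9, 125), missing = rep(FALSE, 125))
  rep1 <- markerDistortion(det, ref)
  expect_equal(maxDistortion(rep1), 2, tolerance = 1e-9)
  expect_equal(meanDistortion(rep1), 2 / 125, tolerance = 1e-9)
  # global rigid motion of the detected set changes nothing
  R <- rotZ(7); tvec <- c(4, -3, 2)
  posR <- sweep(pos %*% t(R), 2L, tvec, "+")
  detR <- new("MarkerSet", ids = markerIds(ref), gridIndex = gridIndex(ref),
              posMm = posR, score = rep(0.9, 125), missing = rep(FALSE, 125))
  repR <- markerDistortion(detR, ref)
  expect_equal(perMarkerTable(repR)$distance_mm,
               perMarkerTable(rep1)$distance_mm, tolerance = 1e-6)
})

test_that("central selection requires an odd lattice", {
  gi <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  mk <- new("MarkerSet", ids = sprintf("m%d", seq_len(nrow(gi))),
            gridIndex = unname(gi), posMm = unname(gi) * 25,
            score = rep(NA_real_, nrow(gi)), missing = rep(FALSE, nrow(gi)))
  expect_error(centralMarkers(mk), "even lattice")
})

test_that("scenario summaries average means and maxima arithmetically", {
  mkRep <- function(mean_, max_) {
    new("DistortionReport",
        perMarker = data.frame(id = "m", distance_mm = max_),
        meanMm = mean_, maxMm = max_, nDetected = 1L, nReference = 1L,
        transform = new("RigidTransform", rotation = diag(3),
                        translation = c(0, 0, 0)))
  }
  expect_equal(scenarioSummary(list(mkRep(0.4, 1)))[["mean_mm"]], 0.4)
  s <- scenarioSummary(list(mkRep(0.4, 1), mkRep(0.6, 2), mkRep(0.5, 3)))
  expect_equal(s[["mean_mm"]], 0.5)
  expect_equal(s[["max_mm"]], 2)
  expect_error(scenarioSummary(list()), "at least one")
})

test_that("manufacturing QC resolves sub-0.1 mm accuracy at CT resolution", {
  vox <- c(0.78, 0.78, 0.6)
  grid <- makeGridPhantom(voxelSize = vox, marginMm = 12)
  qc <- gridManufacturingQC(grid$image, grid$affine, grid$markers)
  expect_equal(qc@nDetected, 125L)
  expect_lt(meanDistortion(qc), 0.1)
})

test_that("manufacturing QC recovers a known 0.3 mm marker jitter", {
  # stamp cross shapes at jittered lattice positions: each marker is
  # displaced by exactly 0.3 mm in a random direction
  vox <- c(0.78, 0.78, 0.6)
  grid <- makeGridPhantom(voxelSize = vox, marginMm = 12)
  ref <- grid$markers
  set.seed(53)
  dir_ <- matrix(rnorm(125 * 3), 125, 3)
  dir_ <- dir_ / sqrt(rowSums(dir_^2))
  jit <- 0.3 * dir_
  img <- array(0, dim(grid$image))
  affineInv <- solve(grid$affine)
  coords <- lapply(1:3, function(ax) (0:(dim(img)[ax] - 1L)) * vox[ax])
  pos <- markerPositions(ref) + jit
  for (m in seq_len(125)) {
    ctr <- pos[m, ]
    onB <- lapply(1:3, function(ax) abs(coords[[ax]] - ctr[ax]) <= 3)
    within <- lapply(1:3, function(ax) abs(coords[[ax]] - ctr[ax]) <= 9)
    for (a in 1:3) {
      axMask <- lapply(1:3, function(ax) if (ax == a) within[[ax]] else onB[[ax]])
      ii <- which(axMask[[1L]]); jj <- which(axMask[[2L]]); kk <- which(axMask[[3L]])
      img[ii, jj, kk] <- 1
    }
  }
  qc <- gridManufacturingQC(img, grid$affine, ref)
  expect_lt(abs(meanDistortion(qc) - 0.3) / 0.3, 0.3)
})
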