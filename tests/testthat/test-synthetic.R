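# Scene generators, signal model, Rician noise and EPI warping.

test_that("vial phantom carries the requested diffusion coefficients", {
  sc <- makeVialPhantom(c(32, 32, 10), c(3, 3, 6))
  tp <- tissueParams(sc)
  expect_equal(tp$D, c(400, 1000, 1600, 2020))
  expect_equal(sort(unique(as.vector(labelMap(sc)))), 0:4)
  # a zero-ADC vial decays nowhere
  sc0 <- makeVialPhantom(c(16, 16, 10), c(3, 3, 6), vialAdcs = 0)
  expect_equal(simulateSignal(sc0, 800), simulateSignal(sc0, 0))
})

test_that("rasterized vial volume matches the analytic cylinder volume", {
  vox <- c(3, 3, 6)
  sc <- makeVialPhantom(c(32, 32, 10), vox, vialAdcs = 1000,
                        vialRadiusMm = 12, vialHeightMm = 42)
  nvox <- sum(labelMap(sc) == 1L)
  analytic <- pi * 12^2 * 42 / prod(vox)
  expect_lt(abs(nvox - analytic) / analytic, 0.05)
})

test_that("vial geometry errors are caught", {
  expect_error(makeVialPhantom(c(10, 10, 10), c(3, 3, 6), vialAdcs = c(1, 2)),
               "overlap|fit")
  expect_error(makeVialPhantom(c(32, 32, 5), c(3, 3, 6), vialAdcs = 1000,
                               vialHeightMm = 48), "height")
})

test_that("grid phantom realizes the theoretical lattice", {
  grid <- makeGridPhantom(voxelSize = c(0.78, 0.78, 0.6))
  mk <- grid$markers
  gi <- gridIndex(mk)
  # five lines per axis, full 5^3 lattice
  expect_equal(apply(gi, 2, function(x) length(unique(x))), rep(5L, 3))
  expect_equal(length(markerIds(mk)), 125L)
  # world coordinates are exact multiples of 25 mm relative to the origin
  pos <- markerPositions(mk)
  rel <- sweep(pos, 2L, pos[1L, ])
  expect_equal(rel, gi * 25, tolerance = 1e-12, ignore_attr = TRUE)
  # nearest-neighbour distance is the spacing, exactly
  d01 <- sqrt(sum((pos[2L, ] - pos[1L, ])^2))
  expect_identical(d01, 25)
  # central block of the 5^3 lattice has 3^3 members
  expect_length(centralMarkers(mk), 27L)
  # lexicographic ordering by grid index
  expect_true(!is.unsorted(gi[, 1L]))
})

test_that("grid phantom rejects impossible geometries", {
  expect_error(makeGridPhantom(spacingMm = 5, beamThicknessMm = 6,
                               voxelSize = c(1, 1, 1)), "spacing")
  expect_error(makeGridPhantom(voxelSize = c(7, 7, 7)), "voxel")
  expect_error(makeGridPhantom(fovMm = c(30, 30, 30),
                               voxelSize = c(1, 1, 1)), "3 grid lines")
})

test_that("brain scene labels are mutually exclusive and parameterized", {
  sc <- makeBrainScene(c(40, 40, 18), c(3, 3, 6))
  lab <- labelMap(sc)
  expect_equal(sort(unique(as.vector(lab))), 0:3)
  tp <- tissueParams(sc)
  D <- c(3000, 900, 700)
  for (l in 1:3) expect_equal(tp$D[tp$label == l], D[l])
  expect_error(makeBrainScene(c(10, 10, 4), c(3, 3, 6)), "grid|room")
})

test_that("signal model matches its closed forms", {
  sc <- makeVialPhantom(c(16, 16, 10), c(3, 3, 6), vialAdcs = 1000)
  expect_equal(max(simulateSignal(sc, 800)), 1000 * exp(-0.8),
               tolerance = 1e-12)
  expect_equal(max(simulateSignal(sc, 0)), 1000)
  # bi-exponential IVIM compartment
  tp <- data.frame(label = 1L, S0 = 1000, D = 1000, f = 0.2, Dstar = 10000)
  sc2 <- newSceneForTest(tp)
  expect_equal(max(simulateSignal(sc2, 800)),
               1000 * (0.2 * exp(-8) + 0.8 * exp(-0.8)), tolerance = 1e-12)
  # CSF-like bi-exponential signal at b = 0 exceeds the mono-exponential
  # extrapolation from the b >= 200 points
  b <- c(200, 400, 600, 800)
  tpc <- data.frame(label = 1L, S0 = 1000, D = 3000, f = 0.3, Dstar = 10000)
  scc <- newSceneForTest(tpc)
  s <- vapply(b, function(bb) max(simulateSignal(scc, bb)), numeric(1))
  fit <- stats::lm(log(s) ~ b)
  extrap0 <- exp(stats::coef(fit)[[1L]])
  expect_gt(max(simulateSignal(scc, 0)), extrap0)
})

test_that("signal is monotone non-increasing in b everywhere", {
  set.seed(11)
  for (rep_ in 1:3) {
    tp <- data.frame(label = 1:2, S0 = runif(2, 500, 1500),
                     D = runif(2, 200, 3000), f = c(0, runif(1, 0, 0.5)),
                     Dstar = 12000)
    sc <- newSceneForTest(tp)
    b <- sort(runif(5, 0, 1000))
    prev <- simulateSignal(sc, 0)
    for (bb in b) {
      cur <- simulateSignal(sc, bb)
      expect_true(all(cur <= prev + 1e-12))
      prev <- cur
    }
  }
})

test_that("Rician background reproduces the Rayleigh moments", {
  x <- addRicianNoise(array(0, c(100, 100, 100)), sigma = 10, seed = 99)
  expect_lt(abs(mean(x) - 10 * sqrt(pi / 2)) / (10 * sqrt(pi / 2)), 0.01)
  expect_lt(abs(mean(x^2) - 200) / 200, 0.01)
})

test_that("Rician noise edge cases and determinism", {
  v <- array(runif(64), c(4, 4, 4))
  expect_identical(addRicianNoise(v, 0, seed = 1), v)
  expect_error(addRicianNoise(v, -1, seed = 1), "sigma")
  expect_error(addRicianNoise(v, 1), "seed")
  expect_identical(addRicianNoise(v, 5, seed = 7), addRicianNoise(v, 5, seed = 7))
})

test_that("EPI warp: identity, rigid shift, conservation, PE symmetry", {
  p <- testProtocol()
  img <- smoothBoxObject()
  zero <- array(0, dim(img))
  expect_equal(applyEpiWarp(img, zero, p), img)
  # uniform field of one bandwidth: exact one-pixel shift along PE
  f1 <- array(bwPePx(p), dim(img))
  w <- applyEpiWarp(img, f1, p, peSign = 1L)
  expect_equal(w[, 2:24, ], img[, 1:23, ], tolerance = 1e-12)
  # smooth field: every PE line integral conserved within 0.5%
  fm <- makeSusceptibilityField(dim(img), rep(2, 3), smoothScaleMm = 10,
                                amplitudeHz = 2 * bwPePx(p), seed = 5)
  ws <- applyEpiWarp(img, fm, p, peSign = 1L)
  sumsBefore <- apply(img, c(1, 3), sum)
  sumsAfter <- apply(ws, c(1, 3), sum)
  keep <- sumsBefore > 0.1 * max(sumsBefore)
  expect_lt(max(abs(sumsAfter[keep] - sumsBefore[keep]) / sumsBefore[keep]),
            0.005)
  # negating the field equals flipping the PE sign
  wNeg <- applyEpiWarp(img, -fieldValues(fm), p, peSign = 1L)
  wDown <- applyEpiWarp(img, fm, p, peSign = -1L)
  expect_lt(max(abs(wNeg - wDown)), 1e-6 * max(img))
})

test_that("susceptibility field generator is bounded and reproducible", {
  f0 <- makeSusceptibilityField(c(10, 10, 4), c(3, 3, 6), amplitudeHz = 0,
                                seed = 1)
  expect_true(all(fieldValues(f0) == 0))
  blob <- list(centerMm = c(15, 15, 12), sigmaMm = 8, amplitudeHz = 50)
  f1 <- makeSusceptibilityField(c(10, 10, 4), c(3, 3, 6), amplitudeHz = 100,
                                blobSpec = blob, seed = 2)
  expect_lte(max(abs(fieldValues(f1))), 150 + 1e-9)
  f2 <- makeSusceptibilityField(c(10, 10, 4), c(3, 3, 6), amplitudeHz = 100,
                                blobSpec = blob, seed = 2)
  expect_identical(fieldValues(f1), fieldValues(f2))
})

test_that("simulated acquisitions are bit-reproducible under a fixed seed", {
  s1 <- simulateVialPhantomStudy(seed = 5, gridShape = c(16L, 16L, 10L),
                                 vialAdcs = 1000)
  s2 <- simulateVialPhantomStudy(seed = 5, gridShape = c(16L, 16L, 10L),
                                 vialAdcs = 1000)
  expect_identical(seriesData(s1$dwi), seriesData(s2$dwi))
})
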