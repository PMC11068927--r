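# Background noise estimation, noise-floor correction and the ADC fit.

test_that("background noise estimate is the second moment of the cuboid", {
  x <- array(5, c(10, 10, 10, 3))
  est <- estimateBackgroundNoise(x, c(0, 0, 0), c(5, 5, 5))
  expect_equal(etaSq(est), 25)
  expect_equal(etaSq(estimateBackgroundNoise(x * 0, c(0, 0, 0), c(5, 5, 5))), 0)
  # Rayleigh background converges to 2 sigma^2
  bg <- addRicianNoise(array(0, c(50, 50, 50)), sigma = 10, seed = 3)
  est2 <- estimateBackgroundNoise(array(bg, c(50, 50, 50, 1)),
                                  c(0, 0, 0), c(50, 50, 40))
  expect_lt(abs(etaSq(est2) - 200) / 200, 0.02)
})

test_that("noise cuboid bounds and size are validated", {
  x <- array(1, c(10, 10, 10, 2))
  expect_error(estimateBackgroundNoise(x, c(8, 0, 0), c(5, 5, 5)), "outside")
  expect_warning(estimateBackgroundNoise(x, c(0, 0, 0), c(4, 4, 4)),
                 "fewer than 100")
})

test_that("noise-floor correction applies the power subtraction rule", {
  r <- correctNoiseFloor(100, 400)
  expect_equal(r$corrected, sqrt(9600))
  expect_false(r$flagged)
  # identity with a zero noise floor
  v <- array(runif(27, 0, 10), c(3, 3, 3))
  expect_identical(correctNoiseFloor(v, 0)$corrected, v)
  # at or below the floor: zeroed and flagged
  r2 <- correctNoiseFloor(c(10, 30), 400)
  expect_equal(r2$corrected[1L], 0)
  expect_true(r2$flagged[1L])
  expect_false(r2$flagged[2L])
})

test_that("two-point ADC fits match their closed forms", {
  # noise-free: ADC = ln(1000/449.33)/ (800e-6) = 1000
  dwi <- seriesFromSignal(c(1000, 1000 * exp(-0.8)), c(0, 800))
  m <- fitADC(dwi)
  expect_equal(adcValues(m)[1L], 1000, tolerance = 1e-9)
  expect_equal(s0Values(m)[1L], 1000, tolerance = 1e-9)
  # with a 400 a.u.^2 noise floor: corrected {sqrt(9600), sqrt(2100)}
  dwi2 <- seriesFromSignal(c(100, 50), c(0, 800))
  noise <- new("NoiseEstimate", etaSq = 400, nVoxels = 1000L,
               cuboid = list(start = c(0L, 0L, 0L), size = c(10L, 10L, 10L)))
  m2 <- fitADC(dwi2, noise = noise)
  expected <- log(sqrt(9600) / sqrt(2100)) / 800e-6
  expect_equal(adcValues(m2)[1L], expected, tolerance = 1e-12)
  # constant signal: zero ADC
  m3 <- fitADC(seriesFromSignal(c(500, 500, 500), c(0, 400, 800)))
  expect_equal(adcValues(m3)[1L], 0, tolerance = 1e-12)
})

test_that("noise-free mono-exponential data is recovered exactly", {
  set.seed(21)
  b <- c(0, 200, 400, 600, 800)
  for (rep_ in 1:5) {
    D <- runif(1, 100, 3000)
    S0 <- runif(1, 200, 2000)
    s <- S0 * exp(-b * D * 1e-6)
    dwi <- seriesFromSignal(s, b)
    for (sub in list(b, c(0, 800), c(0, 400, 800))) {
      m <- fitADC(dwi, bSubset = sub)
      expect_equal(adcValues(m)[1L], D, tolerance = 1e-9)
    }
  }
})

test_that("replicate volumes at the same b are averaged after correction", {
  # two replicates at each b, one biased high and one low around the truth
  b <- c(0, 800, 0, 800)
  s <- c(1010, 1000 * exp(-0.8) + 5, 990, 1000 * exp(-0.8) - 5)
  dwi <- seriesFromSignal(s, b, peSigns = c(1L, 1L, -1L, -1L))
  m <- fitADC(dwi)
  expect_equal(adcValues(m)[1L], log(1000 / (1000 * exp(-0.8))) / 800e-6,
               tolerance = 1e-9)
})

test_that("fit validates its b-value subset", {
  dwi <- seriesFromSignal(c(1000, 500), c(0, 800))
  expect_error(fitADC(dwi, bSubset = c(200, 800)), "subset|b = 0")
  expect_error(fitADC(dwi, bSubset = 800), "b = 0")
})

test_that("noise-floor correction reduces ADC bias at low SNR", {
  # CSF-like diffusivity at SNR(b=0) = 20: the b = 800 signal sits close
  # to the noise floor, the regime the correction is designed for;
  # >= 1000 voxels, paired with/without correction on identical data
  p <- mrLinacProtocol()
  sc <- makeVialPhantom(c(24L, 24L, 10L), voxelSize(p), vialAdcs = 3000,
                        vialRadiusMm = 20, vialHeightMm = 60)
  dwi <- simulateAcquisition(sc, p, seed = 17, sigma = 1000 / 20)
  noise <- estimateBackgroundNoise(dwi, c(0L, 0L, 0L), c(5L, 5L, 10L))
  vial <- labelMap(sc) == 1L
  expect_gte(sum(vial), 1000)
  mC <- fitADC(dwi, noise = noise)
  mU <- fitADC(dwi, noise = NULL)
  vC <- vial & validMask(mC)
  vU <- vial & validMask(mU)
  biasC <- abs(mean(adcValues(mC)[vC]) - 3000)
  biasU <- abs(mean(adcValues(mU)[vU]) - 3000)
  expect_lt(biasC, biasU)
})

test_that("ADC from all b-values agrees with the two-point subset at SNR 40", {
  p <- mrLinacProtocol()
  sc <- makeVialPhantom(c(24L, 24L, 10L), voxelSize(p), vialAdcs = 1000,
                        vialRadiusMm = 20, vialHeightMm = 60)
  dwi <- simulateAcquisition(sc, p, seed = 23, sigma = 1000 / 40)
  noise <- estimateBackgroundNoise(dwi, c(0L, 0L, 0L), c(5L, 5L, 10L))
  vial <- labelMap(sc) == 1L
  mAll <- fitADC(dwi, noise = noise)
  mTwo <- fitADC(dwi, bSubset = c(0, 800), noise = noise)
  mA <- mean(adcValues(mAll)[vial & validMask(mAll)])
  mT <- mean(adcValues(mTwo)[vial & validMask(mTwo)])
  expect_lt(abs(mA - mT) / 1000, 0.01)
})

test_that("IVIM-like bi-exponential decay inflates the all-b fit", {
  # noiseless fits per voxel would order the other way; at realistic low
  # SNR the noise floor flags high-b CSF points, which both inflates the
  # all-b fit and restricts the two-point fit to higher-signal voxels
  p <- mrLinacProtocol()
  tp <- data.frame(label = 1L, S0 = 1000, D = 3000, f = 0.3, Dstar = 10000)
  lab <- array(0L, c(24L, 24L, 8L))
  lab[5:20, 5:20, 3:6] <- 1L
  sc <- new("Scene", labelMap = lab, tissueParams = tp,
            affine = diagAffine(voxelSize(p)), meta = list())
  dwi <- simulateAcquisition(sc, p, seed = 29, sigma = 1000 / 20)
  noise <- estimateBackgroundNoise(dwi, c(0L, 0L, 0L), c(4L, 4L, 8L))
  csf <- lab == 1L
  mAll <- fitADC(dwi, noise = noise)
  mTwo <- fitADC(dwi, bSubset = c(0, 800), noise = noise)
  expect_gt(mean(adcValues(mAll)[csf & validMask(mAll)]),
            mean(adcValues(mTwo)[csf & validMask(mTwo)]))
})

test_that("reference ADC temperature correction interpolates linearly", {
  tab <- data.frame(vial = c("v1", "v1"), temp_c = c(15, 25),
                    adc = c(800, 1200))
  expect_equal(temperatureCorrectReference("v1", 19.5, tab), 980)
  tab20 <- data.frame(vial = "v1", temp_c = 20, adc = 1000)
  expect_equal(temperatureCorrectReference("v1", 20, tab20), 1000)
  expect_error(temperatureCorrectReference("v1", 30, tab), "range")
  expect_error(temperatureCorrectReference("v2", 20, tab), "not found")
})
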