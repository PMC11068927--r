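# End-to-end workflows on simulated studies.

test_that("noise-free vial workflow reproduces the references exactly", {
  sim <- simulateVialPhantomStudy(seed = 1, snr = Inf, fieldAmplitudeHz = 0)
  rep <- runPhantom1Workflow(sim$dwi, sim$voiMasks, sim$noiseCuboid$start,
                             sim$noiseCuboid$size,
                             referenceAdcs = sim$trueAdcs)
  expect_equal(nrow(rep$table), 4L * 2L)  # vials x methods
  expect_equal(rep$table$rel_diff_mean, rep(0, 8), tolerance = 1e-9)
  expect_equal(rep$table$rel_diff_median, rep(0, 8), tolerance = 1e-9)
  expect_equal(etaSq(rep$noise), 0)
})

test_that("vial workflow applies temperature-corrected references", {
  sim <- simulateVialPhantomStudy(seed = 1, snr = Inf, fieldAmplitudeHz = 0)
  # calibration: at 19.5 C the true values; at 25 C inflated by 20%
  tab <- do.call(rbind, lapply(1:4, function(v) {
    data.frame(vial = paste0("vial", v), temp_c = c(19.5, 25),
               adc = sim$trueAdcs[v] * c(1, 1.2))
  }))
  rep <- runPhantom1Workflow(sim$dwi, sim$voiMasks, sim$noiseCuboid$start,
                             sim$noiseCuboid$size,
                             calibrationTable = tab, temperatureC = 19.5)
  expect_equal(unique(rep$table$reference[rep$table$method == "ADCall"]),
               sim$trueAdcs, tolerance = 1e-12)
  expect_error(runPhantom1Workflow(sim$dwi, sim$voiMasks,
                                   sim$noiseCuboid$start,
                                   sim$noiseCuboid$size,
                                   calibrationTable = tab), "temperatureC")
})

test_that("undistorted grid pair yields distortions at the detection floor", {
  sim <- simulateGridStudy(seed = 2, dMaxMm = 0)
  wf <- runPhantom2Workflow(sim$imgUp, sim$imgDown, sim$affine,
                            sim$protocol, sim$markers)
  expect_equal(nrow(wf$table), 6L)  # mean/max x up/down/corrected
  means <- vapply(wf$reports, meanDistortion, numeric(1))
  expect_true(all(means < 0.2))
})

test_that("distortion correction beats both uncorrected images", {
  sim <- simulateGridStudy(seed = 3, dMaxMm = 2)
  wf <- runPhantom2Workflow(sim$imgUp, sim$imgDown, sim$affine,
                            sim$protocol, sim$markers)
  corr <- meanDistortion(wf$reports$corrected)
  expect_lte(corr, min(meanDistortion(wf$reports$up),
                       meanDistortion(wf$reports$down)))
})

test_that("mono-exponential brain: b-subset choice barely matters", {
  sim <- simulateBrainStudy(seed = 7, snr = 40, csfF = 0)
  wf <- runBrainWorkflow(sim$dwi, sim$labels, sim$noiseCuboid$start,
                         sim$noiseCuboid$size,
                         tissueNames = c("CSF", "GM", "WM"))
  t <- wf$table
  for (v in unique(t$voi)) {
    a <- t$mean[t$voi == v & t$method == "ADCall"]
    b <- t$mean[t$voi == v & t$method == "ADC0_800"]
    expect_lt(abs(a - b) / a, 0.01)
  }
})

test_that("field metrics scale linearly with the field amplitude", {
  sim <- simulateBrainStudy(seed = 8)
  wf1 <- runBrainWorkflow(sim$dwi, sim$labels, sim$noiseCuboid$start,
                          sim$noiseCuboid$size, fieldHz = sim$fieldHz)
  wf3 <- runBrainWorkflow(sim$dwi, sim$labels, sim$noiseCuboid$start,
                          sim$noiseCuboid$size,
                          fieldHz = fieldValues(sim$fieldHz) * 3)
  expect_equal(wf3$fieldMetrics, 3 * wf1$fieldMetrics)
  expect_true(all(c("p95_hz", "p95_ppm", "p95_mm") %in%
                  names(wf1$fieldMetrics)))
})

test_that("workflow reruns are byte-identical and reports are written", {
  dir <- withr::local_tempdir()
  run <- function() {
    sim <- simulateVialPhantomStudy(seed = 11, gridShape = c(16L, 16L, 10L),
                                    vialAdcs = 1000)
    runPhantom1Workflow(sim$dwi, sim$voiMasks, sim$noiseCuboid$start,
                        sim$noiseCuboid$size, referenceAdcs = 1000)$table
  }
  t1 <- run(); t2 <- run()
  expect_identical(t1, t2)
  paths <- writeReport(t1, dir, "phantom1",
                       metrics = c(max_rel_diff = max(abs(t1$rel_diff_mean))),
                       manifest = list(seed = 11))
  expect_true(all(file.exists(paths)))
  back <- utils::read.delim(paths[1L])
  expect_equal(back$mean, t1$mean, tolerance = 1e-9)
})
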