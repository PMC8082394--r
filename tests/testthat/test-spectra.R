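renderedLine <- function(shift = 175, lwHz = 4, amp = 1, B0T = 11.7,
                         points = 2048L, centerPpm = 175) {
  scheme <- AcquisitionScheme(nTimepoints = 2, spectralPoints = points,
                              bandwidthPpm = 20, centerPpm = centerPpm,
                              B0T = B0T)
  res <- list(dGL = Resonance("dGL", shift, lwHz, 31.7, 90))
  model <- KineticModel(0, 0, 0, M0 = amp, deltaGammaRatio0 = 1)
  sim <- simulatePoolDynamics(model, scheme, res)
  list(spectrum = spectrumAt(
         renderSpectrumSeries(sim, scheme, res, NoiseSpec(0)), 1),
       scheme = scheme, amp = amp)
}

test_that("apodization with lb = 0 is the identity", {
  fx <- cellFixture(nT = 5)
  expect_identical(apodize(fx$series, 0)@spectra, fx$series@spectra)
  expect_error(apodize(fx$series, -1), "non-negative")
})

test_that("5 Hz line broadening adds 5 Hz to a Lorentzian FWHM and preserves areas", {
  rl <- renderedLine(lwHz = 4)
  ap <- apodize(rl$spectrum, 5)
  measureFWHM <- function(sp) {
    y <- Re(spectrumValues(sp)); x <- axisPpm(sp)
    hm <- max(y) / 2
    above <- which(y > hm)
    lo <- min(above); hi <- max(above)
    f1 <- x[lo - 1] + (x[lo] - x[lo - 1]) * (hm - y[lo - 1]) / (y[lo] - y[lo - 1])
    f2 <- x[hi] + (x[hi + 1] - x[hi]) * (hm - y[hi]) / (y[hi + 1] - y[hi])
    abs(f1 - f2) * rl$scheme@refFreqMHz
  }
  expect_equal(measureFWHM(ap), 9, tolerance = 0.02)
  # peak area (window spanning the whole axis interior) preserved
  w <- PeakWindow("dGL", 175, 9.9)
  expect_equal(integratePeak(ap, w), integratePeak(rl$spectrum, w),
               tolerance = 1e-3)
})

test_that("peak integration matches the analytic Lorentzian coverage", {
  rl <- renderedLine(lwHz = 4, amp = 2.5)
  fwhmPpm <- 4 / rl$scheme@refFreqMHz
  # analytic CDF of a Lorentzian: coverage of +/- m FWHM is (2/pi) atan(2m)
  for (m in c(5, 10)) {
    got <- integratePeak(rl$spectrum, PeakWindow("dGL", 175, m * fwhmPpm))
    expect_equal(got / rl$amp, (2 / pi) * atan(2 * m), tolerance = 1e-2)
  }
  # a +/- 10 FWHM window recovers ~97% of the area (tail truncation)
  got10 <- integratePeak(rl$spectrum, PeakWindow("dGL", 175, 10 * fwhmPpm))
  expect_gt(got10 / rl$amp, 0.96)
  expect_lt(got10 / rl$amp, 1.0)
})

test_that("peak integration is linear and additive over disjoint windows", {
  fx <- cellFixture(nT = 3, spectralPoints = 1024L)
  sp <- spectrumAt(fx$series, 3)
  w <- fx$windows[["dGL"]]
  spScaled <- Spectrum(3 * spectrumValues(sp), axisPpm(sp), sp@meta)
  expect_equal(integratePeak(spScaled, w), 3 * integratePeak(sp, w))
  # split in the flat tail region, away from the narrow peak apex
  wl <- PeakWindow("left", 173.65, 0.35)    # [173.3, 174.0]
  wr <- PeakWindow("right", 174.16, 0.14)   # [174.02, 174.3]
  whole <- PeakWindow("dGL", 173.8, 0.5)
  expect_equal(integratePeak(sp, wl) + integratePeak(sp, wr),
               integratePeak(sp, whole), tolerance = 0.02)
  expect_equal(integratePeak(Spectrum(complex(1024), axisPpm(sp), sp@meta), w), 0)
  expect_error(integratePeak(sp, PeakWindow("x", 140, 0.5)), "outside")
})

test_that("three noiseless lines are detected at their published shifts", {
  scheme <- AcquisitionScheme(nTimepoints = 2, spectralPoints = 2048L,
                              bandwidthPpm = 20, centerPpm = 175, B0T = 3)
  res <- gluconolactoneResonances("invivo")
  model <- KineticModel(kPGLSPerS = 0.02, bolusDurationS = 15)
  sim <- simulatePoolDynamics(model, scheme, res)
  series <- renderSpectrumSeries(sim, scheme, res, NoiseSpec(0))
  summed <- Spectrum(colSums(series@spectra), axisPpm(series), series@meta)
  pk <- detectPeaks(summed, absoluteThreshold = max(Re(summed@values)) / 100)
  expect_equal(nrow(pk), 3)
  # sorted downfield -> upfield
  expect_equal(pk$shiftPpm, c(178.6, 177.0, 173.8), tolerance = 0.02)
  # gamma / 6PG separation of 1.6 ppm
  expect_equal(pk$shiftPpm[1] - pk$shiftPpm[2], 1.6, tolerance = 0.04)
})

test_that("peak detection is translation-covariant", {
  delta <- 0.8
  base <- renderedLine(shift = 174, lwHz = 8, B0T = 3, points = 2048L)
  shifted <- renderedLine(shift = 174 + delta, lwHz = 8, B0T = 3, points = 2048L)
  p1 <- detectPeaks(base$spectrum, absoluteThreshold = 0.01)
  p2 <- detectPeaks(shifted$spectrum, absoluteThreshold = 0.01)
  expect_equal(nrow(p1), 1)
  expect_equal(p2$shiftPpm - p1$shiftPpm, delta, tolerance = 0.02)
})

test_that("pure noise yields no 5-sigma detections in almost all seeds", {
  scheme <- AcquisitionScheme(nTimepoints = 2, spectralPoints = 1024L, B0T = 3)
  axis <- axisPpm(spectrumAt(cellFixture(nT = 2, spectralPoints = 1024L)$series, 1))
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    sp <- Spectrum(complex(real = rnorm(1024), imaginary = rnorm(1024)),
                   axis, list(refFreqMHz = 32))
    if (nrow(detectPeaks(sp, sigma = 1, snrThreshold = 5)) > 0) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})

test_that("noiseless-detection guard requires an absolute threshold", {
  rl <- renderedLine()
  expect_error(detectPeaks(rl$spectrum, sigma = 0), "absolute")
})

test_that("noise estimation recovers the generating sigma", {
  fx <- cellFixture(nT = 2, spectralPoints = 2048L, sigma = 1, seed = 11)
  sp <- spectrumAt(fx$series, 1)
  est <- estimateNoise(sp, ppmRange = c(166.2, 167.5))
  expect_gt(est$sigma, 0.85)
  expect_lt(est$sigma, 1.15)
  clean <- spectrumAt(cellFixture(nT = 2, spectralPoints = 2048L)$series, 1)
  # noiseless input: only faint line-tail residue remains in the region
  expect_lt(estimateNoise(clean, ppmRange = c(166.2, 167.5))$sigma, 1e-4)
  expect_warning(estimateNoise(sp, ppmRange = c(173, 174),
                               resonances = fx$resonances), "overlaps")
})

test_that("noise estimated outside the brain agrees with a signal-free ppm range", {
  fx <- epsiFixture(nT = 15, sigma = 0.5, seed = 3)
  ds <- fx$dataset
  fromVoxel <- estimateNoise(ds, voxel = c(1, 1))$sigma
  ser <- voxelSeries(ds, 4, 4)
  fromRange <- estimateNoise(ser, ppmRange = c(166.5, 168.5))$sigma
  expect_equal(fromVoxel, 0.5, tolerance = 0.1)
  expect_lt(abs(fromVoxel - fromRange) / fromVoxel, 0.2)
  expect_error(estimateNoise(ds, voxel = c(4, 4)), "outside")
})

test_that("SNR is height over sigma and scales with the signal", {
  rl <- renderedLine(B0T = 3, lwHz = 8)
  w <- PeakWindow("dGL", 175, 0.5)
  h <- peakHeight(rl$spectrum, w)
  expect_equal(peakSNR(rl$spectrum, w, h / 5), 5)
  doubled <- Spectrum(2 * rl$spectrum@values, rl$spectrum@axisPpm,
                      rl$spectrum@meta)
  expect_equal(peakSNR(doubled, w, 2), 2 * peakSNR(rl$spectrum, w, 2))
  expect_error(peakSNR(rl$spectrum, w, 0), "sigma")
})

test_that("the peak table has one row per timepoint and metabolite", {
  fx <- cellFixture(nT = 4, spectralPoints = 256L)
  tb <- peakTimecourse(fx$series, fx$windows, sigma = 0.01)
  expect_equal(nrow(tb), 4 * 3)
  expect_named(tb, c("time_s", "metabolite", "area", "height", "snr"))
  expect_true(all(tb$snr == tb$height / 0.01))
  path <- tempfile(fileext = ".csv")
  writePeakTable(tb, path)
  expect_equal(read.csv(path)$area, tb$area)
})
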