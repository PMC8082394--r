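test_that("single-pool trajectories match the closed-form RF-sampled decay", {
  grid <- expand.grid(T1 = c(15.7, 31.7), theta = c(3.4, 10, 13), M0 = c(1, 2.5))
  for (j in seq_len(nrow(grid))) {
    fx <- soloDecayFixture(T1 = grid$T1[j], thetaDeg = grid$theta[j],
                           M0 = grid$M0[j], nT = 25)
    sim <- simulatePoolDynamics(fx$model, fx$scheme, fx$resonances)
    expected <- closedFormAmplitudes(grid$M0[j], grid$theta[j], 3,
                                     grid$T1[j], 25)
    expect_lt(max(abs(sim$amplitudes[, "dGL"] - expected) / expected), 1e-6)
  }
})

test_that("no conversion means no 6PG at any timepoint", {
  fx <- cellFixture(k = 0)
  expect_true(all(fx$sim$amplitudes[, "6PG"] == 0))
})

test_that("the in vivo acquisition uses the published per-metabolite flip angles", {
  res <- gluconolactoneResonances("invivo")
  expect_equal(res$dGL@flipAngleDeg, 3.4)
  expect_equal(res$gGL@flipAngleDeg, 12)
  expect_equal(res$`6PG`@flipAngleDeg, 15.3)
  expect_equal(res$dGL@shiftPpm, 173.8)
  expect_equal(res$gGL@shiftPpm, 177)
  expect_equal(res$`6PG`@shiftPpm, 178.6)
})

test_that("exchange and conversion only redistribute magnetization when decay and RF are off", {
  scheme <- AcquisitionScheme(TRs = 3, nTimepoints = 30, B0T = 11.7)
  bigT1 <- 1e12
  res <- list(
    dGL = Resonance("dGL", 173.8, 4, bigT1, 1e-7),
    gGL = Resonance("gGL", 177.0, 4, bigT1, 1e-7),
    `6PG` = Resonance("6PG", 178.6, 4, bigT1, 1e-7)
  )
  model <- KineticModel(kPGLSPerS = 0.02, kDGPerS = 0.01, kGDPerS = 0.008,
                        M0 = 1, deltaGammaRatio0 = 0.6)
  sim <- simulatePoolDynamics(model, scheme, res)
  totals <- rowSums(sim$M)
  expect_lt(max(abs(totals - 1)), 1e-9)
})

test_that("noiseless 6PG AUC is nondecreasing in the conversion rate", {
  ks <- seq(0, 0.05, length.out = 10)
  aucs <- vapply(ks, function(k) {
    fx <- cellFixture(k = k, nT = 50, spectralPoints = 256L)
    tc <- areaTimecourse(fx$series, fx$windows)
    sum(diff(tc$times) * (head(tc$areas[, "6PG"], -1) +
                          tail(tc$areas[, "6PG"], -1)) / 2)
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
  # at k = 0 only Lorentzian-tail cross-talk from the nearby gamma line
  # remains in the 6PG window; conversion dominates it several-fold
  expect_gt(aucs[10], 5 * aucs[1])
})

test_that("no magnetization is created after the bolus ends", {
  scheme <- AcquisitionScheme(TRs = 3, nTimepoints = 40, B0T = 3)
  res <- gluconolactoneResonances("invivo")
  model <- KineticModel(kPGLSPerS = 0.005, bolusStartS = 0,
                        bolusDurationS = 15, bolusTauS = 2)
  sim <- simulatePoolDynamics(model, scheme, res)
  totals <- rowSums(sim$M)
  after <- which(sim$times > 15 + 4 * 2)
  # pre-pulse totals can only shrink once input has stopped
  expect_true(all(diff(totals[after]) < 0))
  expect_true(all(sim$M >= 0))
})

test_that("rendered spectra integrate to the sampled amplitudes", {
  fx <- soloDecayFixture(nT = 5, B0T = 11.7)
  fx$scheme@spectralPoints <- 1024L
  sim <- simulatePoolDynamics(fx$model, fx$scheme, fx$resonances)
  series <- renderSpectrumSeries(sim, fx$scheme, fx$resonances, NoiseSpec(0))
  w <- PeakWindow("dGL", 173.8, 2)
  for (i in c(1, 3, 5)) {
    a <- integratePeak(spectrumAt(series, i), w)
    expect_equal(a, unname(sim$amplitudes[i, "dGL"]), tolerance = 0.01)
  }
})

test_that("zero amplitudes and zero noise render a zero spectrum", {
  fx <- soloDecayFixture()
  fx$model@M0 <- 0
  sim <- simulatePoolDynamics(fx$model, fx$scheme, fx$resonances)
  series <- renderSpectrumSeries(sim, fx$scheme, fx$resonances, NoiseSpec(0))
  expect_true(all(series@spectra == 0))
})

test_that("rendering is bit-identical for a fixed seed and differs across seeds", {
  fx <- soloDecayFixture(nT = 6)
  sim <- simulatePoolDynamics(fx$model, fx$scheme, fx$resonances)
  s1 <- renderSpectrumSeries(sim, fx$scheme, fx$resonances, NoiseSpec(0.1, 42))
  s2 <- renderSpectrumSeries(sim, fx$scheme, fx$resonances, NoiseSpec(0.1, 42))
  s3 <- renderSpectrumSeries(sim, fx$scheme, fx$resonances, NoiseSpec(0.1, 43))
  expect_identical(s1@spectra, s2@spectra)
  expect_false(identical(s1@spectra, s3@spectra))
})

test_that("a resonance outside the axis is rejected by name", {
  fx <- soloDecayFixture()
  res <- list(dGL = Resonance("dGL", 150, 4, 31.7, 10))
  model <- fx$model
  sim <- simulatePoolDynamics(model, fx$scheme, res)
  expect_error(renderSpectrumSeries(sim, fx$scheme, res, NoiseSpec(0)), "dGL")
})

test_that("unknown pool names and invalid rates are rejected", {
  fx <- soloDecayFixture()
  badRes <- list(Resonance("lactate", 183, 4, 30, 10))
  expect_error(simulatePoolDynamics(fx$model, fx$scheme, badRes), "unknown pool")
  expect_error(KineticModel(kPGLSPerS = -0.01), "rates")
})

test_that("uniform phantoms give identical in-brain voxel spectra and outside voxels stay silent", {
  ph <- referencePhantom(kTumor = 0.005, kBackground = 0.005)
  scheme <- AcquisitionScheme(TRs = 3, nTimepoints = 10, spectralPoints = 128L,
                              B0T = 3, mode = "epsi_grid")
  res <- gluconolactoneResonances("invivo")
  model <- KineticModel(kPGLSPerS = 0.005, bolusDurationS = 15)
  ds <- simulateEPSIDataset(ph, model, scheme, res, NoiseSpec(0))
  inb <- which(!ph@outsideMask, arr.ind = TRUE)
  ref <- ds@spectra[, inb[1, 1], inb[1, 2], ]
  for (j in seq_len(nrow(inb)))
    expect_identical(ds@spectra[, inb[j, 1], inb[j, 2], ], ref)
  out <- which(ph@outsideMask, arr.ind = TRUE)
  expect_true(all(ds@spectra[, out[1, 1], out[1, 2], ] == 0))
})

test_that("tumor voxels produce strictly more 6PG than background in every brain voxel", {
  fx <- epsiFixture(nT = 20, sigma = 0)
  ds <- fx$dataset
  w <- fx$windows[["6PG"]]
  auc <- matrix(NA_real_, 8, 8)
  for (r in 1:8) for (cc in 1:8) {
    if (fx$phantom@outsideMask[r, cc]) next
    tc <- areaTimecourse(voxelSeries(ds, r, cc), list(w))
    auc[r, cc] <- sum(diff(tc$times) * (head(tc$areas[, 1], -1) +
                                        tail(tc$areas[, 1], -1)) / 2)
  }
  expect_gt(min(auc[fx$phantom@tumorMask]),
            max(auc[!fx$phantom@tumorMask & !fx$phantom@outsideMask]))
})

test_that("EPSI simulation rejects single-voxel schemes and shape mismatches", {
  fx <- epsiFixture(nT = 5, sigma = 0)
  svScheme <- AcquisitionScheme(mode = "single_voxel")
  expect_error(simulateEPSIDataset(fx$phantom, fx$model, svScheme,
                                   fx$resonances), "epsi_grid")
  expect_error(Phantom(c(8, 8), kMap = matrix(0, 4, 4),
                       deliveryMap = matrix(1, 8, 8),
                       tumorMask = matrix(FALSE, 8, 8),
                       outsideMask = matrix(FALSE, 8, 8)),
               "gridShape")
})

test_that("thermal spectrum amplitude follows the summed-average convention", {
  scheme <- AcquisitionScheme(nTimepoints = 2, spectralPoints = 512L, B0T = 11.7)
  res <- Resonance("dGL", 173.8, 4, 15.7, 90)
  PTh <- thermalPolarization(11.7)
  w <- PeakWindow("dGL", 173.8, 2)
  a16 <- integratePeak(renderThermalSpectrum(1, scheme, res, PTh, 16), w)
  a32 <- integratePeak(renderThermalSpectrum(1, scheme, res, PTh, 32), w)
  expect_equal(a32 / a16, 2, tolerance = 1e-9)
  zero <- renderThermalSpectrum(1, scheme, res, 0, 16)
  expect_true(all(zero@values == 0))
})
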