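test_that("Lanczos-2 resize maps 8x8 to 256x256 and keeps constants constant", {
  out <- lanczos2Resize(matrix(1, 8, 8))
  expect_equal(dim(out), c(256L, 256L))
  expect_lt(max(abs(out - 1)), 1e-9)
})

test_that("single-hot input equals the tensor product of 1-D kernel responses", {
  m <- matrix(0, 8, 8); m[3, 5] <- 1
  out <- lanczos2Resize(m, c(64, 64))
  er <- rep(0, 8); er[3] <- 1
  ec <- rep(0, 8); ec[5] <- 1
  oracle <- outer(oracleLanczos1D(er, 64), oracleLanczos1D(ec, 64))
  expect_lt(max(abs(out - oracle)), 1e-12)
})

test_that("Lanczos-2 resize agrees with the 1-D oracle row by row", {
  set.seed(4)
  v <- rnorm(8)
  expect_lt(max(abs(lanczos2Resize(matrix(v, 1, 8), c(1, 96)) -
                    oracleLanczos1D(v, 96))), 1e-12)
})

test_that("Lanczos-2 resize commutes with affine intensity maps", {
  set.seed(9)
  X <- matrix(rnorm(64), 8, 8)
  a <- 2.7; b <- -1.3
  expect_lt(max(abs(lanczos2Resize(a * X + b, c(64, 64)) -
                    (a * lanczos2Resize(X, c(64, 64)) + b))), 1e-9)
  expect_error(lanczos2Resize(matrix(c(NaN, 1:63), 8, 8)), "finite")
})

test_that("metabolite SNR grids are scale-invariant and near zero without signal", {
  fx <- epsiFixture(nT = 10, sigma = 0.5, seed = 21)
  ds <- fx$dataset
  g <- metaboliteSNRGrid(ds, fx$windows[["6PG"]], c(1, 1))
  dsScaled <- EPSIDataset(3 * ds@spectra, ds@axisPpm, ds@TRs, ds@t0s,
                          ds@geometry, ds@masks, ds@meta)
  gScaled <- metaboliteSNRGrid(dsScaled, fx$windows[["6PG"]], c(1, 1))
  expect_equal(gScaled$values, g$values, tolerance = 1e-12)
  expect_error(metaboliteSNRGrid(ds, fx$windows[["6PG"]], c(4, 4)), "outside")

  # noise-only datasets: the max-over-window statistic stays below 4 sigma
  hits <- 0L
  for (s in 1:30) {
    ph0 <- referencePhantom()
    ph0@deliveryMap[] <- 0
    scheme <- AcquisitionScheme(TRs = 3, nTimepoints = 8, spectralPoints = 128L,
                                B0T = 3, mode = "epsi_grid")
    ds0 <- simulateEPSIDataset(ph0, fx$model, scheme, fx$resonances,
                               NoiseSpec(1, 1000 + s))
    g0 <- metaboliteSNRGrid(ds0, fx$windows[["6PG"]], c(1, 1))
    if (any(abs(g0$values) >= 4)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("tumor voxels have higher 6PG SNR and ratio than contralateral across seeds", {
  for (s in 1:5) {
    fx <- epsiFixture(nT = 20, sigma = 0.002, seed = 100 + s)
    ds <- fx$dataset
    g6 <- metaboliteSNRGrid(ds, fx$windows[["6PG"]], c(1, 1))
    expect_gt(min(g6$values[ds@masks$tumor]),
              max(g6$values[ds@masks$contralateral]))
    m6 <- metaboliteSNRMap(ds, fx$windows[["6PG"]], c(1, 1), c(64, 64))
    mD <- metaboliteSNRMap(ds, fx$windows[["dGL"]], c(1, 1), c(64, 64))
    rmap <- ratioMap(m6, mD, snrFloor = 5)
    geom <- c(ds@geometry, list(gridShapeNative = c(8, 8)))
    rt <- roiQuantify(rmap, list(mask = ds@masks$tumor), geom)
    rc <- roiQuantify(rmap, list(mask = ds@masks$contralateral), geom)
    expect_gt(rt$mean, rc$mean)
  }
})

test_that("ratio maps mask the substrate floor and are rescale-invariant", {
  p <- matrix(10, 8, 8)
  s <- matrix(c(rep(2, 32), rep(20, 32)), 8, 8)
  rm_ <- ratioMap(p, s, snrFloor = 5)
  expect_true(all(is.nan(rm_@values[s < 5])))
  expect_equal(rm_@values[s >= 5], rep(0.5, 32))
  rm2 <- ratioMap(3 * p, 3 * s, snrFloor = 5 * 3)
  expect_equal(rm2@values[s >= 5], rm_@values[s >= 5])
  expect_true(all(is.nan(ratioMap(p, p * 0, 5)@values)))
  expect_equal(ratioMap(p, p, 5)@values, matrix(1, 8, 8))
  expect_error(ratioMap(p, matrix(1, 4, 4)), "shape")
})

test_that("ROI quantification reports volumes and statistics correctly", {
  geom <- list(voxelSizeMm = c(4.375, 4.375), sliceThicknessMm = 8,
               gridShapeNative = c(8, 8))
  u <- matrix(5, 8, 8)
  st <- roiQuantify(u, list(voxels = cbind(3, 4)), geom)
  expect_equal(st$mean, 5)
  expect_equal(st$sd, 0)
  expect_equal(st$roiVolumeMm3, 4.375 * 4.375 * 8, tolerance = 1e-9)  # 153.1 mm3
  # a 1.875 mm box on the interpolated map realises the 28.13 mm3 volume
  big <- matrix(2, 256, 256)
  stBox <- roiQuantify(big, list(boxMm = c(17.5, 17.5, 1.875)), geom)
  expect_equal(stBox$roiVolumeMm3, 28.125, tolerance = 1e-6)
  expect_equal(stBox$mean, 2)
  # ROI mean of a uniform map is invariant to interpolation
  stNative <- roiQuantify(matrix(2, 8, 8), list(voxels = cbind(4, 4)), geom)
  expect_equal(stBox$mean, stNative$mean)
  expect_error(roiQuantify(matrix(NaN, 8, 8), list(voxels = cbind(4, 4)), geom),
               "empty|masked")
})

test_that("tumor volume is the contoured area sum times slice thickness", {
  expect_equal(tumorVolume(c(0.1, 0.2), 0.1), 0.03)
  expect_equal(tumorVolume(2.8, 0.1), 0.28)
  expect_error(tumorVolume(numeric(), 0.1), "no contoured")
  expect_error(tumorVolume(c(0.1, -0.2), 0.1), "negative|>= 0")
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(slice_index = 1:3, area_cm2 = c(0.5, 0.9, 0.4)), path,
            row.names = FALSE)
  expect_equal(tumorVolumeFromCSV(path, 0.1), 0.18)
})

test_that("longitudinal tables track a treatment-induced drop in tumor ratio", {
  scheme <- AcquisitionScheme(TRs = 3, nTimepoints = 20, spectralPoints = 128L,
                              B0T = 3, mode = "epsi_grid")
  res <- gluconolactoneResonances("invivo")
  model <- KineticModel(kPGLSPerS = 0.005, bolusDurationS = 15)
  windows <- defaultWindows(res)
  for (s in 1:3) {
    mk <- function(kTum, seed) simulateEPSIDataset(
      referencePhantom(kTumor = kTum), model, scheme, res, NoiseSpec(0.002, seed))
    d0 <- mk(0.02, 300 + s)
    d4 <- mk(0.02 * 0.6, 400 + s)   # treated: tumor conversion reduced 40%
    tb <- longitudinalTable(list(`0` = d0, `4` = d4), windows, c(1, 1),
                            list(tumor = d0@masks$tumor,
                                 contralateral = d0@masks$contralateral))
    get <- function(day, region, metric)
      tb$mean[tb$day == day & tb$region == region & tb$metric == metric]
    expect_lt(get("4", "tumor", "ratioDGL"), get("0", "tumor", "ratioDGL"))
    expect_equal(get("4", "contralateral", "ratioDGL"),
                 get("0", "contralateral", "ratioDGL"), tolerance = 0.1)
  }
  # identical datasets give identical rows
  fx <- epsiFixture(nT = 8, sigma = 0.002, seed = 77)
  tbEq <- longitudinalTable(list(a = fx$dataset, b = fx$dataset), windows,
                            c(1, 1), list(tumor = fx$dataset@masks$tumor))
  expect_equal(tbEq$mean[tbEq$day == "a"], tbEq$mean[tbEq$day == "b"])
})
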