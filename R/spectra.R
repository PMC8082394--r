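#' @importFrom stats setNames fft nextn
NULL

# Apodize one complex spectrum (vector) given the Hz-per-point spacing.
# On the descending ppm axis the causal FID is recovered by the forward
# DFT; the line-broadening weight is applied over the causal time index and
# the spectrum rebuilt with the inverse DFT. The first FID point (total
# integral) is weighted by 1, so the spectrum sum is preserved exactly.
apodizeValues <- function(values, dfHz, lbHz) {
  n <- length(values)
  dt <- 1 / (n * dfHz)
  fid <- fft(values) / n
  w <- exp(-pi * lbHz * (0:(n - 1)) * dt)
  fft(fid * w, inverse = TRUE)
}

apodizeCheck <- function(x, lbHz) {
  stopIfNot(is.numeric(lbHz) && length(lbHz) == 1 && lbHz >= 0,
            "lbHz must be a single non-negative number")
  rf <- x@meta$refFreqMHz
  stopIfNot(!is.null(rf) && rf > 0,
            "apodize needs refFreqMHz in the object metadata to convert Hz to ppm")
  abs(diff(x@axisPpm[1:2])) * rf
}

#' @rdname apodize
setMethod("apodize", "Spectrum", function(x, lbHz = 5) {
  dfHz <- apodizeCheck(x, lbHz)
  if (lbHz == 0) return(x)
  initialize(x, values = apodizeValues(x@values, dfHz, lbHz))
})

#' @rdname apodize
setMethod("apodize", "DynamicSpectrumSeries", function(x, lbHz = 5) {
  dfHz <- apodizeCheck(x, lbHz)
  if (lbHz == 0) return(x)
  sp <- t(apply(x@spectra, 1, apodizeValues, dfHz = dfHz, lbHz = lbHz))
  initialize(x, spectra = sp)
})

#' Default integration windows for the gluconolactone / 6PG system
#'
#' Closed ppm windows of half-width `halfWidthPpm` centred on each
#' resonance. The default +/- 0.5 ppm keeps the gamma-gluconolactone and
#' 6PG windows (1.6 ppm apart) disjoint at in vivo linewidths.
#'
#' @param resonances list of [Resonance] (default: the in vivo set)
#' @param halfWidthPpm window half width in ppm
#' @return named list of [PeakWindow]
#' @export
defaultWindows <- function(resonances = gluconolactoneResonances("invivo"),
                           halfWidthPpm = 0.5) {
  setNames(
    lapply(resonances, function(r) PeakWindow(r@name, r@shiftPpm, halfWidthPpm)),
    vapply(resonances, slot, character(1), "name"))
}

windowPoints <- function(axis, window) {
  lo <- window@centerPpm - window@halfWidthPpm
  hi <- window@centerPpm + window@halfWidthPpm
  idx <- which(axis >= lo & axis <= hi)
  if (length(idx) < 2)
    stop(sprintf("window '%s' [%.2f, %.2f] ppm lies outside the spectral axis",
                 window@name, lo, hi), call. = FALSE)
  idx
}

#' Integrate the real part of a spectrum over a peak window
#'
#' Trapezoidal integral of the real (absorption) part over the closed ppm
#' window; linear in the spectrum amplitude.
#'
#' @param spectrum a [Spectrum]
#' @param window a [PeakWindow]
#' @return area in signal units times ppm
#' @export
integratePeak <- function(spectrum, window) {
  idx <- windowPoints(spectrum@axisPpm, window)
  trapz(spectrum@axisPpm[idx], Re(spectrum@values[idx]))
}

#' Peak height of the real part within a window
#'
#' @inheritParams integratePeak
#' @return maximum of the real part over the window
#' @export
peakHeight <- function(spectrum, window) {
  idx <- windowPoints(spectrum@axisPpm, window)
  max(Re(spectrum@values[idx]))
}

#' Detect peaks in a spectrum
#'
#' Finds local maxima of the real part above `snrThreshold * sigma` (or an
#' absolute height threshold) and refines each centre by three-point
#' parabolic interpolation on the ppm axis.
#'
#' @param spectrum a [Spectrum]
#' @param sigma noise standard deviation (from [estimateNoise()]); required
#'   unless `absoluteThreshold` is given
#' @param snrThreshold detection threshold as a multiple of `sigma`
#' @param absoluteThreshold absolute height threshold, overrides the
#'   SNR-relative mode
#' @return data.frame with `shiftPpm` and `height`, sorted downfield (high
#'   ppm) to upfield
#' @export
detectPeaks <- function(spectrum, sigma = NULL, snrThreshold = 5,
                        absoluteThreshold = NULL) {
  if (is.null(absoluteThreshold)) {
    if (is.null(sigma) || !isTRUE(sigma > 0))
      stop("sigma must be > 0 for SNR-relative detection; ",
           "use absoluteThreshold for noiseless spectra", call. = FALSE)
    stopIfNot(snrThreshold > 0, "snrThreshold must be > 0")
    thr <- snrThreshold * sigma
  } else {
    thr <- absoluteThreshold
  }
  y <- Re(spectrum@values)
  x <- spectrum@axisPpm
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[y[i] > thr]
  if (!length(i))
    return(data.frame(shiftPpm = numeric(), height = numeric()))
  refine <- function(j) {
    y0 <- y[j - 1]; y1 <- y[j]; y2 <- y[j + 1]
    denom <- y0 - 2 * y1 + y2
    d <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / denom
    d <- max(min(d, 0.5), -0.5)
    c(x[j] + d * (x[min(j + 1, n)] - x[j]),
      y1 - 0.25 * (y0 - y2) * d)
  }
  out <- t(vapply(i, refine, numeric(2)))
  out <- data.frame(shiftPpm = out[, 1], height = out[, 2])
  out[order(-out$shiftPpm), , drop = FALSE]
}

noiseRegionCheck <- function(ppmRange, resonances, guardPpm = 1) {
  if (is.null(resonances)) return(invisible(TRUE))
  lo <- min(ppmRange); hi <- max(ppmRange)
  for (r in resonances) {
    if (r@shiftPpm + guardPpm >= lo && r@shiftPpm - guardPpm <= hi)
      warning(sprintf("noise region [%.2f, %.2f] ppm overlaps the '%s' resonance window",
                      lo, hi, r@name), call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname estimateNoise
#' @param ppmRange length-2 numeric, signal-free ppm range
#' @param resonances optional list of [Resonance] used to warn when the
#'   region overlaps a declared line
setMethod("estimateNoise", "Spectrum", function(x, ppmRange, resonances = NULL, ...) {
  noiseRegionCheck(ppmRange, resonances)
  idx <- which(x@axisPpm >= min(ppmRange) & x@axisPpm <= max(ppmRange))
  stopIfNot(length(idx) >= 2, "ppmRange covers fewer than 2 points")
  list(sigma = sd(Re(x@values[idx])),
       source = sprintf("ppm range [%.2f, %.2f]", min(ppmRange), max(ppmRange)))
})

#' @rdname estimateNoise
setMethod("estimateNoise", "DynamicSpectrumSeries",
          function(x, ppmRange, resonances = NULL, ...) {
  noiseRegionCheck(ppmRange, resonances)
  idx <- which(x@axisPpm >= min(ppmRange) & x@axisPpm <= max(ppmRange))
  stopIfNot(length(idx) >= 2, "ppmRange covers fewer than 2 points")
  list(sigma = sd(Re(x@spectra[, idx])),
       source = sprintf("ppm range [%.2f, %.2f], all timepoints",
                        min(ppmRange), max(ppmRange)))
})

#' @rdname estimateNoise
#' @param voxel `c(row, col)` native-grid indices of a voxel under the
#'   outside mask
setMethod("estimateNoise", "EPSIDataset", function(x, voxel, ...) {
  outside <- x@masks$outside
  stopIfNot(!is.null(outside), "dataset has no 'outside' mask")
  if (!outside[voxel[1], voxel[2]])
    stop(sprintf("voxel (%d, %d) is not under the outside mask; noise must be estimated outside the brain",
                 voxel[1], voxel[2]), call. = FALSE)
  list(sigma = sd(Re(x@spectra[, voxel[1], voxel[2], ])),
       source = sprintf("outside voxel (%d, %d), all timepoints",
                        voxel[1], voxel[2]))
})

#' Signal-to-noise ratio of a peak
#'
#' Peak height of the real part within the window divided by the noise
#' standard deviation.
#'
#' @inheritParams integratePeak
#' @param sigma noise standard deviation (> 0)
#' @return unitless SNR
#' @export
peakSNR <- function(spectrum, window, sigma) {
  stopIfNot(isTRUE(sigma > 0), "sigma must be > 0")
  peakHeight(spectrum, window) / sigma
}

#' Tabulate per-timepoint peak areas, heights and SNR
#'
#' The flat quantification table of a dynamic series: one row per
#' (timepoint, metabolite), with the trapezoidal area, the peak height and
#' (when `sigma` is given) the SNR.
#'
#' @param series a [DynamicSpectrumSeries]
#' @param windows named list of [PeakWindow]
#' @param sigma optional noise standard deviation for the `snr` column
#' @return data.frame with columns `time_s`, `metabolite`, `area`, `height`,
#'   `snr`
#' @export
peakTimecourse <- function(series, windows, sigma = NULL) {
  times <- acquisitionTimes(series)
  rows <- lapply(seq_along(times), function(i) {
    sp <- spectrumAt(series, i)
    do.call(rbind, lapply(windows, function(w) {
      h <- peakHeight(sp, w)
      data.frame(time_s = times[i], metabolite = w@name,
                 area = integratePeak(sp, w), height = h,
                 snr = if (is.null(sigma)) NA_real_ else h / sigma)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wide per-metabolite area matrix of a dynamic series
#'
#' @inheritParams peakTimecourse
#' @return list with `times` (s) and `areas` (timepoints x metabolites)
#' @export
areaTimecourse <- function(series, windows) {
  times <- acquisitionTimes(series)
  areas <- vapply(windows, function(w)
    vapply(seq_along(times), function(i)
      integratePeak(spectrumAt(series, i), w), numeric(1)),
    numeric(length(times)))
  areas <- matrix(areas, nrow = length(times),
                  dimnames = list(NULL, vapply(windows, slot, character(1), "name")))
  list(times = times, areas = areas)
}
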