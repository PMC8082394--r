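#' Accessors for the spectral containers
#'
#' @name accessors
#' @return `axisPpm`: the ppm axis; `nTimepoints`: the number of dynamic
#'   acquisitions; `acquisitionTimes`: the sampling times in seconds;
#'   `spectrumValues`: the complex amplitudes.
NULL

#' @rdname accessors
setMethod("axisPpm", "Spectrum", function(x) x@axisPpm)
#' @rdname accessors
setMethod("axisPpm", "DynamicSpectrumSeries", function(x) x@axisPpm)
#' @rdname accessors
setMethod("axisPpm", "EPSIDataset", function(x) x@axisPpm)

#' @rdname accessors
setMethod("nTimepoints", "DynamicSpectrumSeries", function(x) nrow(x@spectra))
#' @rdname accessors
setMethod("nTimepoints", "EPSIDataset", function(x) dim(x@spectra)[1])

#' @rdname accessors
setMethod("acquisitionTimes", "DynamicSpectrumSeries", function(x)
  x@t0s + (seq_len(nrow(x@spectra)) - 1) * x@TRs)
#' @rdname accessors
setMethod("acquisitionTimes", "EPSIDataset", function(x)
  x@t0s + (seq_len(dim(x@spectra)[1]) - 1) * x@TRs)

#' @rdname accessors
setMethod("spectrumValues", "Spectrum", function(x) x@values)

setMethod("spectrumAt", "DynamicSpectrumSeries", function(x, i) {
  stopifnot(i >= 1, i <= nrow(x@spectra))
  Spectrum(x@spectra[i, ], x@axisPpm, x@meta)
})

setMethod("voxelSeries", "EPSIDataset", function(x, row, col) {
  d <- dim(x@spectra)
  stopifnot(row >= 1, row <= d[2], col >= 1, col <= d[3])
  DynamicSpectrumSeries(x@spectra[, row, col, , drop = TRUE],
                        x@axisPpm, x@TRs, x@t0s, x@meta)
})

setMethod("show", "Resonance", function(object) {
  cat(sprintf("Resonance '%s': %.1f ppm, FWHM %.1f Hz, T1 %.1f s, flip %.1f deg\n",
              object@name, object@shiftPpm, object@linewidthHz,
              object@T1s, object@flipAngleDeg))
})

setMethod("show", "AcquisitionScheme", function(object) {
  cat(sprintf("AcquisitionScheme (%s): TR %.1f s x %d, %d pts over %.1f ppm @ %.1f ppm, B0 %.1f T (%.2f MHz)\n",
              object@mode, object@TRs, object@nTimepoints,
              object@spectralPoints, object@bandwidthPpm, object@centerPpm,
              object@B0T, object@refFreqMHz))
})

setMethod("show", "KineticModel", function(object) {
  bolus <- if (object@bolusDurationS > 0)
    sprintf("bolus %.0f s from t=%.0f s (tau %.1f s)",
            object@bolusDurationS, object@bolusStartS, object@bolusTauS)
  else "pre-loaded at t=0"
  cat(sprintf("KineticModel: kPGLS %.4g /s, exchange %.4g/%.4g /s, M0 %.3g (delta fraction %.2f), %s\n",
              object@kPGLSPerS, object@kDGPerS, object@kGDPerS, object@M0,
              object@deltaGammaRatio0, bolus))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom %dx%d, voxel %.3f x %.3f x %.1f mm; tumor %d, outside %d voxels; k in [%.4g, %.4g] /s\n",
              object@gridShape[1], object@gridShape[2],
              object@voxelSizeMm[1], object@voxelSizeMm[2],
              object@sliceThicknessMm, sum(object@tumorMask),
              sum(object@outsideMask), min(object@kMap), max(object@kMap)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.2f to %.2f ppm\n",
              length(object@values), max(object@axisPpm), min(object@axisPpm)))
})

setMethod("show", "DynamicSpectrumSeries", function(object) {
  cat(sprintf("DynamicSpectrumSeries: %d timepoints (TR %.1f s, t0 %.1f s), %d points, %.2f to %.2f ppm\n",
              nrow(object@spectra), object@TRs, object@t0s,
              ncol(object@spectra), max(object@axisPpm), min(object@axisPpm)))
})

setMethod("show", "EPSIDataset", function(object) {
  d <- dim(object@spectra)
  cat(sprintf("EPSIDataset: %d x %d grid, %d timepoints (TR %.1f s), %d points; masks: %s\n",
              d[2], d[3], d[1], object@TRs, d[4],
              paste(names(object@masks), collapse = ", ")))
})

setMethod("show", "HeatMap", function(object) {
  cat(sprintf("HeatMap (%s): %d x %d, %s; %.0f%% valid\n",
              object@kind, nrow(object@values), ncol(object@values),
              paste(object@sourceMetabolites, collapse = "/"),
              100 * mean(is.finite(object@values))))
})
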