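#' @rdname accessors
#' @param x an object
#' @export
setGeneric("axisPpm", function(x) standardGeneric("axisPpm"))

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname accessors
#' @export
setGeneric("acquisitionTimes", function(x) standardGeneric("acquisitionTimes"))

#' @rdname accessors
#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))

#' Extract one timepoint of a dynamic series as a Spectrum
#' @param x a `DynamicSpectrumSeries`
#' @param i timepoint index
#' @export
setGeneric("spectrumAt", function(x, i) standardGeneric("spectrumAt"))

#' Extract the dynamic series of one voxel of an EPSI dataset
#' @param x an `EPSIDataset`
#' @param row,col native-grid voxel indices (1-based)
#' @export
setGeneric("voxelSeries", function(x, row, col) standardGeneric("voxelSeries"))

#' Apply exponential line broadening (apodization)
#'
#' Implemented as inverse transform to the time domain, multiplication by
#' `exp(-pi * lbHz * t)`, and forward transform back -- i.e. convolution of
#' the complex spectrum with a Lorentzian of FWHM `lbHz`. For Lorentzian
#' lines this adds exactly `lbHz` to the linewidth and preserves peak areas.
#' `lbHz = 0` is the identity.
#'
#' @param x a `Spectrum` or `DynamicSpectrumSeries` with `refFreqMHz` in its
#'   metadata
#' @param lbHz line broadening in Hz (default 5, the standard processing
#'   value for this acquisition)
#' @return an object of the same class as `x`
#' @export
setGeneric("apodize", function(x, lbHz = 5) standardGeneric("apodize"))

#' Estimate the noise standard deviation from a signal-free region
#'
#' The noise level is the sample standard deviation of the real part of the
#' signal in a region known to contain no resonances: either a ppm range far
#' from every line (spectra), or a voxel outside the brain (EPSI datasets).
#'
#' @param x a `Spectrum`, `DynamicSpectrumSeries` or `EPSIDataset`
#' @param ... `ppmRange` (length-2 numeric) for spectra; `voxel = c(row, col)`
#'   for EPSI datasets; optionally `resonances` (list of [Resonance]) to
#'   check that the region is signal-free
#' @return a list with `sigma` and `source`
#' @export
setGeneric("estimateNoise", function(x, ...) standardGeneric("estimateNoise"))
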