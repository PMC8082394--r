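#' @import methods
#' @importFrom stats rnorm sd coef lm optim pt qnorm
NULL

#' Resonance: one 13C line and its acquisition physics
#'
#' A `Resonance` describes a single carbon-13 line: its chemical shift,
#' Lorentzian linewidth, longitudinal relaxation time of the hyperpolarized
#' magnetization, and the per-excitation flip angle the acquisition applies
#' to it (spectral-spatial excitation allows a different flip angle per
#' metabolite).
#'
#' @slot name metabolite label (e.g. `"dGL"`, `"gGL"`, `"6PG"`)
#' @slot shiftPpm chemical shift in ppm
#' @slot linewidthHz Lorentzian full width at half maximum, Hz
#' @slot T1s longitudinal relaxation time, seconds
#' @slot flipAngleDeg per-excitation tip angle, degrees
#' @export
setClass("Resonance",
  representation(
    name = "character",
    shiftPpm = "numeric",
    linewidthHz = "numeric",
    T1s = "numeric",
    flipAngleDeg = "numeric"
  )
)

setValidity("Resonance", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (!is.finite(object@shiftPpm)) msg <- c(msg, "shiftPpm must be finite")
  if (!isTRUE(object@linewidthHz > 0)) msg <- c(msg, "linewidthHz must be > 0")
  if (!isTRUE(object@T1s > 0)) msg <- c(msg, "T1s must be > 0")
  if (!isTRUE(object@flipAngleDeg > 0 && object@flipAngleDeg <= 90))
    msg <- c(msg, "flipAngleDeg must be in (0, 90]")
  if (length(msg)) msg else TRUE
})

#' @param name,shiftPpm,linewidthHz,T1s,flipAngleDeg see slots
#' @rdname Resonance-class
#' @export
Resonance <- function(name, shiftPpm, linewidthHz, T1s, flipAngleDeg) {
  new("Resonance", name = name, shiftPpm = shiftPpm,
      linewidthHz = linewidthHz, T1s = T1s, flipAngleDeg = flipAngleDeg)
}

#' AcquisitionScheme: spectral and temporal sampling parameters
#'
#' Describes how dynamic spectra are sampled: repetition time, number of
#' acquisitions, spectral grid (points, bandwidth and centre in ppm), static
#' field and carrier frequency, and whether the acquisition is single-voxel
#' or an EPSI grid.
#'
#' @slot TRs repetition time, seconds
#' @slot nTimepoints number of dynamic acquisitions
#' @slot spectralPoints points across the spectral axis
#' @slot bandwidthPpm spectral width, ppm
#' @slot centerPpm centre of the spectral axis, ppm
#' @slot B0T static field, tesla
#' @slot refFreqMHz 13C carrier frequency, MHz
#' @slot mode `"single_voxel"` or `"epsi_grid"`
#' @export
setClass("AcquisitionScheme",
  representation(
    TRs = "numeric",
    nTimepoints = "integer",
    spectralPoints = "integer",
    bandwidthPpm = "numeric",
    centerPpm = "numeric",
    B0T = "numeric",
    refFreqMHz = "numeric",
    mode = "character"
  )
)

setValidity("AcquisitionScheme", function(object) {
  msg <- character()
  if (!isTRUE(object@TRs > 0)) msg <- c(msg, "TRs must be > 0")
  if (!isTRUE(object@nTimepoints >= 2L)) msg <- c(msg, "nTimepoints must be >= 2")
  if (!isTRUE(object@spectralPoints >= 64L)) msg <- c(msg, "spectralPoints must be >= 64")
  if (!isTRUE(object@bandwidthPpm > 0)) msg <- c(msg, "bandwidthPpm must be > 0")
  if (!isTRUE(object@refFreqMHz > 0)) msg <- c(msg, "refFreqMHz must be > 0")
  if (!object@mode %in% c("single_voxel", "epsi_grid"))
    msg <- c(msg, "mode must be 'single_voxel' or 'epsi_grid'")
  if (length(msg)) msg else TRUE
})

# 13C gyromagnetic ratio over 2*pi, MHz/T
GAMMA_13C_RAD <- 6.72828e7
GAMMA_13C_MHZ_PER_T <- GAMMA_13C_RAD / (2 * pi) / 1e6

#' @param TRs,nTimepoints,spectralPoints,bandwidthPpm,centerPpm,B0T,refFreqMHz,mode see slots;
#'   `refFreqMHz` defaults to the 13C Larmor frequency at `B0T`
#' @rdname AcquisitionScheme-class
#' @export
AcquisitionScheme <- function(TRs = 3, nTimepoints = 100L, spectralPoints = 128L,
                              bandwidthPpm = 20, centerPpm = 176, B0T = 3,
                              refFreqMHz = NULL, mode = "single_voxel") {
  if (is.null(refFreqMHz)) refFreqMHz <- GAMMA_13C_MHZ_PER_T * B0T
  new("AcquisitionScheme", TRs = TRs, nTimepoints = as.integer(nTimepoints),
      spectralPoints = as.integer(spectralPoints), bandwidthPpm = bandwidthPpm,
      centerPpm = centerPpm, B0T = B0T, refFreqMHz = refFreqMHz, mode = mode)
}

#' KineticModel: hyperpolarized pool dynamics
#'
#' First-order kinetics of the three-pool delta-gluconolactone /
#' gamma-gluconolactone / 6PG system: enzymatic conversion of the delta
#' anomer to 6PG (the gamma anomer is not a PGLS substrate), slow delta/gamma
#' anomer exchange, and substrate delivery either pre-loaded at time zero
#' (cell suspension mode, `bolusDurationS = 0`) or as a smoothed boxcar
#' bolus (in vivo mode).
#'
#' @slot kPGLSPerS delta -> 6PG conversion rate, 1/s
#' @slot kDGPerS,kGDPerS delta -> gamma and gamma -> delta exchange rates, 1/s
#' @slot M0 total initial (or delivered) hyperpolarized magnetization, a.u.
#' @slot deltaGammaRatio0 fraction of substrate delivered as the delta anomer
#' @slot bolusStartS,bolusDurationS boxcar input window, seconds
#'   (`bolusDurationS = 0` pre-loads `M0` at time zero)
#' @slot bolusTauS exponential smoothing time constant of the boxcar edges, s
#' @export
setClass("KineticModel",
  representation(
    kPGLSPerS = "numeric",
    kDGPerS = "numeric",
    kGDPerS = "numeric",
    M0 = "numeric",
    deltaGammaRatio0 = "numeric",
    bolusStartS = "numeric",
    bolusDurationS = "numeric",
    bolusTauS = "numeric"
  )
)

setValidity("KineticModel", function(object) {
  msg <- character()
  rates <- c(object@kPGLSPerS, object@kDGPerS, object@kGDPerS)
  if (any(!is.finite(rates)) || any(rates < 0))
    msg <- c(msg, "rates must be finite and >= 0")
  if (!isTRUE(object@M0 >= 0)) msg <- c(msg, "M0 must be >= 0")
  if (!isTRUE(object@deltaGammaRatio0 >= 0 && object@deltaGammaRatio0 <= 1))
    msg <- c(msg, "deltaGammaRatio0 must be in [0, 1]")
  if (!isTRUE(object@bolusDurationS >= 0)) msg <- c(msg, "bolusDurationS must be >= 0")
  if (!isTRUE(object@bolusTauS >= 0)) msg <- c(msg, "bolusTauS must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param kPGLSPerS,kDGPerS,kGDPerS,M0,deltaGammaRatio0,bolusStartS,bolusDurationS,bolusTauS see slots
#' @rdname KineticModel-class
#' @export
KineticModel <- function(kPGLSPerS = 0.005, kDGPerS = 0.005, kGDPerS = 0.005,
                         M0 = 1, deltaGammaRatio0 = 0.6,
                         bolusStartS = 0, bolusDurationS = 0, bolusTauS = 2) {
  new("KineticModel", kPGLSPerS = kPGLSPerS, kDGPerS = kDGPerS,
      kGDPerS = kGDPerS, M0 = M0, deltaGammaRatio0 = deltaGammaRatio0,
      bolusStartS = bolusStartS, bolusDurationS = bolusDurationS,
      bolusTauS = bolusTauS)
}

#' Phantom: spatial layout for EPSI simulation
#'
#' Per-voxel kinetic parameters on the native acquisition grid, with a tumor
#' mask (elevated PGLS rate), an outside-the-brain mask (signal-free voxels
#' used for noise estimation) and the acquisition geometry.
#'
#' @slot gridShape rows x cols of the native grid
#' @slot voxelSizeMm in-plane voxel size per axis, mm
#' @slot sliceThicknessMm slice thickness, mm
#' @slot kMap per-voxel PGLS conversion rate, 1/s
#' @slot deliveryMap per-voxel substrate delivery scale (multiplies M0)
#' @slot tumorMask,outsideMask logical matrices on the grid
#' @export
setClass("Phantom",
  representation(
    gridShape = "integer",
    voxelSizeMm = "numeric",
    sliceThicknessMm = "numeric",
    kMap = "matrix",
    deliveryMap = "matrix",
    tumorMask = "matrix",
    outsideMask = "matrix"
  )
)

setValidity("Phantom", function(object) {
  msg <- character()
  gs <- object@gridShape
  if (length(gs) != 2L || any(gs < 1L)) msg <- c(msg, "gridShape must be two positive integers")
  for (nm in c("kMap", "deliveryMap", "tumorMask", "outsideMask")) {
    m <- slot(object, nm)
    if (!identical(dim(m), as.integer(gs)))
      msg <- c(msg, sprintf("%s dimensions must equal gridShape", nm))
  }
  if (!length(msg)) {
    if (any(object@tumorMask & object@outsideMask))
      msg <- c(msg, "tumorMask and outsideMask must not intersect")
    if (any(object@deliveryMap < 0)) msg <- c(msg, "deliveryMap must be >= 0")
    if (any(object@kMap < 0)) msg <- c(msg, "kMap must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @param gridShape,voxelSizeMm,sliceThicknessMm,kMap,deliveryMap,tumorMask,outsideMask see slots
#' @rdname Phantom-class
#' @export
Phantom <- function(gridShape, voxelSizeMm = c(4.375, 4.375),
                    sliceThicknessMm = 8, kMap, deliveryMap,
                    tumorMask, outsideMask) {
  new("Phantom", gridShape = as.integer(gridShape), voxelSizeMm = voxelSizeMm,
      sliceThicknessMm = sliceThicknessMm, kMap = kMap,
      deliveryMap = deliveryMap, tumorMask = tumorMask,
      outsideMask = outsideMask)
}

#' NoiseSpec: additive complex Gaussian noise
#'
#' @slot sigma standard deviation of the real and imaginary noise per
#'   spectral point, signal units
#' @slot seed RNG seed; identical (configuration, seed) pairs give
#'   bit-identical datasets
#' @export
setClass("NoiseSpec", representation(sigma = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  if (!isTRUE(object@sigma >= 0)) "sigma must be >= 0" else TRUE
})

#' @param sigma,seed see slots
#' @rdname NoiseSpec-class
#' @export
NoiseSpec <- function(sigma = 0, seed = 1L) {
  new("NoiseSpec", sigma = sigma, seed = as.integer(seed))
}

#' Spectrum: one complex NMR spectrum on a ppm axis
#'
#' @slot values complex amplitudes per spectral point (absorption mode in the
#'   real part for in-phase synthetic data)
#' @slot axisPpm ppm value per point, strictly monotone, stored descending
#'   (downfield on the left)
#' @slot meta provenance list (carrier frequency, field, flip angles, ...)
#' @export
setClass("Spectrum",
  representation(values = "complex", axisPpm = "numeric", meta = "list")
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@values) != length(object@axisPpm))
    msg <- c(msg, "values and axisPpm must have equal length")
  d <- diff(object@axisPpm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    msg <- c(msg, "axisPpm must be strictly monotone")
  if (length(msg)) msg else TRUE
})

#' @param values,axisPpm,meta see slots
#' @rdname Spectrum-class
#' @export
Spectrum <- function(values, axisPpm, meta = list()) {
  new("Spectrum", values = as.complex(values), axisPpm = axisPpm, meta = meta)
}

#' DynamicSpectrumSeries: time-resolved spectra from one voxel
#'
#' @slot spectra complex matrix, timepoints x spectral points
#' @slot axisPpm shared ppm axis (descending)
#' @slot TRs sampling interval, seconds
#' @slot t0s time of the first acquisition relative to injection/dissolution, s
#' @slot meta provenance list
#' @export
setClass("DynamicSpectrumSeries",
  representation(spectra = "matrix", axisPpm = "numeric", TRs = "numeric",
                 t0s = "numeric", meta = "list")
)

setValidity("DynamicSpectrumSeries", function(object) {
  msg <- character()
  if (!is.complex(object@spectra)) msg <- c(msg, "spectra must be a complex matrix")
  if (ncol(object@spectra) != length(object@axisPpm))
    msg <- c(msg, "ncol(spectra) must equal length(axisPpm)")
  if (!isTRUE(object@TRs > 0)) msg <- c(msg, "TRs must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param spectra,axisPpm,TRs,t0s,meta see slots
#' @rdname DynamicSpectrumSeries-class
#' @export
DynamicSpectrumSeries <- function(spectra, axisPpm, TRs, t0s = 0, meta = list()) {
  new("DynamicSpectrumSeries", spectra = spectra, axisPpm = axisPpm,
      TRs = TRs, t0s = t0s, meta = meta)
}

#' EPSIDataset: a grid of dynamic spectra with geometry and masks
#'
#' @slot spectra complex 4-D array: time x row x col x spectral point
#' @slot axisPpm shared ppm axis (descending)
#' @slot TRs sampling interval, s
#' @slot t0s time of first acquisition, s
#' @slot geometry list with `voxelSizeMm` (length 2) and `sliceThicknessMm`
#' @slot masks list of logical matrices (`tumor`, `outside`, optionally others)
#' @slot meta provenance list
#' @export
setClass("EPSIDataset",
  representation(spectra = "array", axisPpm = "numeric", TRs = "numeric",
                 t0s = "numeric", geometry = "list", masks = "list",
                 meta = "list")
)

setValidity("EPSIDataset", function(object) {
  msg <- character()
  d <- dim(object@spectra)
  if (length(d) != 4L) msg <- c(msg, "spectra must be a 4-D array (time x row x col x point)")
  else {
    if (d[4] != length(object@axisPpm))
      msg <- c(msg, "4th dim of spectra must equal length(axisPpm)")
    for (nm in names(object@masks)) {
      m <- object@masks[[nm]]
      if (!is.logical(m) || !identical(dim(m), d[2:3]))
        msg <- c(msg, sprintf("mask '%s' must be a logical row x col matrix", nm))
    }
  }
  if (!isTRUE(object@TRs > 0)) msg <- c(msg, "TRs must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param spectra,axisPpm,TRs,t0s,geometry,masks,meta see slots
#' @rdname EPSIDataset-class
#' @export
EPSIDataset <- function(spectra, axisPpm, TRs, t0s = 0, geometry = list(),
                        masks = list(), meta = list()) {
  new("EPSIDataset", spectra = spectra, axisPpm = axisPpm, TRs = TRs,
      t0s = t0s, geometry = geometry, masks = masks, meta = meta)
}

#' PeakWindow: a closed ppm integration window
#'
#' @slot name metabolite label
#' @slot centerPpm window centre, ppm
#' @slot halfWidthPpm half width, ppm
#' @export
setClass("PeakWindow",
  representation(name = "character", centerPpm = "numeric",
                 halfWidthPpm = "numeric")
)

setValidity("PeakWindow", function(object) {
  if (!isTRUE(object@halfWidthPpm > 0)) "halfWidthPpm must be > 0" else TRUE
})

#' @param name,centerPpm,halfWidthPpm see slots
#' @rdname PeakWindow-class
#' @export
PeakWindow <- function(name, centerPpm, halfWidthPpm = 0.5) {
  new("PeakWindow", name = name, centerPpm = centerPpm,
      halfWidthPpm = halfWidthPpm)
}

#' HeatMap: an interpolated metabolite map
#'
#' @slot values interpolated map (typically 256 x 256); `NaN` outside the
#'   validity mask
#' @slot kind `"snr"` or `"ratio"`
#' @slot sourceMetabolites labels of the metabolites the map was built from
#' @slot noiseSigma noise normalization constant used (NA for ratio maps)
#' @export
setClass("HeatMap",
  representation(values = "matrix", kind = "character",
                 sourceMetabolites = "character", noiseSigma = "numeric")
)

setValidity("HeatMap", function(object) {
  if (!object@kind %in% c("snr", "ratio")) "kind must be 'snr' or 'ratio'" else TRUE
})

#' @param values,kind,sourceMetabolites,noiseSigma see slots
#' @rdname HeatMap-class
#' @export
HeatMap <- function(values, kind, sourceMetabolites = character(),
                    noiseSigma = NA_real_) {
  new("HeatMap", values = values, kind = kind,
      sourceMetabolites = sourceMetabolites, noiseSigma = noiseSigma)
}
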