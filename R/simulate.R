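#' Default resonance sets for the gluconolactone / 6PG system
#'
#' Returns the three carbon-13 resonances of the system: the delta anomer of
#' [1-13C]gluconolactone at 173.8 ppm, the gamma anomer at 177 ppm and
#' [1-13C]6-phosphogluconate (6PG) at 178.6 ppm.
#'
#' Two acquisition settings are provided. `"invivo"` reflects the 3 T EPSI
#' acquisition: metabolite-specific flip angles of 3.4 (delta), 12 (gamma)
#' and 15.3 (6PG) degrees from the spectral-spatial excitation, 8 Hz
#' linewidths, and the 3 T substrate T1 of 31.7 s. `"cell"` reflects the
#' 11.7 T cell-suspension acquisition: a uniform 13 degree flip angle, 4 Hz
#' linewidths, and the 11.7 T substrate T1 of 15.7 s. The gamma-anomer T1 is
#' set equal to the measured delta value and the 6PG T1 somewhat shorter
#' (phosphorylated metabolite), both configurable by rebuilding the
#' [Resonance] objects.
#'
#' @param mode `"invivo"` (3 T EPSI) or `"cell"` (11.7 T spectrometer)
#' @return named list of three [Resonance] objects (`dGL`, `gGL`, `6PG`)
#' @export
gluconolactoneResonances <- function(mode = c("invivo", "cell")) {
  mode <- match.arg(mode)
  if (mode == "invivo") {
    list(
      dGL   = Resonance("dGL", 173.8, 8, 31.7, 3.4),
      gGL   = Resonance("gGL", 177.0, 8, 31.7, 12),
      `6PG` = Resonance("6PG", 178.6, 8, 25, 15.3)
    )
  } else {
    list(
      dGL   = Resonance("dGL", 173.8, 4, 15.7, 13),
      gGL   = Resonance("gGL", 177.0, 4, 15.7, 13),
      `6PG` = Resonance("6PG", 178.6, 4, 12, 13)
    )
  }
}

POOL_NAMES <- c("dGL", "gGL", "6PG")

# Kinetic matrix over the present pools: T1 decay on the diagonal,
# delta<->gamma exchange, delta->6PG conversion (gamma is not converted).
poolMatrix <- function(model, resonances) {
  pools <- vapply(resonances, slot, character(1), "name")
  if (any(duplicated(pools))) stop("duplicate pool names in resonances", call. = FALSE)
  unknown <- setdiff(pools, POOL_NAMES)
  if (length(unknown))
    stop("unknown pool name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  has <- function(p) p %in% pools
  if (model@kPGLSPerS > 0 && !(has("dGL") && has("6PG")))
    stop("kPGLSPerS > 0 requires both 'dGL' and '6PG' resonances", call. = FALSE)
  if ((model@kDGPerS > 0 || model@kGDPerS > 0) && !(has("dGL") && has("gGL")))
    stop("anomer exchange requires both 'dGL' and 'gGL' resonances", call. = FALSE)

  n <- length(pools)
  A <- matrix(0, n, n, dimnames = list(pools, pools))
  T1 <- vapply(resonances, slot, numeric(1), "T1s")
  diag(A) <- -1 / T1
  if (has("dGL")) {
    A["dGL", "dGL"] <- A["dGL", "dGL"] - model@kPGLSPerS - model@kDGPerS
    if (has("gGL")) {
      A["gGL", "dGL"] <- model@kDGPerS
      A["dGL", "gGL"] <- model@kGDPerS
      A["gGL", "gGL"] <- A["gGL", "gGL"] - model@kGDPerS
    }
    if (has("6PG")) A["6PG", "dGL"] <- model@kPGLSPerS
  }
  A
}

# Delivery partition of substrate over the present pools.
inputVector <- function(model, pools) {
  b <- setNames(numeric(length(pools)), pools)
  r <- model@deltaGammaRatio0
  if ("dGL" %in% pools && "gGL" %in% pools) {
    b["dGL"] <- r; b["gGL"] <- 1 - r
  } else if ("dGL" %in% pools) {
    b["dGL"] <- 1
  } else if ("gGL" %in% pools) {
    b["gGL"] <- 1
  } else {
    stop("no substrate pool to deliver magnetization into", call. = FALSE)
  }
  b
}

denseExpm <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

#' Simulate hyperpolarized multi-pool magnetization dynamics
#'
#' Integrates the first-order pool system between excitations and applies
#' instantaneous RF depletion at each acquisition. Between pulses the
#' longitudinal magnetization evolves as `dM/dt = A M + b u(t)`, where `A`
#' combines metabolite-specific T1 decay, delta/gamma anomer exchange and
#' delta -> 6PG conversion, and `u(t)` is the substrate input (zero in cell
#' mode, a smoothed boxcar bolus in vivo). At acquisition `i` each pool `p`
#' emits a transverse amplitude `M_p sin(theta_p)` and retains
#' `M_p cos(theta_p)`. The linear system is propagated by exact piecewise
#' matrix exponentials, so trajectories carry no integration error beyond
#' machine precision.
#'
#' When `bolusDurationS = 0` (cell mode) the magnetization `M0` is present
#' at time zero, partitioned `deltaGammaRatio0 : 1 - deltaGammaRatio0`
#' between the anomers. Otherwise `M0` enters through a boxcar of the given
#' duration whose edges are smoothed by an exponential of time constant
#' `bolusTauS`; input is truncated four time constants after the boxcar ends
#' so that no magnetization is created after the bolus.
#'
#' @param model a [KineticModel]
#' @param scheme an [AcquisitionScheme]
#' @param resonances list of [Resonance] covering every pool the model uses
#' @param t0s time of the first excitation relative to time zero
#'   (dissolution / start of injection), seconds
#' @return a list with `times` (s), `M` (pre-pulse longitudinal
#'   magnetization, timepoints x pools), `amplitudes` (sampled transverse
#'   amplitude `M sin(theta)`, same shape), and `pools`
#' @export
simulatePoolDynamics <- function(model, scheme, resonances, t0s = 0) {
  validObject(model); validObject(scheme)
  A <- poolMatrix(model, resonances)
  pools <- rownames(A)
  n <- length(pools)
  theta <- degToRad(vapply(resonances, slot, numeric(1), "flipAngleDeg"))
  names(theta) <- vapply(resonances, slot, character(1), "name")
  theta <- theta[pools]

  nT <- scheme@nTimepoints
  times <- t0s + (seq_len(nT) - 1) * scheme@TRs

  hasBolus <- model@bolusDurationS > 0
  b <- inputVector(model, pools)
  a0 <- model@bolusStartS
  D <- model@bolusDurationS
  tau <- model@bolusTauS
  inputEnd <- if (!hasBolus) -Inf else if (tau > 0) a0 + D + 4 * tau else a0 + D
  h <- if (hasBolus) model@M0 / D else 0

  expmCache <- new.env(parent = emptyenv())
  plainStep <- function(M, dt) {
    key <- format(dt, digits = 17)
    P <- expmCache[[key]]
    if (is.null(P)) {
      P <- denseExpm(A * dt)
      expmCache[[key]] <- P
    }
    drop(P %*% M)
  }

  # Propagate through one sub-interval that lies inside a single bolus piece.
  bolusStep <- function(M, s0, s1) {
    if (tau == 0) {
      c0 <- h; c1 <- 0
    } else if (s0 < a0 + D) {
      c0 <- h; c1 <- -h * exp(-(s0 - a0) / tau)
    } else {
      c0 <- 0; c1 <- h * (1 - exp(-D / tau)) * exp(-(s0 - a0 - D) / tau)
    }
    Aaug <- matrix(0, n + 2, n + 2)
    Aaug[1:n, 1:n] <- A
    Aaug[1:n, n + 1] <- b * c1
    Aaug[1:n, n + 2] <- b * c0
    if (tau > 0) Aaug[n + 1, n + 1] <- -1 / tau
    z <- c(M, 1, 1)
    drop(denseExpm(Aaug * (s1 - s0)) %*% z)[1:n]
  }

  propagate <- function(M, t0, t1) {
    if (t1 <= t0) return(M)
    if (!hasBolus || t1 <= a0 || t0 >= inputEnd) return(plainStep(M, t1 - t0))
    breaks <- sort(unique(c(t0, t1,
                            a0, a0 + D, inputEnd)))
    breaks <- breaks[breaks >= t0 & breaks <= t1]
    for (j in seq_len(length(breaks) - 1)) {
      s0 <- breaks[j]; s1 <- breaks[j + 1]
      if (s1 <= a0 || s0 >= inputEnd) M <- plainStep(M, s1 - s0)
      else M <- bolusStep(M, s0, s1)
    }
    M
  }

  M <- setNames(numeric(n), pools)
  if (!hasBolus) M <- model@M0 * inputVector(model, pools)
  if (times[1] > 0) M <- propagate(M, 0, times[1])

  Mpre <- matrix(0, nT, n, dimnames = list(NULL, pools))
  for (i in seq_len(nT)) {
    Mpre[i, ] <- M
    M <- M * cos(theta)
    if (i < nT) M <- propagate(M, times[i], times[i + 1])
  }
  amps <- sweep(Mpre, 2, sin(theta), `*`)
  list(times = times, M = Mpre, amplitudes = amps, pools = pools)
}

# Unit-area complex Lorentzian line as the DFT of its finite sampled FID
# (one-sided decaying exponential, first point half-weighted to suppress the
# baseline offset). This is the lineshape a Fourier-transformed acquisition
# actually yields on a discrete axis, so discrete integrals of the real part
# behave like their continuous counterparts even for lines narrower than the
# grid spacing. Absorption mode in Re, dispersion in Im; real-part area over
# a wide ppm window is 1.
lorentzLine <- function(axis, shiftPpm, fwhmPpm, refFreqMHz) {
  n <- length(axis)
  d <- abs(axis[1] - axis[2])                  # ppm per point
  dt <- 1 / (n * d * refFreqMHz)               # dwell time, s (ppm x MHz = Hz)
  nuHz <- (axis - shiftPpm) * refFreqMHz       # frequency offsets, Hz
  fwhmHz <- fwhmPpm * refFreqMHz
  ex <- (-2i * pi * nuHz - pi * fwhmHz) * dt
  z <- exp(ex)
  zN <- exp(n * ex)
  (2 / (n * d)) * (-0.5 + (1 - zN) / (1 - z))
}

checkShiftInSpan <- function(resonances, axis) {
  lo <- min(axis); hi <- max(axis)
  for (r in resonances)
    if (r@shiftPpm < lo || r@shiftPpm > hi)
      stop(sprintf("resonance '%s' (%.2f ppm) lies outside the spectral axis [%.2f, %.2f] ppm",
                   r@name, r@shiftPpm, lo, hi), call. = FALSE)
  invisible(TRUE)
}

seriesMeta <- function(scheme, resonances, noise = NULL) {
  m <- list(refFreqMHz = scheme@refFreqMHz, B0T = scheme@B0T,
            centerPpm = scheme@centerPpm, mode = scheme@mode,
            flipAnglesDeg = setNames(
              vapply(resonances, slot, numeric(1), "flipAngleDeg"),
              vapply(resonances, slot, character(1), "name")))
  if (!is.null(noise)) { m$noiseSigma <- noise@sigma; m$noiseSeed <- noise@seed }
  m
}

#' Render a dynamic spectrum series from sampled pool amplitudes
#'
#' Each timepoint becomes a complex spectrum: the sum over resonances of an
#' absorption-mode Lorentzian (with its dispersion counterpart in the
#' imaginary part) centred at the resonance's shift, with real-part area
#' equal to the sampled amplitude, plus i.i.d. complex Gaussian noise of
#' standard deviation `noise@sigma` on both quadratures. Identical
#' (inputs, seed) give bit-identical output.
#'
#' @param sim output of [simulatePoolDynamics()]
#' @param scheme the [AcquisitionScheme] (defines the ppm axis)
#' @param resonances list of [Resonance] matching the simulated pools
#' @param noise a [NoiseSpec]
#' @return a [DynamicSpectrumSeries]
#' @export
renderSpectrumSeries <- function(sim, scheme, resonances, noise = NoiseSpec()) {
  axis <- schemeAxisPpm(scheme)
  checkShiftInSpan(resonances, axis)
  names(resonances) <- vapply(resonances, slot, character(1), "name")
  resonances <- resonances[sim$pools]
  L <- t(vapply(resonances, function(r)
    lorentzLine(axis, r@shiftPpm, r@linewidthHz / scheme@refFreqMHz,
                scheme@refFreqMHz),
    complex(length(axis))))
  spectra <- sim$amplitudes %*% L
  if (noise@sigma > 0) {
    spectra <- spectra + withSeed(noise@seed, {
      nre <- matrix(rnorm(length(spectra), sd = noise@sigma), nrow(spectra))
      nim <- matrix(rnorm(length(spectra), sd = noise@sigma), nrow(spectra))
      nre + 1i * nim
    })
  }
  DynamicSpectrumSeries(spectra, axis, scheme@TRs, t0s = sim$times[1],
                        meta = seriesMeta(scheme, resonances, noise))
}

#' Reference tumor-bearing phantom on the native EPSI grid
#'
#' An 8 x 8 layout emulating an axial slice through a tumor-bearing rat
#' brain: a one-voxel border outside the head (signal-free, used for noise
#' estimation), a brain with background PGLS activity, and a 2 x 2 tumor
#' with elevated conversion in one hemisphere. Substrate delivery is uniform
#' across the brain (tumor and normal brain do not differ measurably in
#' substrate delivery) and zero outside.
#'
#' @param gridShape native matrix size (default `c(8, 8)`)
#' @param kTumor,kBackground PGLS conversion rates, 1/s
#' @param voxelSizeMm,sliceThicknessMm acquisition geometry, mm
#' @return a [Phantom]
#' @export
referencePhantom <- function(gridShape = c(8, 8), kTumor = 0.02,
                             kBackground = 0.005,
                             voxelSizeMm = c(4.375, 4.375),
                             sliceThicknessMm = 8) {
  gr <- as.integer(gridShape)
  outside <- matrix(FALSE, gr[1], gr[2])
  outside[c(1, gr[1]), ] <- TRUE
  outside[, c(1, gr[2])] <- TRUE
  tumor <- matrix(FALSE, gr[1], gr[2])
  tr <- pmin(3:4, gr[1] - 1); tc <- pmin(2:3, gr[2] - 1)
  tumor[tr, tc] <- TRUE
  tumor[outside] <- FALSE
  k <- matrix(kBackground, gr[1], gr[2])
  k[tumor] <- kTumor
  k[outside] <- 0
  delivery <- matrix(1, gr[1], gr[2])
  delivery[outside] <- 0
  Phantom(gr, voxelSizeMm, sliceThicknessMm, k, delivery, tumor, outside)
}

#' Mirror a mask across the vertical midline
#'
#' Used to place a "normal-appearing contralateral brain" region opposite
#' the tumor.
#'
#' @param mask logical matrix
#' @return logical matrix with columns reversed
#' @export
mirrorMask <- function(mask) mask[, rev(seq_len(ncol(mask))), drop = FALSE]

#' Simulate a full EPSI dataset over a phantom
#'
#' Instantiates the kinetic model voxel by voxel: voxel `(r, c)` uses the
#' conversion rate `kMap[r, c]` and `M0` scaled by `deliveryMap[r, c]`.
#' Voxels under the outside mask carry no signal (noise only). Identical
#' kinetic parameters are simulated once and shared.
#'
#' @param phantom a [Phantom]
#' @param baseModel a [KineticModel]; its `kPGLSPerS` and `M0` are
#'   overridden per voxel by the phantom maps
#' @param scheme an [AcquisitionScheme] with `mode = "epsi_grid"`
#' @param resonances list of [Resonance]
#' @param noise a [NoiseSpec]
#' @return an [EPSIDataset] with `tumor`, `contralateral` and `outside` masks
#' @export
simulateEPSIDataset <- function(phantom, baseModel, scheme, resonances,
                                noise = NoiseSpec()) {
  validObject(phantom)
  stopIfNot(scheme@mode == "epsi_grid",
            "simulateEPSIDataset requires scheme mode 'epsi_grid'")
  gr <- phantom@gridShape
  axis <- schemeAxisPpm(scheme)
  checkShiftInSpan(resonances, axis)
  nT <- scheme@nTimepoints
  arr <- array(0 + 0i, dim = c(nT, gr[1], gr[2], length(axis)))

  key <- paste(signif(phantom@kMap, 12), signif(phantom@deliveryMap, 12))
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(gr[1])) for (cc in seq_len(gr[2])) {
    if (phantom@outsideMask[r, cc] || phantom@deliveryMap[r, cc] == 0) next
    kk <- key[(cc - 1) * gr[1] + r]
    sp <- cache[[kk]]
    if (is.null(sp)) {
      m <- baseModel
      m@kPGLSPerS <- phantom@kMap[r, cc]
      m@M0 <- baseModel@M0 * phantom@deliveryMap[r, cc]
      sim <- simulatePoolDynamics(m, scheme, resonances)
      sp <- renderSpectrumSeries(sim, scheme, resonances, NoiseSpec(0))@spectra
      cache[[kk]] <- sp
    }
    arr[, r, cc, ] <- sp
  }
  if (noise@sigma > 0) {
    arr <- arr + withSeed(noise@seed, {
      nre <- array(rnorm(length(arr), sd = noise@sigma), dim = dim(arr))
      nim <- array(rnorm(length(arr), sd = noise@sigma), dim = dim(arr))
      nre + 1i * nim
    })
  }
  EPSIDataset(arr, axis, scheme@TRs, t0s = 0,
              geometry = list(voxelSizeMm = phantom@voxelSizeMm,
                              sliceThicknessMm = phantom@sliceThicknessMm),
              masks = list(tumor = phantom@tumorMask,
                           contralateral = mirrorMask(phantom@tumorMask),
                           outside = phantom@outsideMask),
              meta = seriesMeta(scheme, resonances, noise))
}

#' Render a thermal-equilibrium reference spectrum
#'
#' The thermal reference is acquired at equilibrium polarization `PTh` with
#' a 90 degree pulse and `nAverages` summed averages (long TR so the signal
#' recovers fully between acquisitions). The rendered amplitude is
#' `concentrationScale * PTh * sin(theta) * nAverages` -- the summed-average
#' convention, mirrored exactly by [backCalculatePolarization()].
#'
#' @param concentrationScale signal per unit polarization (absorbs
#'   concentration, coil sensitivity and receiver gain; must match the
#'   hyperpolarized acquisition it is compared against)
#' @param scheme an [AcquisitionScheme] (defines the ppm axis)
#' @param resonance the observed [Resonance]
#' @param PTh thermal equilibrium polarization (fraction), e.g. from
#'   [thermalPolarization()]
#' @param nAverages number of summed averages (default 16)
#' @param thetaDeg excitation flip angle (default 90)
#' @param noise a [NoiseSpec]
#' @return a [Spectrum]
#' @export
renderThermalSpectrum <- function(concentrationScale, scheme, resonance,
                                  PTh, nAverages = 16, thetaDeg = 90,
                                  noise = NoiseSpec()) {
  stopIfNot(nAverages >= 1, "nAverages must be >= 1")
  stopIfNot(PTh >= 0, "PTh must be >= 0")
  axis <- schemeAxisPpm(scheme)
  checkShiftInSpan(list(resonance), axis)
  amp <- concentrationScale * PTh * sin(degToRad(thetaDeg)) * nAverages
  v <- amp * lorentzLine(axis, resonance@shiftPpm,
                         resonance@linewidthHz / scheme@refFreqMHz,
                         scheme@refFreqMHz)
  if (noise@sigma > 0) {
    v <- v + withSeed(noise@seed, {
      complex(real = rnorm(length(v), sd = noise@sigma),
              imaginary = rnorm(length(v), sd = noise@sigma))
    })
  }
  Spectrum(v, axis, meta = c(seriesMeta(scheme, list(resonance), noise),
                             list(nAverages = nAverages,
                                  thetaDeg = thetaDeg)))
}
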