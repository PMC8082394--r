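# Shared fixture builders; everything is generated in code at test time.

# Single delta-pool solution configuration (T1 decay only, no chemistry).
soloDecayFixture <- function(T1 = 31.7, thetaDeg = 10, TRs = 3, nT = 20,
                             M0 = 1, B0T = 3, linewidthHz = 4) {
  scheme <- AcquisitionScheme(TRs = TRs, nTimepoints = nT, B0T = B0T)
  res <- list(dGL = Resonance("dGL", 173.8, linewidthHz, T1, thetaDeg))
  model <- KineticModel(kPGLSPerS = 0, kDGPerS = 0, kGDPerS = 0,
                        M0 = M0, deltaGammaRatio0 = 1)
  list(scheme = scheme, resonances = res, model = model)
}

# Full three-pool cell-suspension configuration.
cellFixture <- function(k = 0.01, nT = 100, spectralPoints = 512L,
                        sigma = 0, seed = 1L) {
  scheme <- AcquisitionScheme(TRs = 3, nTimepoints = nT,
                              spectralPoints = spectralPoints,
                              bandwidthPpm = 20, centerPpm = 176, B0T = 11.7)
  res <- gluconolactoneResonances("cell")
  model <- KineticModel(kPGLSPerS = k)
  sim <- simulatePoolDynamics(model, scheme, res)
  series <- renderSpectrumSeries(sim, scheme, res, NoiseSpec(sigma, seed))
  list(scheme = scheme, resonances = res, model = model, sim = sim,
       series = series, windows = defaultWindows(res))
}

# Small in vivo EPSI dataset over the reference phantom.
epsiFixture <- function(nT = 30, sigma = 0.001, seed = 1L,
                        kTumor = 0.02, kBackground = 0.005) {
  phantom <- referencePhantom(kTumor = kTumor, kBackground = kBackground)
  scheme <- AcquisitionScheme(TRs = 3, nTimepoints = nT, spectralPoints = 128L,
                              bandwidthPpm = 20, centerPpm = 176, B0T = 3,
                              mode = "epsi_grid")
  res <- gluconolactoneResonances("invivo")
  model <- KineticModel(kPGLSPerS = kBackground, bolusDurationS = 15)
  ds <- simulateEPSIDataset(phantom, model, scheme, res, NoiseSpec(sigma, seed))
  list(phantom = phantom, scheme = scheme, resonances = res, model = model,
       dataset = ds, windows = defaultWindows(res))
}

# Direct 1-D Lanczos-2 resampling oracle: explicit per-pixel loop over the
# kernel definition, independent of the package's matrix implementation.
oracleLanczos1D <- function(v, outLen) {
  n <- length(v)
  scale <- n / outLen
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  out <- numeric(outLen)
  for (j in seq_len(outLen)) {
    u <- (j - 0.5) * scale - 0.5
    acc <- 0; wsum <- 0
    for (i in floor(u - 2):ceiling(u + 2)) {
      x <- u - i
      if (abs(x) >= 2) next
      w <- sinc(x) * sinc(x / 2)
      ic <- min(max(i, 0), n - 1)
      acc <- acc + w * v[ic + 1]
      wsum <- wsum + w
    }
    out[j] <- acc / wsum
  }
  out
}

# Independent closed-form oracle for a single pool under RF sampling:
# amplitude_i = M0 sin(theta) cos(theta)^(i-1) exp(-(i-1) TR / T1).
closedFormAmplitudes <- function(M0, thetaDeg, TRs, T1, nT) {
  th <- thetaDeg * pi / 180
  i <- seq_len(nT)
  M0 * sin(th) * cos(th)^(i - 1) * exp(-(i - 1) * TRs / T1)
}
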