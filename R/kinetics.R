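# Physical constants (SI)
HBAR <- 1.054571817e-34
KBOLTZ <- 1.380649e-23

#' Flip-angle-corrected mono-exponential T1 fit
#'
#' In a dynamic hyperpolarized acquisition each excitation consumes part of
#' the magnetization, so the raw peak integrals decay faster than T1. The
#' integrals are first corrected for flip angle,
#' `corrected_i = area_i / (sin(theta) cos(theta)^(i-1))`, and the corrected
#' series is fitted with the mono-exponential
#' `A exp(-(i-1) TR / T1)`. The fit is performed on the log scale (linear
#' least squares, deterministic); when any corrected value is non-positive
#' (noisy data) it falls back to bounded nonlinear least squares initialised
#' from the positive subset.
#'
#' @param areas peak integrals per acquisition, in acquisition order
#' @param thetaDeg excitation flip angle, degrees, in (0, 90)
#' @param TRs repetition time, seconds
#' @return a list with `T1s`, `amplitude0`, `rmse` (on the corrected scale),
#'   `thetaDeg`, `TRs` and `method`
#' @export
flipAngleCorrectedT1Fit <- function(areas, thetaDeg, TRs) {
  stopIfNot(length(areas) >= 3, "need at least 3 timepoints to fit T1")
  stopIfNot(thetaDeg > 0, "thetaDeg must be > 0")
  if (thetaDeg >= 90 && length(areas) > 1)
    stop("thetaDeg = 90 leaves no longitudinal magnetization after the first pulse; T1 cannot be fitted",
         call. = FALSE)
  if (all(areas == 0)) stop("all-zero signal: nothing to fit", call. = FALSE)
  theta <- degToRad(thetaDeg)
  i <- seq_along(areas)
  corrected <- areas / (sin(theta) * cos(theta)^(i - 1))
  t <- (i - 1) * TRs

  fitted <- NULL
  if (all(corrected > 0)) {
    fit <- lm(log(corrected) ~ t)
    slope <- coef(fit)[[2]]
    if (slope < 0) {
      T1 <- -1 / slope
      A0 <- exp(coef(fit)[[1]])
      fitted <- list(T1s = T1, amplitude0 = A0, method = "log-linear")
    }
  }
  if (is.null(fitted)) {
    pos <- corrected > 0
    stopIfNot(sum(pos) >= 2, "too few positive corrected values to fit T1")
    init <- c(A = max(corrected[pos]), T1 = max(t[2], 1))
    obj <- function(p) sum((corrected - p[1] * exp(-t / p[2]))^2)
    opt <- optim(init, obj, method = "L-BFGS-B",
                 lower = c(1e-12, 1e-3), upper = c(Inf, 1e5))
    fitted <- list(T1s = opt$par[[2]], amplitude0 = opt$par[[1]],
                   method = "nls-fallback")
  }
  resid <- corrected - fitted$amplitude0 * exp(-t / fitted$T1s)
  c(fitted[c("T1s", "amplitude0")],
    list(rmse = sqrt(mean(resid^2)), thetaDeg = thetaDeg, TRs = TRs,
         method = fitted$method))
}

aucByMetabolite <- function(times, areas) {
  vapply(colnames(areas), function(m) trapz(times, areas[, m]), numeric(1))
}

#' Product/substrate AUC ratio metrics
#'
#' Computes the trapezoidal area under the dynamic curve (AUC) of each
#' metabolite and the flux surrogates used for the gluconolactone system:
#' 6PG AUC normalised to the delta-gluconolactone AUC (`ratioDGL`) and to
#' total gluconolactone, delta plus gamma (`ratioTotal`). When `cellCount`
#' is given the ratios are additionally divided by it.
#'
#' @param times acquisition times, seconds
#' @param areas timepoints x metabolites area matrix with columns named
#'   `6PG`, `dGL` and (for `ratioTotal`) `gGL`; alternatively pass the list
#'   returned by [areaTimecourse()] as `times`
#' @param cellCount optional number of cells for per-cell normalisation
#' @return list with `auc6PG`, `aucDGL`, `aucGGL`, `ratioDGL`, `ratioTotal`
#'   and `perCellScale`
#' @export
computeRatioMetrics <- function(times, areas = NULL, cellCount = NULL) {
  if (is.list(times) && is.null(areas)) {
    areas <- times$areas; times <- times$times
  }
  stopIfNot(all(c("6PG", "dGL") %in% colnames(areas)),
            "areas must have '6PG' and 'dGL' columns")
  auc <- aucByMetabolite(times, areas)
  aucGGL <- if ("gGL" %in% names(auc)) auc[["gGL"]] else NA_real_
  if (auc[["dGL"]] <= 0)
    stop("substrate (dGL) AUC is zero: ratio undefined", call. = FALSE)
  scale <- if (is.null(cellCount)) 1 else cellCount
  ratioTotal <- if (is.na(aucGGL)) NA_real_
    else auc[["6PG"]] / (auc[["dGL"]] + aucGGL) / scale
  list(auc6PG = auc[["6PG"]], aucDGL = auc[["dGL"]], aucGGL = aucGGL,
       ratioDGL = auc[["6PG"]] / auc[["dGL"]] / scale,
       ratioTotal = ratioTotal,
       perCellScale = if (is.null(cellCount)) NA_real_ else cellCount)
}

#' Thermal equilibrium 13C polarization
#'
#' Boltzmann polarization of a spin-1/2 13C nucleus,
#' `P = tanh(hbar gamma B0 / (2 kB T))` -- about 1.01e-5 at 11.7 T and
#' 298 K. This is the denominator of the hyperpolarized enhancement factor.
#'
#' @param B0T static field, tesla
#' @param temperatureK sample temperature, kelvin (default 298)
#' @param gamma13C 13C gyromagnetic ratio, rad/s/T
#' @return polarization as a fraction
#' @export
thermalPolarization <- function(B0T, temperatureK = 298,
                                gamma13C = GAMMA_13C_RAD) {
  stopIfNot(temperatureK > 0, "temperatureK must be > 0")
  stopIfNot(B0T >= 0, "B0T must be >= 0")
  tanh(HBAR * gamma13C * B0T / (2 * KBOLTZ * temperatureK))
}

#' Back-calculate percent polarization at dissolution
#'
#' Compares the first spectrum of the hyperpolarized dynamic set to a
#' thermal equilibrium reference of the same sample, correcting each for
#' flip angle and the thermal spectrum for its number of summed averages,
#' then decays the enhancement back through the dissolution-to-acquisition
#' delay:
#' \deqn{E_{acq} = \frac{S_{hp}/\sin\theta_{hp}}{S_{th}/(NA\,\sin\theta_{th})},\quad
#'       E = E_{acq} e^{delay/T1},\quad P_0 = 100\, E\, P_{th}.}
#' The result is invariant to the common signal scale of the two spectra.
#'
#' @param hpFirstArea peak area of the first hyperpolarized spectrum
#' @param thArea peak area of the thermal reference spectrum (summed over
#'   averages)
#' @param thetaHpDeg,thetaThDeg flip angles of the two acquisitions, degrees
#' @param nAveragesTh number of summed thermal averages
#' @param delayS dissolution-to-first-acquisition delay, seconds
#' @param T1s decay constant used for the back-calculation, seconds
#' @param B0T,temperatureK conditions of the thermal reference
#' @return list with `P0Percent`, `enhancement` (at dissolution),
#'   `enhancementAtAcq`, `delayS`, `T1UsedS` and `PTh`
#' @export
backCalculatePolarization <- function(hpFirstArea, thArea, thetaHpDeg,
                                      thetaThDeg = 90, nAveragesTh = 16,
                                      delayS = 0, T1s, B0T,
                                      temperatureK = 298) {
  stopIfNot(thArea > 0, "thermal reference area must be > 0")
  stopIfNot(delayS >= 0, "delayS must be >= 0")
  stopIfNot(T1s > 0, "T1s must be > 0")
  PTh <- thermalPolarization(B0T, temperatureK)
  eAcq <- (hpFirstArea / sin(degToRad(thetaHpDeg))) /
          (thArea / (nAveragesTh * sin(degToRad(thetaThDeg))))
  enh <- eAcq * exp(delayS / T1s)
  P0 <- 100 * enh * PTh
  if (P0 > 100)
    warning("back-calculated polarization exceeds 100%; check inputs", call. = FALSE)
  list(P0Percent = P0, enhancement = enh, enhancementAtAcq = eAcq,
       delayS = delayS, T1UsedS = T1s, PTh = PTh)
}
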