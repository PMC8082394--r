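---
title: "Methods: hyperpolarized gluconolactone MRS simulation and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperpolarized gluconolactone MRS simulation and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpGlucoMRS)
```

## The physical model

Hyperpolarized δ-[1-¹³C]gluconolactone is a probe of the oxidative
pentose phosphate pathway: the δ anomer is phosphorylated and hydrolyzed
by 6-phosphogluconolactonase to [1-¹³C]6-phosphogluconate (6PG), while
the γ anomer, present in aqueous solution through slow anomeric
equilibrium, is not a substrate for this route. The simulator therefore
evolves three longitudinal magnetization pools — δ-gluconolactone
(173.8 ppm), γ-gluconolactone (177 ppm) and 6PG (178.6 ppm) — under

$$\frac{dM}{dt} = A\,M + b\,u(t),$$

where $A$ combines metabolite-specific T1 decay, δ↔γ exchange
($k_{\delta\gamma}, k_{\gamma\delta}$) and δ→6PG conversion
($k_{PGLS}$), $b$ partitions the substrate input between the anomers,
and $u(t)$ is the delivery function. At each acquisition, pool $p$ emits
a transverse amplitude $M_p \sin\theta_p$ and retains
$M_p \cos\theta_p$; pulses are idealized as instantaneous and relaxation
during the readout is neglected (the repetition time of 3 s dwarfs the
acquisition window — the standard approximation for hyperpolarized MR).
Chemical-shift evolution during pulses, B0/B1 inhomogeneity, slice
profiles and k-space EPSI encoding are out of scope: voxel spectra are
synthesized directly.

Because the system is linear, trajectories are propagated by exact
piecewise matrix exponentials rather than an adaptive ODE solver: each
inter-pulse interval (split at bolus breakpoints, with the smoothed
boxcar input handled by augmenting the state with the input's
exponential mode) is advanced by one `expm` evaluation. The result
carries no integration error beyond machine precision, is fully
deterministic, and is cheap enough for the power simulations in the
test suite. The single-pool closed form
$M_0 \sin\theta\,(\cos\theta)^{i-1} e^{-(i-1)TR/T_1}$ serves as an
independent oracle in the tests.

### Delivery modes

* **Cell mode** (`bolusDurationS = 0`): the substrate magnetization
  `M0` is present at time zero, split δ:γ by `deltaGammaRatio0`.
* **In vivo mode**: `M0` enters through a boxcar of 15 s (the injection
  duration) whose edges are smoothed by a 2 s exponential, a minimal
  model of dispersion in the delivery line and vasculature. The
  smoothing tail is truncated four time constants after the boxcar ends
  so that *no input occurs after the bolus* holds exactly; this drops
  about 0.2% of the input mass.

### Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| shifts δ/γ/6PG | 173.8 / 177 / 178.6 | ppm | published positions |
| flip angles (in vivo) | 3.4 / 12 / 15.3 | deg | spectral-spatial EPSI excitation; small on the substrate to preserve it, large on the product |
| flip angle (cell, 11.7 T) | 13 | deg | single-pulse spectrometer acquisition |
| TR | 3 | s | temporal resolution of the dynamic acquisitions |
| spectral axis | 128 points over 20 ppm | — | in vivo spectral resolution (finer grids used where tests need sub-linewidth sampling) |
| substrate T1 | 31.7 (3 T), 15.7 (11.7 T) | s | measured solution values |
| γ T1 | equal to δ | s | not separately reported; anomers are chemically near-identical |
| 6PG T1 | 25 (3 T), 12 (11.7 T) | s | chosen shorter than the substrate (phosphorylated species relax faster); not reported |
| linewidths | 4 (solution/cell), 8 (in vivo) | Hz | plausible shimmed-solution vs in vivo widths; not reported |
| δ:γ partition | 0.6 : 0.4 | — | anomeric equilibrium favors δ; the in-solution ratio is not reported, so this is a declared convention |
| exchange rates | 0.005 / 0.005 | 1/s | "slow exchange" regime; not reported |
| phantom k (tumor / brain) | 0.02 / 0.005 | 1/s | four-fold conversion contrast driving the tumor-vs-contralateral effect |
| voxel geometry | 4.375 × 4.375 × 8 | mm | native EPSI resolution |

All of these are constructor arguments and can be overridden; the
defaults define the reference study conditions used by the tests.

## Spectral rendering and processing

Rendered lines are not continuous Lorentzians evaluated on the grid but
the DFT of the finite sampled free-induction decay (computed in closed
geometric form, with the first FID point half-weighted to suppress the
baseline offset). This is the lineshape an actual Fourier-transformed
acquisition produces, and it matters on the coarse in vivo axis: the
20 ppm / 128 point grid samples a 4–8 Hz line near or below its width,
and only the discrete-FID form keeps peak integrals accurate there. The
real part holds the absorption mode; quantification uses the real part
throughout, matching the noise definition (standard deviation of the
real part in a signal-free voxel).

**Apodization** multiplies the FID by $e^{-\pi\,lb\,t}$ (default
5 Hz), which adds exactly `lb` to a Lorentzian FWHM and preserves the
spectrum sum exactly (the first FID point is unweighted). **Peak
integration** is the trapezoidal integral of the real part over a
closed ppm window; default windows are ±0.5 ppm around each shift,
which keeps the γ and 6PG windows (1.6 ppm apart) disjoint at 3 T
linewidths. Window widths are a declared convention — they are not part
of the published record. With narrow solution linewidths roughly 1% of
the γ line's area leaks into the 6PG window through Lorentzian tails;
this is inherent to window integration (as in any spectroscopy
software) and is visible in the tests as a small nonzero "6PG" area at
zero conversion. **Peak detection** finds local maxima above a
threshold (a multiple of the noise SD, or absolute for noiseless
spectra) and refines centres by three-point parabolic interpolation.
Only zero-order phasing considerations apply: synthetic data are
rendered in absorption mode and baselines are flat, so no baseline
correction is implemented.

## Scalar quantification

The **T1 fit** divides each area by $\sin\theta(\cos\theta)^{i-1}$ and
fits $A e^{-(i-1)TR/T_1}$, by linear least squares in log space
(deterministic, exact on conforming input); if noise drives any
corrected value non-positive it falls back to bounded nonlinear least
squares initialised from the positive subset. Metabolism is neglected
in the substrate T1 fit — solution QC data contain no enzyme.

**Percent polarization** compares the first hyperpolarized spectrum to
a thermal-equilibrium reference after flip-angle and
number-of-averages correction, then decays the enhancement back through
the dissolution-to-acquisition delay:
$P_0 = 100\,E_{acq}\,e^{delay/T_1}\,P_{th}$ with
$P_{th} = \tanh(\hbar\gamma B_0/2k_BT)$. Two conventions had to be
declared because they are not part of the record: the thermal reference
temperature defaults to 298 K, and the thermal spectrum uses the
*summed* number-of-averages convention (amplitude ∝ NA), mirrored
exactly between the renderer and the back-calculation so round trips
are exact. Consequently the enhancement factor is reproducible only to
its order of magnitude — the exact delay (18–25 s) and temperature
shift it by tens of percent.

**AUC ratios** are trapezoidal time-integrals of the product over the
substrate, with either the δ-only or the total (δ+γ) denominator, and
optional division by cell count. Rate constants are deliberately not
fitted — the AUC ratio is the flux surrogate.

## Spatial analysis

Per-voxel SNR grids sum the dynamic spectra over all timepoints before
measuring peak height (the acquisition record does not state whether
summed or peak-timepoint spectra were used; time-summing is declared
here, and the noise SD is scaled by $\sqrt{n_t}$ accordingly). Grids
are interpolated 8×8 → 256×256 with the Lanczos-2 kernel
$L(x)=\mathrm{sinc}(x)\,\mathrm{sinc}(x/2)$, $|x|<2$, applied
separably with the half-pixel centre convention, edge clamping and
per-pixel weight normalization (constant maps stay constant to 1e−9);
the implementation is pinned against a direct 1-D oracle in the tests.
Ratio maps divide the *separately interpolated* SNR maps
(interpolate-then-divide — the interpolated, noise-normalized maps are
the inputs to the ratio), masking pixels where the substrate SNR falls
below a floor (default 5; the validity floor is a package convention).
ROIs may be native voxel sets or sub-voxel boxes on the interpolated
map — e.g. a 1.875 × 1.875 × 8 mm box realizing the 28.13 mm³
assessment volume; any box of that stated volume is accepted, since its
shape is not part of the record. Tumor volume is the classic
contour-area sum times slice thickness.

## Group statistics

Welch's unequal-variance two-tailed t-test is implemented directly from
the formulas with the t CDF as the only numerical primitive, and is
cross-checked against `stats::t.test` in the suite. No multiple-testing
correction is applied — each endpoint is tested at α = 0.05 — and
reports flag this. Day-to-day in vivo comparisons are unpaired, as the
analysis is described. Significance tiers are rendered as `*`/`**`/`***`
at 0.05/0.01/0.001.

## What the generator does and does not emulate

The synthetic data reproduce the statistical structure the analysis
assumes: three Lorentzian resonances with metabolite-specific T1 and
flip angles, first-order conversion and exchange, bolus or pre-loaded
delivery, i.i.d. complex Gaussian noise, signal-free outside-the-brain
voxels, and a tumor with elevated conversion. They do **not** emulate
B0 drift, lineshape distortions, baseline roll, partial-volume mixing
at tumor margins, perfusion heterogeneity, or inter-animal biological
variability (replicates differ only by measurement noise). Passing
tests therefore demonstrate correctness of the quantification chain
under its stated assumptions, not robustness to every artifact of real
scanner data.

One consequence worth noting: with the four-fold conversion contrast of
the reference phantom and uniform substrate delivery, the tumor's
higher conversion measurably depletes its substrate pool, so simulated
substrate-SNR comparisons between tumor and contralateral brain come
out significant — whereas in real data substrate SNR is dominated by
delivery and such comparisons are typically non-significant. The
workflow reports the substrate comparison either way; interpreting it
requires keeping this divergence in mind.

## Problem sizes and numerical tolerances

The test suite and acceptance script run desk-scale problems chosen to
exercise every code path: 20–40 timepoint dynamic series, 8×8 phantoms
with 128-point spectra, 20-cohort power simulations at n = 6 animals,
and a 2000-replicate null calibration of the Welch test. Closed-form
oracle agreement is asserted at 1e−6 relative, T1 recovery at 1e−4,
polarization round trips at 1e−6, Lanczos oracle agreement at 1e−12,
and detection geography at 0.02–0.05 ppm (the parabolic-refinement
limit on a 0.01 ppm grid). Seeds are explicit everywhere; identical
configuration and seed give bit-identical datasets and reports.

## Known limitations

* The δ:γ equilibrium ratio, exchange rates, in vivo linewidths and
  6PG/γ T1 values are declared defaults, not measured quantities.
* Full Bloch–McConnell dynamics, multi-exponential relaxation and
  k-space reconstruction are out of scope.
* The enhancement factor is order-of-magnitude reproducible only (see
  above).
* The on-disk container is a plain-text directory format (JSON metadata
  plus CSV arrays) designed for portability and versionability rather
  than I/O speed; very large EPSI datasets would warrant a binary
  container.
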