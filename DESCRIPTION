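Package: hpGlucoMRS
Title: Simulation and Quantification of Hyperpolarized
    delta-[1-13C]Gluconolactone MRS and EPSI Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dynamic hyperpolarized 13C magnetic resonance
    spectroscopy of the delta-[1-13C]gluconolactone / 6-phosphogluconate
    (6PG) system. Simulates multi-pool hyperpolarized magnetization
    dynamics (T1 decay, per-metabolite RF depletion, anomer exchange,
    enzymatic conversion, bolus delivery) for single-voxel and
    echo-planar spectroscopic imaging (EPSI) acquisitions; processes
    dynamic spectra (exponential line broadening, peak integration,
    peak detection, noise and SNR estimation); quantifies
    flip-angle-corrected T1, thermal polarization, percent polarization
    at dissolution and product/substrate AUC ratios; builds Lanczos-2
    interpolated metabolite SNR and ratio heatmaps with ROI statistics;
    and compares groups with Welch's unequal-variance t-test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
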