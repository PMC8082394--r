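#' Write a peak table to CSV
#'
#' Flat interoperability export: one row per (timepoint, metabolite) with
#' columns `time_s`, `metabolite`, `area`, `height`, `snr`.
#'
#' @param peakTable data.frame from [peakTimecourse()]
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writePeakTable <- function(peakTable, path) {
  write.csv(peakTable, path, row.names = FALSE)
  invisible(path)
}

#' Write a QC report as JSON
#'
#' @param qc result of [runQC()]
#' @param path output JSON path
#' @return the path, invisibly
#' @export
writeQCReport <- function(qc, path) {
  jsonlite::write_json(
    list(T1_s = qc$t1Fit$T1s, rmse = qc$t1Fit$rmse,
         P0_percent = qc$polarization$P0Percent,
         enhancement = qc$polarization$enhancement,
         settings = qc$settings,
         note = "no multiple-testing correction is applied anywhere in this package"),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

flattenComplex <- function(arr) {
  data.frame(re = as.vector(Re(arr)), im = as.vector(Im(arr)))
}

#' Save a spectral dataset to a plain-text directory container
#'
#' The on-disk container is a directory holding `meta.json` (class, axis,
#' timing, geometry, masks, provenance) and `values.csv` (real and
#' imaginary parts of the complex data in column-major order, dimensions
#' recorded in the metadata). Plain-text throughout, so datasets survive
#' versioning and remain readable without this package.
#'
#' @param x a [DynamicSpectrumSeries] or [EPSIDataset]
#' @param dir target directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeSpectraDataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  isEPSI <- is(x, "EPSIDataset")
  vals <- if (isEPSI) x@spectra else x@spectra
  meta <- list(
    class = class(x)[1], dims = dim(vals), axisPpm = x@axisPpm,
    TRs = x@TRs, t0s = x@t0s, meta = x@meta,
    geometry = if (isEPSI) x@geometry else NULL,
    masks = if (isEPSI) lapply(x@masks, function(m)
      list(dims = dim(m), values = as.vector(m))) else NULL)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(dir, "meta.json"))
  write.csv(flattenComplex(vals), file.path(dir, "values.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a spectral dataset from the plain-text directory container
#'
#' @param dir directory written by [writeSpectraDataset()]
#' @return a [DynamicSpectrumSeries] or [EPSIDataset]
#' @export
readSpectraDataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  df <- read.csv(file.path(dir, "values.csv"))
  vals <- array(complex(real = df$re, imaginary = df$im),
                dim = unlist(meta$dims))
  metaList <- as.list(meta$meta)
  if (!is.null(metaList$flipAnglesDeg))
    metaList$flipAnglesDeg <- unlist(metaList$flipAnglesDeg)
  if (identical(meta$class, "EPSIDataset")) {
    masks <- lapply(meta$masks, function(m)
      matrix(as.logical(unlist(m$values)), nrow = unlist(m$dims)[1]))
    EPSIDataset(vals, meta$axisPpm, meta$TRs, meta$t0s,
                geometry = as.list(meta$geometry), masks = masks,
                meta = metaList)
  } else {
    DynamicSpectrumSeries(vals, meta$axisPpm, meta$TRs, meta$t0s,
                          meta = metaList)
  }
}

#' Plot a heatmap
#'
#' Displays a [HeatMap] with `graphics::image`; `NaN` (masked) pixels are
#' left blank.
#'
#' @param map a [HeatMap]
#' @param main title
#' @param col color palette
#' @return invisibly, the map
#' @export
#' @importFrom graphics image
#' @importFrom grDevices hcl.colors
plotHeatMap <- function(map, main = map@kind, col = hcl.colors(64, "Inferno")) {
  v <- map@values
  image(t(v[nrow(v):1, , drop = FALSE]), main = main, col = col,
        axes = FALSE, useRaster = TRUE)
  invisible(map)
}
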