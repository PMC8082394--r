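#' Time-summed metabolite SNR on the native EPSI grid
#'
#' For each voxel the dynamic spectra are summed over time and the peak
#' height of the real part within the metabolite window is divided by the
#' noise level of the summed spectrum. Noise is estimated as the standard
#' deviation of the real part of the signal in the designated voxel outside
#' the brain, scaled by `sqrt(nTimepoints)` for the time-summed spectrum.
#'
#' @param ds an [EPSIDataset]
#' @param window a [PeakWindow]
#' @param noiseVoxel `c(row, col)` of a voxel under the outside mask
#' @return list with `values` (rows x cols SNR matrix), `sigma` (per-single-
#'   spectrum noise SD) and `sigmaSummed`
#' @export
metaboliteSNRGrid <- function(ds, window, noiseVoxel) {
  ns <- estimateNoise(ds, voxel = noiseVoxel)
  stopIfNot(ns$sigma > 0, "estimated noise is zero; SNR undefined")
  d <- dim(ds@spectra)
  sigmaSummed <- ns$sigma * sqrt(d[1])
  idx <- windowPoints(ds@axisPpm, window)
  summed <- apply(Re(ds@spectra), c(2, 3, 4), sum)  # rows x cols x points
  vals <- apply(summed[, , idx, drop = FALSE], c(1, 2), max)
  list(values = vals / sigmaSummed, sigma = ns$sigma,
       sigmaSummed = sigmaSummed)
}

# Lanczos-2 kernel: sinc(x) * sinc(x/2) on |x| < 2.
lanczos2Kernel <- function(x) {
  k <- numeric(length(x))
  inside <- abs(x) < 2
  xi <- x[inside]
  s <- function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u))
  k[inside] <- s(xi) * s(xi / 2)
  k
}

# 1-D Lanczos-2 resampling matrix (outLen x inLen), half-pixel centre
# convention with edge clamping and per-row weight normalization (so
# constant input maps to constant output).
lanczos2Matrix <- function(inLen, outLen) {
  scale <- inLen / outLen
  W <- matrix(0, outLen, inLen)
  for (j in seq_len(outLen)) {
    u <- (j - 0.5) * scale - 0.5          # 0-based input coordinate
    i <- floor(u - 2):ceiling(u + 2)
    w <- lanczos2Kernel(u - i)
    i <- pmin(pmax(i, 0), inLen - 1)      # clamp at the edges
    keep <- w != 0
    for (m in which(keep)) W[j, i[m] + 1] <- W[j, i[m] + 1] + w[m]
  }
  sweep(W, 1, rowSums(W), `/`)
}

#' Lanczos-2 separable image resampling
#'
#' Upsamples a matrix with the Lanczos-2 windowed-sinc kernel
#' `L(x) = sinc(x) sinc(x/2)` for `|x| < 2`, applied separably along rows
#' and columns with the half-pixel centre convention, edge clamping and
#' weight normalisation (constant input gives constant output). The default
#' target reproduces the native 8 x 8 acquisition matrix interpolated to
#' 256 x 256 for display.
#'
#' @param m numeric matrix (all finite)
#' @param outShape target `c(rows, cols)` (default `c(256, 256)`)
#' @return resampled matrix
#' @export
lanczos2Resize <- function(m, outShape = c(256, 256)) {
  if (any(!is.finite(m)))
    stop("lanczos2Resize requires finite input; mask NaN regions first", call. = FALSE)
  Wr <- lanczos2Matrix(nrow(m), outShape[1])
  Wc <- lanczos2Matrix(ncol(m), outShape[2])
  Wr %*% m %*% t(Wc)
}

#' Interpolated metabolite SNR heatmap
#'
#' [metaboliteSNRGrid()] followed by [lanczos2Resize()]; the standard
#' display product for a single metabolite.
#'
#' @inheritParams metaboliteSNRGrid
#' @param outShape interpolation target (default 256 x 256)
#' @return a [HeatMap] of kind `"snr"`
#' @export
metaboliteSNRMap <- function(ds, window, noiseVoxel, outShape = c(256, 256)) {
  g <- metaboliteSNRGrid(ds, window, noiseVoxel)
  HeatMap(lanczos2Resize(g$values, outShape), kind = "snr",
          sourceMetabolites = window@name, noiseSigma = g$sigma)
}

#' Product/substrate ratio map
#'
#' Elementwise ratio of two SNR maps wherever the substrate map reaches the
#' SNR floor; `NaN` elsewhere. Computed from the separately interpolated
#' maps (interpolate-then-divide), the order recorded in the result. The
#' ratio is invariant to a common rescaling of both maps.
#'
#' @param productMap,substrateMap [HeatMap]s (or plain matrices) of the same
#'   shape
#' @param snrFloor substrate validity threshold (default 5)
#' @return a [HeatMap] of kind `"ratio"`
#' @export
ratioMap <- function(productMap, substrateMap, snrFloor = 5) {
  pm <- if (is(productMap, "HeatMap")) productMap@values else productMap
  sm <- if (is(substrateMap, "HeatMap")) substrateMap@values else substrateMap
  if (!identical(dim(pm), dim(sm)))
    stop("product and substrate maps must have the same shape", call. = FALSE)
  out <- pm / sm
  out[!(sm >= snrFloor)] <- NaN
  labs <- c(if (is(productMap, "HeatMap")) productMap@sourceMetabolites,
            if (is(substrateMap, "HeatMap")) substrateMap@sourceMetabolites)
  HeatMap(out, kind = "ratio",
          sourceMetabolites = if (is.null(labs)) character() else labs)
}

# Map a native-grid logical mask onto an interpolated pixel grid by nearest
# native voxel of each pixel centre.
upsampleMask <- function(mask, outShape) {
  rIdx <- pmin(pmax(floor(((seq_len(outShape[1]) - 0.5) * nrow(mask)) / outShape[1]) + 1, 1), nrow(mask))
  cIdx <- pmin(pmax(floor(((seq_len(outShape[2]) - 0.5) * ncol(mask)) / outShape[2]) + 1, 1), ncol(mask))
  mask[rIdx, cIdx, drop = FALSE]
}

#' Quantify a map within a region of interest
#'
#' The ROI may be given as a set of native-grid voxels (`voxels`, a two-
#' column row/col index matrix, or `mask`, a logical matrix matching the
#' map), or -- on an interpolated map -- as a square sub-voxel box of stated
#' side length (`boxMm = c(rowCenterMm, colCenterMm, sideMm)`), which
#' supports assessment volumes smaller than one native voxel (e.g. a
#' 1.875 x 1.875 x 8 mm box of 28.13 mm3).
#'
#' @param values numeric matrix: a native grid or the values of a [HeatMap]
#' @param roi list with one of `voxels`, `mask`, `boxMm` (see above)
#' @param geometry list with `voxelSizeMm` (native, length 2),
#'   `sliceThicknessMm` and `gridShapeNative` (defaults to `dim(values)`)
#' @return list with `mean`, `sd`, `nVoxels` (native voxels covered),
#'   `nPixels` (map pixels used) and `roiVolumeMm3`
#' @export
roiQuantify <- function(values, roi, geometry) {
  if (is(values, "HeatMap")) values <- values@values
  gn <- geometry$gridShapeNative
  if (is.null(gn)) gn <- dim(values)
  vx <- geometry$voxelSizeMm
  thk <- geometry$sliceThicknessMm
  pixMm <- vx * gn / dim(values)

  if (!is.null(roi$boxMm)) {
    rc <- roi$boxMm
    rowMm <- (seq_len(nrow(values)) - 0.5) * pixMm[1]
    colMm <- (seq_len(ncol(values)) - 0.5) * pixMm[2]
    inR <- abs(rowMm - rc[1]) <= rc[3] / 2
    inC <- abs(colMm - rc[2]) <= rc[3] / 2
    sel <- outer(inR, inC)
    vol <- rc[3]^2 * thk
    nVox <- length(unique(ceiling(rowMm[inR] / vx[1]))) *
            length(unique(ceiling(colMm[inC] / vx[2])))
  } else if (!is.null(roi$mask)) {
    m <- roi$mask
    if (identical(dim(m), dim(values))) sel <- m
    else sel <- upsampleMask(m, dim(values))
    nVox <- sum(m)
    vol <- nVox * vx[1] * vx[2] * thk
  } else if (!is.null(roi$voxels)) {
    m <- matrix(FALSE, gn[1], gn[2])
    m[roi$voxels] <- TRUE
    sel <- if (identical(as.integer(gn), dim(values))) m
           else upsampleMask(m, dim(values))
    nVox <- sum(m)
    vol <- nVox * vx[1] * vx[2] * thk
  } else stop("roi must contain 'voxels', 'mask' or 'boxMm'", call. = FALSE)

  v <- values[sel]
  v <- v[is.finite(v)]
  if (!length(v)) stop("ROI is empty (or entirely masked out)", call. = FALSE)
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       nVoxels = nVox, nPixels = length(v), roiVolumeMm3 = vol)
}

#' Tumor volume from manual contours
#'
#' Sum of the contoured tumor areas in each slice multiplied by the slice
#' thickness.
#'
#' @param areasCm2 per-slice contoured areas, cm2
#' @param sliceThicknessCm slice thickness, cm
#' @return volume in cm3
#' @export
tumorVolume <- function(areasCm2, sliceThicknessCm) {
  if (!length(areasCm2)) stop("no contoured slices", call. = FALSE)
  if (any(areasCm2 < 0)) stop("contour areas must be >= 0", call. = FALSE)
  stopIfNot(sliceThicknessCm > 0, "sliceThicknessCm must be > 0")
  sum(areasCm2) * sliceThicknessCm
}

#' Read a contour CSV (slice_index, area_cm2) and compute tumor volume
#'
#' @param path CSV file with columns `slice_index` and `area_cm2`
#' @param sliceThicknessCm slice thickness, cm
#' @return volume in cm3
#' @export
#' @importFrom utils read.csv write.csv
tumorVolumeFromCSV <- function(path, sliceThicknessCm) {
  df <- read.csv(path)
  stopIfNot(all(c("slice_index", "area_cm2") %in% names(df)),
            "contour CSV needs columns slice_index and area_cm2")
  tumorVolume(df$area_cm2, sliceThicknessCm)
}

regionMetricsOneDay <- function(ds, windows, noiseVoxel, rois,
                                snrFloor = 5, outShape = c(256, 256)) {
  snrMaps <- lapply(windows, metaboliteSNRMap, ds = ds,
                    noiseVoxel = noiseVoxel, outShape = outShape)
  totalSub <- HeatMap(snrMaps[["dGL"]]@values + snrMaps[["gGL"]]@values,
                      kind = "snr", sourceMetabolites = c("dGL", "gGL"),
                      noiseSigma = snrMaps[["dGL"]]@noiseSigma)
  maps <- list(snr6PG = snrMaps[["6PG"]], snrDGL = snrMaps[["dGL"]],
               snrGGL = snrMaps[["gGL"]],
               ratioDGL = ratioMap(snrMaps[["6PG"]], snrMaps[["dGL"]], snrFloor),
               ratioTotal = ratioMap(snrMaps[["6PG"]], totalSub, snrFloor))
  geom <- c(ds@geometry, list(gridShapeNative = dim(ds@spectra)[2:3]))
  rows <- list()
  for (rg in names(rois)) for (metric in names(maps)) {
    st <- roiQuantify(maps[[metric]], list(mask = rois[[rg]]), geom)
    rows[[length(rows) + 1L]] <- data.frame(
      region = rg, metric = metric, mean = st$mean, sd = st$sd,
      nVoxels = st$nVoxels, roiVolumeMm3 = st$roiVolumeMm3)
  }
  list(table = do.call(rbind, rows), maps = maps)
}

#' Longitudinal per-day ROI table
#'
#' Runs the full mapping pipeline (time-summed SNR grids, Lanczos-2
#' interpolation, ratio maps, ROI statistics) for each day's dataset and
#' stacks the results into a tidy day x region x metric table.
#'
#' @param datasetsByDay named list of [EPSIDataset] (names are day labels)
#' @param windows named list of [PeakWindow] containing `6PG`, `dGL`, `gGL`
#' @param noiseVoxel `c(row, col)` outside-brain voxel
#' @param rois named list of native-grid logical masks
#' @param snrFloor substrate SNR floor for ratio validity
#' @return data.frame with columns `day`, `region`, `metric`, `mean`, `sd`,
#'   `nVoxels`, `roiVolumeMm3`
#' @export
longitudinalTable <- function(datasetsByDay, windows, noiseVoxel, rois,
                              snrFloor = 5) {
  geoms <- lapply(datasetsByDay, function(d) d@geometry)
  if (length(unique(vapply(geoms, function(g)
    paste(unlist(g), collapse = ","), character(1)))) != 1L)
    stop("datasets have mismatched geometry across days", call. = FALSE)
  out <- lapply(names(datasetsByDay), function(day) {
    tb <- regionMetricsOneDay(datasetsByDay[[day]], windows, noiseVoxel,
                              rois, snrFloor)$table
    cbind(day = day, tb)
  })
  do.call(rbind, out)
}
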