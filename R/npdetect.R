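# Nanoparticle localization: in-cell voxels whose RI falls in the
# nanoparticle band (default 1.39-1.41, endpoints inclusive) are flagged,
# grouped into 26-connected accumulations, and counted; the raw band voxel
# count (equivalently its percent of cell voxels) is the relative uptake
# estimate.  Chromatin can also exceed 1.39, so nuclear false positives are
# deliberately left in here and disambiguated by fluorescence (see coloc).

#' Detection parameters
#'
#' @param band_lo,band_hi RI band colorized/counted as nanoparticle
#'   candidate (inclusive endpoints).
#' @param min_component_vox components smaller than this are not listed as
#'   accumulations (raw band counts are reported regardless).
#' @param connectivity 6 or 26.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(band_lo = 1.39, band_hi = 1.41,
                             min_component_vox = 5, connectivity = 26) {
  stopifnot(band_lo < band_hi)
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 min_component_vox = as.integer(min_component_vox),
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

#' Detect the nanoparticle RI band inside a cell
#'
#' @param stack an [ri_stack].
#' @param mask a [cell_mask] on the same grid.
#' @param params a [detection_params()].
#' @return object of class `detection_result`: `band_mask` (logical array,
#'   subset of the cell mask), `band_voxels` (raw count), `band_percent`
#'   (percent of cell voxels), `components` (data frame id / voxel_count /
#'   centroid, only components >= `min_component_vox`), `labels` (integer
#'   array of all band components), `n_components`.  An empty band is a
#'   valid result.
#' @export
detect_band <- function(stack, mask, params = detection_params()) {
  stopifnot(inherits(stack, "ri_stack"), inherits(mask, "cell_mask"),
            inherits(params, "detection_params"))
  if (!identical(dim(stack$voxels), dim(mask$mask))) {
    stop("stack grid does not match mask grid")
  }
  band <- mask$mask & stack$voxels >= params$band_lo &
    stack$voxels <= params$band_hi
  labels <- label_components(band, connectivity = params$connectivity)
  comps <- component_table(labels)
  comps <- comps[comps$voxel_count >= params$min_component_vox, ,
                 drop = FALSE]
  structure(list(band_mask = band,
                 band_voxels = sum(band),
                 band_percent = 100 * mask_fraction(band, mask),
                 components = comps,
                 labels = labels,
                 n_components = nrow(comps),
                 params = params,
                 cell_id = mask$cell_id),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "Band detection '%s': %d voxels in [%.3f, %.3f] (%.4f%% of cell), %d accumulation(s)\n",
    x$cell_id, x$band_voxels, x$params$band_lo, x$params$band_hi,
    x$band_percent, x$n_components))
  invisible(x)
}

#' Red-overlay rendering of the detected band
#'
#' Grayscale min-max scaled RI with band voxels painted pure red, plus a
#' maximum-intensity projection along z for 2-D display.
#'
#' @param stack an [ri_stack].
#' @param band_mask logical array (e.g. `detection_result$band_mask`).
#' @return list with `rgb` (array nz x ny x nx x 3 in `[0, 1]`) and
#'   `projection` (array ny x nx x 3).
#' @export
render_overlay <- function(stack, band_mask) {
  stopifnot(inherits(stack, "ri_stack"), is.logical(band_mask))
  if (!identical(dim(stack$voxels), dim(band_mask))) {
    stop("band mask grid does not match stack grid")
  }
  v <- stack$voxels
  rng <- range(v)
  gray <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  d <- dim(v)
  rgb <- array(0, dim = c(d, 3))
  rgb[, , , 1] <- gray; rgb[, , , 2] <- gray; rgb[, , , 3] <- gray
  idx <- which(band_mask)
  n <- prod(d)
  rgb[idx] <- 1          # red channel
  rgb[idx + n] <- 0      # green
  rgb[idx + 2 * n] <- 0  # blue
  proj_gray <- apply(gray, c(2, 3), max)
  proj_band <- apply(band_mask, c(2, 3), any)
  proj <- array(0, dim = c(d[2], d[3], 3))
  proj[, , 1] <- ifelse(proj_band, 1, proj_gray)
  proj[, , 2] <- ifelse(proj_band, 0, proj_gray)
  proj[, , 3] <- ifelse(proj_band, 0, proj_gray)
  list(rgb = rgb, projection = proj)
}

#' Save an overlay projection as PNG
#'
#' @param overlay result of [render_overlay()].
#' @param file PNG path.
#' @return `file`, invisibly.
#' @export
save_overlay_png <- function(overlay, file) {
  pr <- overlay$projection
  grDevices::png(file, width = dim(pr)[2], height = dim(pr)[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({graphics::par(op); grDevices::dev.off()})
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(pr), 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(file)
}

#' Per-dose uptake summary (mean and SEM of band percent)
#'
#' @param detections data frame with columns `dose` and `band_percent`
#'   (one row per cell), e.g. assembled from [detect_band()] results.
#' @return data frame ordered by dose with columns `dose`, `n`,
#'   `mean_band_percent`, `sem_band_percent`.
#' @export
uptake_by_dose <- function(detections) {
  stopifnot(all(c("dose", "band_percent") %in% names(detections)))
  doses <- sort(unique(detections$dose))
  out <- do.call(rbind, lapply(doses, function(d) {
    v <- detections$band_percent[detections$dose == d]
    if (length(v) < 2) {
      stop(sprintf("dose %s has %d cell(s); SEM undefined (need >= 2)",
                   format(d), length(v)), call. = FALSE)
    }
    data.frame(dose = d, n = length(v), mean_band_percent = mean(v),
               sem_band_percent = stats::sd(v) / sqrt(length(v)))
  }))
  rownames(out) <- NULL
  out
}
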