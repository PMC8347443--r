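# Per-cell delimitation.  The published workflow delimited cells by hand in
# FIJI; here the cell is separated from the medium by a global RI threshold
# (default 1.36, midway between aqueous medium ~1.333 and the cellular
# minimum 1.365), cleaned by morphological closing and hole filling, and
# reduced to its largest 26-connected component.

#' Cell mask container
#'
#' @param mask logical 3-D array (single connected component).
#' @param cell_id identifier.
#' @return object of class `cell_mask`.
#' @export
cell_mask <- function(mask, cell_id = "cell") {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  n <- sum(mask)
  if (n == 0) stop("cell mask is empty")
  structure(list(mask = mask, voxel_count = as.integer(n), cell_id = cell_id),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("Cell mask '%s': %d voxels\n", x$cell_id, x$voxel_count))
  invisible(x)
}

#' Segment the cell from the surrounding medium
#'
#' Thresholds the RI stack, applies morphological closing (ball of
#' `closing_radius_vox`), keeps the largest 26-connected component at least
#' `min_volume_vox` voxels large, and fills internal cavities, yielding a
#' single connected per-cell analysis region.
#'
#' @param stack an [ri_stack].
#' @param ri_threshold RI above which a voxel is considered cellular.
#' @param closing_radius_vox structuring-element radius (voxels); 0 skips
#'   closing.
#' @param min_volume_vox minimum component volume retained.
#' @param cell_id identifier stored in the result.
#' @return a [cell_mask].
#' @export
segment_cell <- function(stack, ri_threshold = 1.36, closing_radius_vox = 2,
                         min_volume_vox = 64, cell_id = "cell") {
  stopifnot(inherits(stack, "ri_stack"))
  fg <- stack$voxels > ri_threshold
  if (!any(fg)) {
    stop(sprintf(
      "empty segmentation: no voxel above RI threshold %g (stack max %.4f)",
      ri_threshold, max(stack$voxels)), call. = FALSE)
  }
  # work inside the foreground bounding box (padded by the closing radius)
  d <- dim(fg)
  bb <- mask_bbox(fg, pad = closing_radius_vox + 1L)
  sub <- fg[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  if (closing_radius_vox > 0) sub <- binary_close(sub, closing_radius_vox)
  labels <- label_components(sub, connectivity = 26)
  sizes <- tabulate(labels[labels > 0L])
  sizes[sizes < min_volume_vox] <- 0L
  if (all(sizes == 0L)) {
    stop(sprintf(
      "empty segmentation: no component reaches min_volume_vox = %d",
      min_volume_vox), call. = FALSE)
  }
  best <- which.max(sizes)
  comp <- labels == best
  dim(comp) <- dim(sub)
  comp <- fill_holes(comp)
  mask <- array(FALSE, dim = d)
  mask[bb[[1]], bb[[2]], bb[[3]]] <- comp
  cell_mask(mask, cell_id = cell_id)
}

#' Fraction of the cell mask covered by a sub-mask
#'
#' The shared denominator of all percent-of-pixels statistics: voxel counts,
#' not physical volume, mirroring pixel-number bookkeeping (anisotropy is
#' deliberately ignored).
#'
#' @param sub logical array on the same grid.
#' @param mask a [cell_mask].
#' @return `count(sub & mask) / voxel_count`, in `[0, 1]`.
#' @export
mask_fraction <- function(sub, mask) {
  stopifnot(inherits(mask, "cell_mask"), is.logical(sub))
  if (!identical(dim(sub), dim(mask$mask))) {
    stop("sub-mask grid does not match cell mask grid")
  }
  if (mask$voxel_count == 0) stop("empty cell mask: fraction undefined")
  sum(sub & mask$mask) / mask$voxel_count
}
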