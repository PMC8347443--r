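#' Label connected components of a 3-D binary mask
#'
#' Flood-fill labelling of the foreground of a logical voxel array under
#' 6- or 26-connectivity (the latter includes edge and corner neighbours and
#' is the convention used throughout the pipeline).
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 or 26.
#' @return Integer array of the same dimension; 0 is background, components
#'   are numbered 1..K in raster-scan discovery order.  The number of
#'   components is attached as attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  .cc_label3d(mask, as.integer(dim(mask)), as.integer(connectivity))
}

# Ball structuring element offsets (index space): all (dz, dy, dx) with
# squared norm <= r^2, excluding the origin-only case r = 0.
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  keep <- g$dz^2 + g$dy^2 + g$dx^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  .binary_dilate3d(mask, as.integer(dim(mask)), ball_offsets(radius))
}

binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  .binary_erode3d(mask, as.integer(dim(mask)), ball_offsets(radius))
}

#' Morphological closing of a 3-D binary mask
#'
#' Dilation followed by erosion with a discrete ball of the given radius
#' (voxel units, isotropic in index space).
#'
#' @param mask logical 3-D array.
#' @param radius structuring-element radius in voxels.
#' @return logical array of the same dimension.
#' @export
binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

#' Fill enclosed cavities of a 3-D binary mask
#'
#' Background voxels not 6-connected to the grid boundary are switched to
#' foreground.
#'
#' @param mask logical 3-D array.
#' @return logical array of the same dimension.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  .fill_holes3d(mask, as.integer(dim(mask)))
}

# axis ranges of the tight bounding box of a mask, padded and clipped
mask_bbox <- function(mask, pad = 0L) {
  d <- dim(mask)
  idx <- which(mask) - 1L
  z <- idx %% d[1]
  rest <- idx %/% d[1]
  y <- rest %% d[2]
  x <- rest %/% d[2]
  lims <- list(range(z), range(y), range(x))
  lapply(1:3, function(a) {
    max(1L, lims[[a]][1] + 1L - pad):min(d[a], lims[[a]][2] + 1L + pad)
  })
}

# data.frame of per-component size and centroid (0-based voxel coordinates)
component_table <- function(labels) {
  k <- attr(labels, "n_components")
  if (is.null(k)) k <- max(0L, max(labels))
  if (k == 0L) {
    return(data.frame(id = integer(), voxel_count = integer(),
                      centroid_z = numeric(), centroid_y = numeric(),
                      centroid_x = numeric()))
  }
  m <- .component_stats3d(labels, as.integer(dim(labels)), as.integer(k))
  data.frame(id = seq_len(k), voxel_count = as.integer(m[, 1]),
             centroid_z = m[, 2], centroid_y = m[, 3], centroid_x = m[, 4])
}
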