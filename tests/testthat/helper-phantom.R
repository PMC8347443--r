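# Scaled-down phantom configurations for fast tests.  Geometry, puncta and
# dose fractions keep the default proportions (the per-cell fluorescence
# calibration is grid-size independent in expectation); only the grid and
# the physical cell size shrink.

# ~1/8 of the default voxel count; used for cohort-level tests
phantom_config_small <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(48L, 128L, 128L),
         cell_semiaxes_nm = c(2750, 6500, 8000),
         nucleus_semiaxes_nm = c(1500, 2250, 2750),
         nucleus_offset_nm = c(0, 0, 2000),
         puncta_radius_vox = c(1.5, 2.5),
         jitter_center_vox = c(1, 3, 3)),
    list(...))
  do.call(phantom_config, args)
}

# minimal cell (~10k in-cell voxels); used for unit tests
phantom_config_tiny <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(24L, 64L, 64L),
         cell_semiaxes_nm = c(2000, 4000, 5000),
         nucleus_semiaxes_nm = c(1000, 1500, 1800),
         nucleus_offset_nm = c(0, 0, 1200),
         perinuclear_shell_nm = 800,
         puncta_radius_vox = c(1.5, 2.5),
         jitter_center_vox = c(1, 2, 2)),
    list(...))
  do.call(phantom_config, args)
}

# independent brute-force 3-D histogram tally (oracle for fingerprints)
brute_force_fingerprint <- function(values, bin_width, anchor = 1.3) {
  idx <- floor((values - anchor) / bin_width + 1e-9)
  lo <- min(idx):max(idx)
  counts <- vapply(lo, function(k) sum(idx == k), 0)
  data.frame(bin_lo = anchor + lo * bin_width,
             percent = 100 * counts / length(values))
}

# independent brute-force connected components (oracle for labelling)
brute_force_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  cur <- 0L
  coords <- which(mask, arr.ind = TRUE)
  neighbors <- function(p) {
    out <- list()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      if (connectivity == 6 && abs(dz) + abs(dy) + abs(dx) != 1) next
      q <- p + c(dz, dy, dx)
      if (all(q >= 1) && all(q <= d)) out[[length(out) + 1]] <- q
    }
    out
  }
  for (i in seq_len(nrow(coords))) {
    p0 <- coords[i, ]
    if (lab[p0[1], p0[2], p0[3]] != 0L) next
    cur <- cur + 1L
    queue <- list(p0)
    lab[p0[1], p0[2], p0[3]] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in neighbors(p)) {
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# wrap a bare numeric vector as a 1-voxel-thick RI stack + full mask
toy_stack <- function(values, dims = c(length(values), 1, 1)) {
  ri_stack(array(values, dim = dims), c(400, 200, 200))
}

toy_mask <- function(stack, keep = NULL) {
  m <- array(TRUE, dim = dim(stack$voxels))
  if (!is.null(keep)) {
    m[] <- FALSE
    m[keep] <- TRUE
  }
  cell_mask(m, "toy")
}
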