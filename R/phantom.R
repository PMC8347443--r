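# Synthetic holotomography phantom: one adherent cell per stack, modelled as
# nested ellipsoids (cell, nucleus) on an anisotropic voxel grid, with
# compartment RI drawn from calibrated truncated skew-normal distributions,
# dose-dependent perinuclear nanoparticle puncta in the 1.39-1.41 band, a
# chromatin tail above 1.39 inside the nucleus as confounder, and a matched
# fluorescence channel.

# package-level cache for the default calibrated distributions
.rifinger_cache <- new.env(parent = emptyenv())

#' Default control-cytoplasm RI constraints
#'
#' Mode 1.3725, support 1.365-1.395, 99.5% of mass in 1.365-1.39, 34% of
#' mass below the mode: the published fingerprint statistics of untreated
#' Panc-1 cells.
#' @return An [ri_constraints] object.
#' @export
control_cytoplasm_constraints <- function() {
  ri_constraints(mode_ri = 1.3725, support_lo = 1.365, support_hi = 1.395,
                 band_lo = 1.365, band_hi = 1.39,
                 frac_in_band = 0.995, frac_below_mode = 0.34)
}

#' Default nucleus RI constraints
#'
#' Mode 1.378 with support up to 1.405 so that a small chromatin tail
#' (0.15% of nuclear voxels) exceeds 1.39 and confounds naive band
#' detection, as chromatin does in real cells.  The below-mode fraction
#' 0.58 makes the nuclear distribution left-skewed, placing enough nuclear
#' mass below 1.3725 that the whole-cell asymmetry (the fraction of
#' in-cell voxels below the whole-cell mode, reported as 34%) is not
#' diluted by the nucleus, while preserving the 0.15% chromatin tail above
#' 1.39; within the truncated skew-normal family these two features trade
#' off, and 0.58 is the largest below-mode fraction that keeps the full
#' tail.
#' @return An [ri_constraints] object.
#' @export
nucleus_constraints <- function() {
  ri_constraints(mode_ri = 1.378, support_lo = 1.368, support_hi = 1.405,
                 band_lo = 1.368, band_hi = 1.39,
                 frac_in_band = 0.9985, frac_below_mode = 0.58)
}

default_cytoplasm_ri <- function() {
  if (is.null(.rifinger_cache$cyto)) {
    .rifinger_cache$cyto <-
      calibrate_ri_distribution(control_cytoplasm_constraints())
  }
  .rifinger_cache$cyto
}

default_nucleus_ri <- function() {
  if (is.null(.rifinger_cache$nuc)) {
    .rifinger_cache$nuc <- calibrate_ri_distribution(nucleus_constraints())
  }
  .rifinger_cache$nuc
}

#' Phantom configuration
#'
#' All geometry is in nanometres on a `(nz, ny, nx)` grid; defaults emulate
#' a 96-slice holotomography stack at 200 nm lateral / 400 nm axial
#' sampling containing one adherent pancreatic-cancer-like cell.
#'
#' @param grid_shape integer `(nz, ny, nx)`.
#' @param voxel_size_nm numeric `(dz, dy, dx)` in nm.
#' @param medium_ri RI of the surrounding culture medium.
#' @param cell_semiaxes_nm ellipsoid semi-axes `(z, y, x)` of the cell.
#' @param nucleus_semiaxes_nm ellipsoid semi-axes `(z, y, x)` of the nucleus.
#' @param nucleus_offset_nm nucleus centre offset `(z, y, x)` from the cell
#'   centre.
#' @param cytoplasm_ri,nucleus_ri [ri_dist] objects; `NULL` selects the
#'   distributions calibrated to [control_cytoplasm_constraints()] and
#'   [nucleus_constraints()].
#' @param np_voxel_fraction_per_dose named numeric: dose (mg/mL, as names)
#'   to fraction of cytoplasm voxels occupied by nanoparticle puncta.  Must
#'   be 0 at dose 0 and non-decreasing in dose.
#' @param np_band RI band assigned to nanoparticle voxels.
#' @param puncta_radius_vox range of punctum sphere radii (voxels).
#' @param perinuclear_shell_nm thickness of the shell around the nucleus in
#'   which puncta are placed.
#' @param fluor_bg_mean,fluor_bg_sd fluorescence background mean and noise
#'   standard deviation (AU).
#' @param fluor_per_np_voxel fluorescence added on nanoparticle voxels (AU);
#'   `NULL` calibrates it so cohort per-cell means reproduce
#'   `fluor_dose_response`.
#' @param fluor_dose_response named numeric: dose to target per-cell mean
#'   fluorescence (AU); defaults to the published 5.1 / 10.1 / 15.1.
#' @param ri_noise_sd imaging noise standard deviation (RI units); the
#'   default 2e-4 is the sensitivity class of commercial holotomography.
#' @param jitter_semiaxes_frac,jitter_center_vox per-cell geometry jitter
#'   ranges used by [generate_cohort()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(96L, 256L, 256L),
                           voxel_size_nm = c(400, 200, 200),
                           medium_ri = 1.333,
                           cell_semiaxes_nm = c(5500, 13000, 16000),
                           nucleus_semiaxes_nm = c(3000, 4500, 5500),
                           nucleus_offset_nm = c(0, 0, 4000),
                           cytoplasm_ri = NULL,
                           nucleus_ri = NULL,
                           np_voxel_fraction_per_dose =
                             c("0" = 0, "0.25" = 0.01, "0.5" = 0.02),
                           np_band = c(1.39, 1.41),
                           puncta_radius_vox = c(2, 4),
                           perinuclear_shell_nm = 1000,
                           fluor_bg_mean = 5.1,
                           fluor_bg_sd = 0.5,
                           fluor_per_np_voxel = NULL,
                           fluor_dose_response =
                             c("0" = 5.1, "0.25" = 10.1, "0.5" = 15.1),
                           ri_noise_sd = 2e-4,
                           jitter_semiaxes_frac = 0.08,
                           jitter_center_vox = c(2, 6, 6)) {
  doses <- as.numeric(names(np_voxel_fraction_per_dose))
  if (anyNA(doses)) stop("np_voxel_fraction_per_dose must have numeric names")
  ord <- order(doses)
  fr <- np_voxel_fraction_per_dose[ord]
  if (any(diff(fr) < 0)) {
    stop("np_voxel_fraction_per_dose must be non-decreasing in dose")
  }
  if (abs(doses[ord][1]) < 1e-12 && fr[1] != 0) {
    stop("np voxel fraction at dose 0 must be 0")
  }
  cfg <- structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_size_nm = as.numeric(voxel_size_nm),
    medium_ri = medium_ri,
    cell_semiaxes_nm = as.numeric(cell_semiaxes_nm),
    nucleus_semiaxes_nm = as.numeric(nucleus_semiaxes_nm),
    nucleus_offset_nm = as.numeric(nucleus_offset_nm),
    cytoplasm_ri = cytoplasm_ri %||% default_cytoplasm_ri(),
    nucleus_ri = nucleus_ri %||% default_nucleus_ri(),
    np_voxel_fraction_per_dose = fr,
    np_band = np_band,
    puncta_radius_vox = puncta_radius_vox,
    perinuclear_shell_nm = perinuclear_shell_nm,
    fluor_bg_mean = fluor_bg_mean,
    fluor_bg_sd = fluor_bg_sd,
    fluor_per_np_voxel = fluor_per_np_voxel,
    fluor_dose_response = fluor_dose_response,
    ri_noise_sd = ri_noise_sd,
    jitter_semiaxes_frac = jitter_semiaxes_frac,
    jitter_center_vox = as.numeric(jitter_center_vox)
  ), class = "phantom_config")
  if (is.null(cfg$fluor_per_np_voxel)) {
    cfg$fluor_per_np_voxel <- calibrate_fluor_gain(cfg)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fluorescence gain such that the expected per-cell mean fluorescence hits
# the configured dose response: mean = bg + gain * f_dose * (V_cyto/V_cell),
# with the volume ratio taken from the unjittered ellipsoid geometry.
calibrate_fluor_gain <- function(cfg) {
  cyto_frac <- 1 - prod(cfg$nucleus_semiaxes_nm) / prod(cfg$cell_semiaxes_nm)
  doses <- as.numeric(names(cfg$np_voxel_fraction_per_dose))
  resp <- cfg$fluor_dose_response
  rdose <- as.numeric(names(resp))
  gains <- c()
  for (i in seq_along(doses)) {
    f <- cfg$np_voxel_fraction_per_dose[i]
    if (f <= 0) next
    j <- which(abs(rdose - doses[i]) < 1e-9)
    if (length(j) != 1) next
    gains <- c(gains, (resp[j] - cfg$fluor_bg_mean) / (f * cyto_frac))
  }
  if (length(gains) == 0) return(0)
  mean(gains)
}

# voxel-centre ellipsoid rasterization; returns logical (nz, ny, nx) array.
# Only the ellipsoid's bounding box is evaluated, the rest stays FALSE.
ellipsoid_mask <- function(grid_shape, voxel_size_nm, center_nm, semiaxes_nm) {
  out <- array(FALSE, dim = grid_shape)
  rng <- vector("list", 3)
  for (a in 1:3) {
    n <- grid_shape[a]
    lo <- max(1L, ceiling((center_nm[a] - semiaxes_nm[a]) /
                            voxel_size_nm[a] + 0.5))
    hi <- min(n, floor((center_nm[a] + semiaxes_nm[a]) /
                         voxel_size_nm[a] + 0.5))
    if (lo > hi) return(out)
    rng[[a]] <- lo:hi
  }
  qz <- (((rng[[1]] - 0.5) * voxel_size_nm[1] - center_nm[1]) /
           semiaxes_nm[1])^2
  qy <- (((rng[[2]] - 0.5) * voxel_size_nm[2] - center_nm[2]) /
           semiaxes_nm[2])^2
  qx <- (((rng[[3]] - 0.5) * voxel_size_nm[3] - center_nm[3]) /
           semiaxes_nm[3])^2
  out[rng[[1]], rng[[2]], rng[[3]]] <-
    outer(outer(qz, qy, "+"), qx, "+") <= 1
  out
}

grid_center_nm <- function(cfg) {
  cfg$grid_shape * cfg$voxel_size_nm / 2
}

lookup_dose_fraction <- function(cfg, dose) {
  doses <- as.numeric(names(cfg$np_voxel_fraction_per_dose))
  j <- which(abs(doses - dose) < 1e-9)
  if (length(j) != 1) {
    stop(sprintf("dose %s is not a key of np_voxel_fraction_per_dose", dose),
         call. = FALSE)
  }
  unname(cfg$np_voxel_fraction_per_dose[j])
}

#' Generate one phantom scene with full ground truth
#'
#' Rasterizes the cell and nucleus, samples compartment RI i.i.d. from the
#' calibrated distributions, places nanoparticle puncta (spheres, RI uniform
#' on the nanoparticle band) inside the perinuclear shell until the
#' dose-specific cytoplasm voxel fraction is reached, and builds the
#' noiseless fluorescence volume.  Nanoparticles never enter the nucleus.
#' Identical `(config, dose, seed)` give bit-identical scenes.
#'
#' @param config a [phantom_config()].
#' @param dose mg/mL; must be a key of `np_voxel_fraction_per_dose`.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_scene` with elements `cell_mask`,
#'   `nucleus_mask`, `np_mask` (logical arrays), `true_ri`, `true_fluor`
#'   (numeric arrays), `dose`, `seed`, `config`.
#' @export
generate_scene <- function(config, dose, seed) {
  stopifnot(inherits(config, "phantom_config"))
  np_frac <- lookup_dose_fraction(config, dose)
  set.seed(as.integer(seed))

  ctr <- grid_center_nm(config)
  cell <- ellipsoid_mask(config$grid_shape, config$voxel_size_nm, ctr,
                         config$cell_semiaxes_nm)
  nuc <- ellipsoid_mask(config$grid_shape, config$voxel_size_nm,
                        ctr + config$nucleus_offset_nm,
                        config$nucleus_semiaxes_nm)
  nuc <- nuc & cell
  cyto <- cell & !nuc
  n_cyto <- sum(cyto)
  if (n_cyto == 0) stop("degenerate geometry: no cytoplasm voxels")

  true_ri <- array(config$medium_ri, dim = config$grid_shape)
  true_ri[cyto] <- ri_dist_sample(config$cytoplasm_ri, n_cyto)
  true_ri[nuc] <- ri_dist_sample(config$nucleus_ri, sum(nuc))

  np <- array(FALSE, dim = config$grid_shape)
  if (np_frac > 0) {
    np <- place_puncta(config, cyto, nuc, ctr, np_frac, n_cyto)
    n_np <- sum(np)
    true_ri[np] <- runif(n_np, config$np_band[1], config$np_band[2])
  }

  true_fluor <- array(0, dim = config$grid_shape)
  true_fluor[cell] <- config$fluor_bg_mean
  true_fluor[np] <- config$fluor_bg_mean + config$fluor_per_np_voxel

  structure(list(cell_mask = cell, nucleus_mask = nuc, np_mask = np,
                 true_ri = true_ri, true_fluor = true_fluor,
                 dose = dose, seed = as.integer(seed), config = config),
            class = "phantom_scene")
}

# Rejection placement of spherical puncta in the perinuclear shell.  The
# shell is the expanded nucleus ellipsoid (semi-axes + shell thickness)
# minus the nucleus, intersected with the cytoplasm; punctum voxels are
# clipped to the cytoplasm so they can never enter the nucleus or leave the
# cell.
place_puncta <- function(cfg, cyto, nuc, ctr, np_frac, n_cyto) {
  target <- round(np_frac * n_cyto)
  if (target == 0) return(array(FALSE, dim = cfg$grid_shape))
  shell_outer <- ellipsoid_mask(cfg$grid_shape, cfg$voxel_size_nm,
                                ctr + cfg$nucleus_offset_nm,
                                cfg$nucleus_semiaxes_nm +
                                  cfg$perinuclear_shell_nm)
  candidates <- which(shell_outer & cyto)
  if (length(candidates) < target) {
    stop(sprintf(
      paste0("cannot reach nanoparticle voxel fraction %.4g: the ",
             "perinuclear shell holds only %d cytoplasm voxels (need %d); ",
             "increase perinuclear_shell_nm"),
      np_frac, length(candidates), target), call. = FALSE)
  }
  nz <- cfg$grid_shape[1]; ny <- cfg$grid_shape[2]; nx <- cfg$grid_shape[3]
  np <- array(FALSE, dim = cfg$grid_shape)
  count <- 0L
  max_puncta <- 200L + 50L * ceiling(target / 30)
  tries <- 0L
  while (count < target) {
    tries <- tries + 1L
    if (tries > max_puncta) {
      stop(paste0("nanoparticle placement did not converge; ",
                  "increase perinuclear_shell_nm"), call. = FALSE)
    }
    c_idx <- candidates[[sample.int(length(candidates), 1L)]]
    r <- runif(1, cfg$puncta_radius_vox[1], cfg$puncta_radius_vox[2])
    off <- ball_offsets(r)
    cz <- (c_idx - 1L) %% nz
    rest <- (c_idx - 1L) %/% nz
    cy <- rest %% ny
    cx <- rest %/% ny
    zz <- cz + off[, 1]; yy <- cy + off[, 2]; xx <- cx + off[, 3]
    ok <- zz >= 0 & zz < nz & yy >= 0 & yy < ny & xx >= 0 & xx < nx
    idx <- 1L + zz[ok] + nz * (yy[ok] + ny * xx[ok])
    idx <- idx[cyto[idx] & !np[idx]]
    if (length(idx) == 0) next
    np[idx] <- TRUE
    count <- count + length(idx)
  }
  np
}

#' Render noisy RI and fluorescence stacks from a scene
#'
#' Adds i.i.d. Gaussian imaging noise to the ground-truth volumes (the RI
#' volume everywhere, medium included; the fluorescence volume clipped at
#' zero).  The noise stream is derived deterministically from the scene
#' seed, so rendering the same scene twice is bit-identical.
#'
#' @param scene a `phantom_scene`.
#' @param config a [phantom_config()]; defaults to the scene's own.
#' @return list with elements `ri` ([ri_stack]) and `fluor` ([fluor_stack]).
#' @export
render_stacks <- function(scene, config = scene$config) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (!identical(dim(scene$true_ri), as.integer(config$grid_shape))) {
    stop("scene grid does not match config grid")
  }
  set.seed((scene$seed + 500009L) %% .Machine$integer.max)
  n <- length(scene$true_ri)
  ri <- scene$true_ri
  if (config$ri_noise_sd > 0) ri <- ri + rnorm(n, 0, config$ri_noise_sd)
  fl <- scene$true_fluor
  if (config$fluor_bg_sd > 0) fl <- fl + rnorm(n, 0, config$fluor_bg_sd)
  fl[fl < 0] <- 0
  dim(ri) <- config$grid_shape
  dim(fl) <- config$grid_shape
  prov <- sprintf("phantom seed %d dose %s", scene$seed,
                  format(scene$dose))
  list(ri = ri_stack(ri, config$voxel_size_nm, provenance = prov),
       fluor = fluor_stack(fl, config$voxel_size_nm, provenance = prov))
}

# deterministic per-cell geometry jitter (separate stream from the scene)
jitter_config <- function(cfg, jseed) {
  set.seed(jseed %% .Machine$integer.max)
  f <- cfg$jitter_semiaxes_frac
  cfg$cell_semiaxes_nm <- cfg$cell_semiaxes_nm * runif(3, 1 - f, 1 + f)
  cfg$nucleus_semiaxes_nm <- cfg$nucleus_semiaxes_nm * runif(3, 1 - f, 1 + f)
  cfg$nucleus_offset_nm <- cfg$nucleus_offset_nm +
    runif(3, -1, 1) * cfg$jitter_center_vox * cfg$voxel_size_nm
  cfg
}

#' Stream over a phantom cohort without holding it in memory
#'
#' Generates `n_cells` scenes with per-cell seeds `seed + i` and per-cell
#' jittered geometry, applies `fn` to each, and collects the results.  This
#' is the memory-safe way to analyze cohorts of full-size stacks (a single
#' rendered cell occupies several hundred MB).
#'
#' @param config a [phantom_config()].
#' @param n_cells number of cells (>= 1).
#' @param dose mg/mL.
#' @param seed master seed; cell i uses seed + i.
#' @param fn function `(scene, stacks, index) -> value`; `stacks` is the
#'   [render_stacks()] result or `NULL` when `render = FALSE`.
#' @param render whether to render noisy stacks for each cell.
#' @return list of `fn` results, one per cell.
#' @export
map_cohort <- function(config, n_cells, dose, seed, fn, render = TRUE) {
  stopifnot(n_cells >= 1)
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell_seed <- as.integer(seed) + i
    cfg_i <- jitter_config(config, cell_seed + 1000003L)
    scene <- tryCatch(
      generate_scene(cfg_i, dose, cell_seed),
      error = function(e) {
        stop(sprintf("cell %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
    stacks <- if (render) render_stacks(scene, cfg_i) else NULL
    out[[i]] <- fn(scene, stacks, i)
  }
  out
}

#' Generate a phantom cohort
#'
#' Materializes every cell of [map_cohort()]; intended for small grids or
#' small cohorts (each full-size rendered cell is ~300 MB).
#'
#' @inheritParams map_cohort
#' @return list of `list(scene, ri, fluor)` per cell.
#' @export
generate_cohort <- function(config, n_cells, dose, seed, render = TRUE) {
  map_cohort(config, n_cells, dose, seed,
             function(scene, stacks, i) {
               list(scene = scene, ri = stacks$ri, fluor = stacks$fluor)
             },
             render = render)
}
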