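# Cohort-level recovery analyses: run the standard pipeline path
# (render -> segment -> fingerprint / fluorescence) over a phantom cohort
# and collect per-cell summaries.  These are the workhorses of the
# parameter-recovery validation.

#' Per-cell fingerprints and statistics for a phantom cohort
#'
#' Streams over `n_cells` phantom cells (seeds `seed + i`, jittered
#' geometry), segments each rendered RI stack, computes its fingerprint and
#' [fingerprint_stats()], and returns both the per-cell tables and the
#' cohort-mean fingerprint.
#'
#' @param config a [phantom_config()].
#' @param n_cells cohort size.
#' @param dose mg/mL.
#' @param seed master seed.
#' @param bin_width fingerprint bin width.
#' @param band,high_cut passed to [fingerprint_stats()].
#' @param ri_threshold,closing_radius_vox segmentation parameters.
#' @return list: `fingerprints` (per-cell list), `stats` (data frame with
#'   one row per cell: frac_in_band, frac_below_mode, mode_ri, ri_min,
#'   ri_max, peak_height, high_ri_frac, mask_voxels), `mean_fingerprint`.
#' @export
cohort_fingerprints <- function(config, n_cells, dose, seed,
                                bin_width = 0.0025,
                                band = c(1.365, 1.39), high_cut = 1.39,
                                ri_threshold = 1.36,
                                closing_radius_vox = 2) {
  rows <- map_cohort(config, n_cells, dose, seed,
                     function(scene, stacks, i) {
                       mask <- segment_cell(stacks$ri,
                                            ri_threshold = ri_threshold,
                                            closing_radius_vox =
                                              closing_radius_vox,
                                            cell_id = sprintf("c%03d", i))
                       fp <- compute_fingerprint(stacks$ri, mask,
                                                 bin_width = bin_width,
                                                 dose = dose)
                       st <- fingerprint_stats(fp, band = band,
                                               high_cut = high_cut)
                       list(fp = fp,
                            row = data.frame(
                              cell_id = mask$cell_id,
                              frac_in_band = st$frac_in_band,
                              frac_below_mode = st$frac_below_mode,
                              mode_ri = st$mode_ri,
                              ri_min = st$ri_min, ri_max = st$ri_max,
                              peak_height = st$peak_height,
                              high_ri_frac = st$high_ri_frac,
                              mask_voxels = mask$voxel_count))
                     })
  fps <- lapply(rows, `[[`, "fp")
  list(fingerprints = fps,
       stats = do.call(rbind, lapply(rows, `[[`, "row")),
       mean_fingerprint = mean_fingerprint(fps, dose = dose))
}

#' Per-cell mean fluorescence for a phantom cohort
#'
#' @inheritParams cohort_fingerprints
#' @return numeric vector of per-cell mean fluorescence (AU).
#' @export
cohort_fluorescence <- function(config, n_cells, dose, seed,
                                ri_threshold = 1.36,
                                closing_radius_vox = 2) {
  unlist(map_cohort(config, n_cells, dose, seed,
                    function(scene, stacks, i) {
                      mask <- segment_cell(stacks$ri,
                                           ri_threshold = ri_threshold,
                                           closing_radius_vox =
                                             closing_radius_vox)
                      per_cell_fluorescence(stacks$fluor, mask)
                    }))
}
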