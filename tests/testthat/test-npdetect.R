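# Band detection, uptake statistics and overlay rendering.

test_that("toy band components match brute-force enumeration", {
  vox <- array(1.37, dim = c(3, 3, 3))
  vox[1, 1, 1] <- 1.395
  vox[1, 2, 1] <- 1.40           # adjacent to the first
  vox[3, 3, 3] <- 1.405          # isolated
  st <- ri_stack(vox, c(400, 200, 200))
  mk <- toy_mask(st)
  det <- detect_band(st, mk, detection_params(min_component_vox = 2))
  expect_equal(det$band_voxels, 3)
  expect_equal(det$n_components, 1)
  expect_equal(det$components$voxel_count, 2)
  want <- brute_force_components(st$voxels >= 1.39 & st$voxels <= 1.41, 26)
  expect_equal(max(want), 2)     # two raw components before the size floor
  expect_equal(max(det$labels), 2)
})

test_that("band mask is a subset of the cell and percent is exact", {
  cfg <- phantom_config_tiny()
  sc <- generate_scene(cfg, 0.5, seed = 11)
  st <- render_stacks(sc)
  m <- segment_cell(st$ri)
  det <- detect_band(st$ri, m)
  expect_equal(sum(det$band_mask & !m$mask), 0)
  expect_equal(det$band_percent, 100 * det$band_voxels / m$voxel_count)
  # the detected band covers the planted nanoparticles up to noise at the
  # band edges (NP RI is uniform on [1.39, 1.41]; noise sd 2e-4 pushes an
  # expected ~0.8% of NP voxels just outside the closed band)
  expect_gte(sum(det$band_mask & sc$np_mask) / sum(sc$np_mask), 0.95)
})

test_that("noiseless dose-0.5 phantom band contains all true NP voxels", {
  cfg <- phantom_config_tiny(ri_noise_sd = 0, fluor_bg_sd = 0)
  sc <- generate_scene(cfg, 0.5, seed = 12)
  st <- render_stacks(sc)
  m <- segment_cell(st$ri)
  det <- detect_band(st$ri, m)
  expect_true(all(det$band_mask[sc$np_mask]))
  np_frac <- 100 * sum(sc$np_mask) / sum(sc$cell_mask)
  expect_gte(det$band_percent, np_frac)
})

test_that("control band load equals the calibrated high-RI tail mass", {
  # oracle: expected band fraction of a control cell is the mixture of the
  # compartment tail masses above 1.39, computed by numerical integration
  cfg <- phantom_config_tiny()
  p_cyto <- 1 - ri_dist_cdf(cfg$cytoplasm_ri, 1.39)
  p_nuc <- 1 - ri_dist_cdf(cfg$nucleus_ri, 1.39)
  sc <- generate_scene(cfg, 0, seed = 13)
  n_cyto <- sum(sc$cell_mask & !sc$nucleus_mask)
  n_nuc <- sum(sc$nucleus_mask)
  expected <- 100 * (n_cyto * p_cyto + n_nuc * p_nuc) / sum(sc$cell_mask)
  st <- render_stacks(sc)
  m <- segment_cell(st$ri)
  det <- detect_band(st$ri, m)
  expect_equal(det$band_percent, expected, tolerance = 0.35)
  expect_gt(det$band_percent, 0)   # controls carry a genuine high-RI tail
})

test_that("a phantom with both compartments capped below the band is empty", {
  cyto <- ri_dist(1.3695, 0.006, 2.5, 1.365, 1.3895)
  nuc <- ri_dist(1.3725, 0.004, 1.5, 1.368, 1.3880)
  cfg <- phantom_config_tiny(cytoplasm_ri = cyto, nucleus_ri = nuc,
                             ri_noise_sd = 0, fluor_bg_sd = 0)
  st <- render_stacks(generate_scene(cfg, 0, seed = 14))
  m <- segment_cell(st$ri)
  det <- detect_band(st$ri, m)
  expect_equal(det$band_voxels, 0)
  expect_equal(det$n_components, 0)
})

test_that("uptake summary is dose-ordered with exact SEM handling", {
  det <- data.frame(dose = rep(c(0.5, 0, 0.25), each = 3),
                    band_percent = c(2.0, 2.2, 2.1, 0, 0.1, 0.05,
                                     1.0, 1.1, 0.9))
  up <- uptake_by_dose(det)
  expect_equal(up$dose, c(0, 0.25, 0.5))
  expect_equal(up$mean_band_percent[3], mean(c(2.0, 2.2, 2.1)))
  expect_equal(up$sem_band_percent[1],
               sd(c(0, 0.1, 0.05)) / sqrt(3))
  # identical cells: SEM 0; singleton: error
  expect_equal(uptake_by_dose(data.frame(
    dose = 0, band_percent = c(1, 1)))$sem_band_percent, 0)
  expect_error(uptake_by_dose(data.frame(dose = 0, band_percent = 1)),
               "SEM undefined")
})

test_that("overlay paints band voxels red and projects them", {
  vox <- array(seq(1.33, 1.40, length.out = 2 * 3 * 3), dim = c(2, 3, 3))
  st <- ri_stack(vox, c(400, 200, 200))
  band <- array(FALSE, dim = dim(vox))
  ov0 <- render_overlay(st, band)
  expect_true(all(ov0$rgb[, , , 1] == ov0$rgb[, , , 2]))  # pure grayscale
  band[1, 2, 2] <- TRUE
  ov1 <- render_overlay(st, band)
  expect_equal(ov1$rgb[1, 2, 2, ], c(1, 0, 0))
  expect_equal(ov1$projection[2, 2, ], c(1, 0, 0))
  expect_equal(sum(ov1$projection[, , 1] == 1 & ov1$projection[, , 2] == 0),
               1)  # exactly one red pixel in the projection
  ov_all <- render_overlay(st, array(TRUE, dim = dim(vox)))
  expect_true(all(ov_all$rgb[, , , 1] == 1) && all(ov_all$rgb[, , , 2] == 0))
})
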