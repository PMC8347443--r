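# Phantom generator: ground truth, dose scaling, determinism.

cfg_tiny <- phantom_config_tiny()

test_that("dose 0 gives an empty NP mask and background-only fluorescence", {
  sc <- generate_scene(cfg_tiny, 0, seed = 3)
  expect_equal(sum(sc$np_mask), 0)
  expect_true(all(sc$true_fluor[sc$cell_mask] == cfg_tiny$fluor_bg_mean))
  expect_true(all(sc$true_fluor[!sc$cell_mask] == 0))
})

test_that("NP voxel fraction matches the dose within one punctum", {
  sc <- generate_scene(cfg_tiny, 0.5, seed = 42)
  n_cyto <- sum(sc$cell_mask & !sc$nucleus_mask)
  target <- round(0.02 * n_cyto)
  max_punctum <- nrow(ball_offsets(cfg_tiny$puncta_radius_vox[2]))
  got <- sum(sc$np_mask)
  expect_gte(got, target)
  expect_lte(got - target, max_punctum)
  # NP voxels carry band RI in the ground truth
  expect_true(all(sc$true_ri[sc$np_mask] >= cfg_tiny$np_band[1]))
  expect_true(all(sc$true_ri[sc$np_mask] <= cfg_tiny$np_band[2]))
})

test_that("nanoparticles never enter the nucleus and stay inside the cell", {
  for (dose in c(0.25, 0.5)) {
    sc <- generate_scene(cfg_tiny, dose, seed = 7)
    expect_equal(sum(sc$np_mask & sc$nucleus_mask), 0)
    expect_equal(sum(sc$np_mask & !sc$cell_mask), 0)
    expect_true(all(sc$nucleus_mask[sc$cell_mask == FALSE] == FALSE))
  }
})

test_that("expected NP voxel count strictly increases with dose", {
  counts <- vapply(c(0, 0.25, 0.5), function(d)
    sum(generate_scene(cfg_tiny, d, seed = 5)$np_mask), 0)
  expect_true(all(diff(counts) > 0))
})

test_that("identical (config, dose, seed) gives bit-identical scenes and stacks", {
  a <- generate_scene(cfg_tiny, 0.25, seed = 9)
  b <- generate_scene(cfg_tiny, 0.25, seed = 9)
  expect_identical(a$true_ri, b$true_ri)
  expect_identical(a$np_mask, b$np_mask)
  sa <- render_stacks(a)
  sb <- render_stacks(b)
  expect_identical(sa$ri$voxels, sb$ri$voxels)
  expect_identical(sa$fluor$voxels, sb$fluor$voxels)
})

test_that("zero noise renders the ground truth exactly", {
  cfg0 <- phantom_config_tiny(ri_noise_sd = 0, fluor_bg_sd = 0)
  sc <- generate_scene(cfg0, 0.5, seed = 2)
  st <- render_stacks(sc)
  expect_identical(st$ri$voxels[sc$cell_mask], sc$true_ri[sc$cell_mask])
  expect_true(all(st$ri$voxels[!sc$cell_mask] == cfg0$medium_ri))
  expect_identical(st$fluor$voxels, sc$true_fluor)
})

test_that("unknown dose and unreachable NP fraction raise informative errors", {
  expect_error(generate_scene(cfg_tiny, 0.3, seed = 1),
               "not a key of np_voxel_fraction_per_dose")
  cramped <- phantom_config_tiny(perinuclear_shell_nm = 50,
                                 np_voxel_fraction_per_dose =
                                   c("0" = 0, "0.5" = 0.2))
  expect_error(generate_scene(cramped, 0.5, seed = 1),
               "perinuclear_shell_nm")
})

test_that("cohorts derive per-cell seeds and jitter deterministically", {
  co <- generate_cohort(cfg_tiny, n_cells = 1, dose = 0.25, seed = 30)
  expect_length(co, 1)
  cfg_j <- rifinger:::jitter_config(cfg_tiny, 31L + 1000003L)
  direct <- generate_scene(cfg_j, 0.25, seed = 31)
  expect_identical(co[[1]]$scene$true_ri, direct$true_ri)

  co2 <- generate_cohort(cfg_tiny, n_cells = 3, dose = 0.5, seed = 30,
                         render = FALSE)
  counts <- vapply(co2, function(c) sum(c$scene$np_mask), 0)
  expect_true(all(counts > 0))
  co3 <- generate_cohort(cfg_tiny, n_cells = 3, dose = 0.5, seed = 30,
                         render = FALSE)
  expect_identical(lapply(co2, function(c) c$scene$true_ri),
                   lapply(co3, function(c) c$scene$true_ri))
  # geometry jitter: cells differ
  expect_false(identical(co2[[1]]$scene$cell_mask, co2[[2]]$scene$cell_mask))
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(np_voxel_fraction_per_dose =
                                c("0" = 0, "0.25" = 0.02, "0.5" = 0.01)),
               "non-decreasing")
  expect_error(phantom_config(np_voxel_fraction_per_dose =
                                c("0" = 0.01, "0.5" = 0.02)),
               "dose 0 must be 0")
})

test_that("fluorescence gain calibration targets the dose response", {
  cyto_frac <- 1 - prod(cfg_tiny$nucleus_semiaxes_nm) /
    prod(cfg_tiny$cell_semiaxes_nm)
  expected_gain <- 5.0 / (0.01 * cyto_frac)
  expect_equal(cfg_tiny$fluor_per_np_voxel, expected_gain, tolerance = 1e-6)
})
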