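# TIFF + sidecar round trips and CSV outputs.

test_that("float32 TIFF write/read round trip is bit-exact", {
  dir <- withr::local_tempdir()
  set.seed(1)
  vox <- array(1.33 + runif(5 * 8 * 6) * 0.07, dim = c(5, 8, 6))
  st <- ri_stack(vox, c(400, 200, 200), provenance = "test")
  p <- file.path(dir, "a_ri.tif")
  write_ri_stack(st, p)
  back <- read_ri_stack(p)
  # first read quantizes double -> float32; a second round trip is exact
  expect_equal(back$voxels, vox, tolerance = 1e-7)
  p2 <- file.path(dir, "b_ri.tif")
  write_ri_stack(back, p2)
  expect_identical(read_ri_stack(p2)$voxels, back$voxels)
  expect_equal(back$voxel_size_nm, c(400, 200, 200))
})

test_that("single-page TIFF yields an nz = 1 stack", {
  dir <- withr::local_tempdir()
  vox <- array(runif(12) + 1.3, dim = c(1, 3, 4))
  p <- file.path(dir, "one.tif")
  write_ri_stack(ri_stack(vox, c(400, 200, 200)), p)
  back <- read_ri_stack(p)
  expect_equal(dim(back$voxels), c(1L, 3L, 4L))
  expect_equal(back$voxels, vox, tolerance = 1e-7)
})

test_that("missing voxel-size metadata is an explicit error", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bare.tif")
  # plain TIFF: no sidecar, no description, no resolution tags
  rifinger:::write_tiff_gray(p, array(1.37, dim = c(2, 4, 4)), bits = 32)
  expect_error(read_ri_stack(p), "no voxel-size metadata")
  # explicit override still works
  st <- read_ri_stack(p, voxel_size_nm = c(400, 200, 200))
  expect_equal(st$voxel_size_nm, c(400, 200, 200))
})

test_that("sidecar metadata is found under both naming conventions", {
  dir <- withr::local_tempdir()
  vox <- array(1.37, dim = c(2, 3, 3))
  p <- file.path(dir, "cell_007_ri.tif")
  rifinger:::write_tiff_gray(p, vox, bits = 32)
  write_stack_meta(file.path(dir, "cell_007_meta.json"), c(300, 150, 150))
  st <- read_ri_stack(p)
  expect_equal(st$voxel_size_nm, c(300, 150, 150))
})

test_that("mask and truth-label volumes round trip through 8-bit TIFF", {
  dir <- withr::local_tempdir()
  set.seed(2)
  m <- array(runif(4 * 5 * 5) < 0.5, dim = c(4, 5, 5))
  p <- file.path(dir, "mask.tif")
  write_mask(m, p)
  expect_identical(read_mask(p), m)

  sc <- generate_scene(phantom_config_tiny(), 0.5, seed = 4)
  pt <- file.path(dir, "truth.tif")
  write_truth_labels(sc, pt)
  lab <- rifinger:::read_tiff_gray(pt)$voxels
  expect_equal(lab == 3, sc$np_mask * 1 == 1, ignore_attr = TRUE)
  expect_equal(sum(lab > 0), sum(sc$cell_mask))
})

test_that("write_results produces the three CSVs with full precision", {
  dir <- withr::local_tempdir()
  fp <- data.frame(cell_id = rep("c1", 13), dose = 0,
                   bin_lo = 1.36 + (0:12) * 0.0025,
                   percent = runif(13) * 10 + 1 / 3)
  det <- data.frame(cell_id = "c1", dose = 0, band_voxels = 10L,
                    band_percent = 0.123456789, n_components = 2L)
  cl <- data.frame(cell_id = "c1", M1 = 0.5, dice = 2 / 3,
                   mean_fluor_au = 5.1234567)
  paths <- write_results(fp, det, cl, dir)
  expect_true(all(file.exists(paths)))
  fp2 <- read.csv(paths[["fingerprints"]])
  expect_equal(nrow(fp2), 13)
  expect_equal(fp2$percent, fp$percent, tolerance = 1e-9)
  cl2 <- read.csv(paths[["coloc"]])
  expect_equal(cl2$mean_fluor_au, 5.1234567, tolerance = 1e-7)

  # empty inputs: headers only
  paths0 <- write_results(fp[0, ], det[0, ], cl[0, ],
                          file.path(dir, "empty"))
  d0 <- read.csv(paths0[["detections"]])
  expect_equal(nrow(d0), 0)
  expect_equal(names(d0), c("cell_id", "dose", "band_voxels",
                            "band_percent", "n_components"))
})

test_that("write_cell emits the standard per-cell file set", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config_tiny()
  sc <- generate_scene(cfg, 0.25, seed = 8)
  st <- render_stacks(sc)
  p <- write_cell(sc, st, "001", dir)
  expect_true(all(file.exists(p)))
  meta <- jsonlite::read_json(p[["meta"]], simplifyVector = TRUE)
  expect_equal(meta$dose, 0.25)
  expect_equal(as.numeric(meta$voxel_size_nm), c(400, 200, 200))
  back <- read_ri_stack(p[["ri"]])   # resolves via cell_001_meta.json
  expect_equal(back$voxels, st$ri$voxels, tolerance = 1e-6)
})
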