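# Fluorescence binarization, overlap statistics and group tests.

test_that("Otsu separates a bimodal toy exactly and rejects constants", {
  set.seed(1)
  v <- c(rep(5, 500), rep(50, 20))
  ot <- otsu_threshold(v)
  expect_gt(ot$threshold, 5)
  expect_lt(ot$threshold, 50)
  expect_gt(ot$eta2, 0.95)
  expect_error(otsu_threshold(rep(3, 10)), "constant")
})

test_that("binarization finds puncta and ignores pure background", {
  cfg <- phantom_config_tiny()
  sc <- generate_scene(cfg, 0.5, seed = 21)
  st <- render_stacks(sc)
  m <- segment_cell(st$ri)
  pos <- binarize_fluorescence(st$fluor, m)
  expect_gte(attr(pos, "eta2"), 0.8)
  # positives recover the planted NP voxels almost exactly
  expect_gte(sum(pos & sc$np_mask) / sum(sc$np_mask), 0.99)
  expect_lte(sum(pos & !sc$np_mask), 0.001 * sum(sc$cell_mask))

  sc0 <- generate_scene(cfg, 0, seed = 21)
  st0 <- render_stacks(sc0)
  m0 <- segment_cell(st0$ri)
  pos0 <- binarize_fluorescence(st0$fluor, m0)
  expect_lte(sum(pos0), 0.01 * m0$voxel_count)  # unimodal: no positives

  flat <- fluor_stack(array(7, dim = dim(st0$fluor$voxels)),
                      st0$fluor$voxel_size_nm)
  expect_error(binarize_fluorescence(flat, m0), "constant")
})

test_that("coloc_stats handles identity, disjoint and partial overlap", {
  a <- array(FALSE, dim = c(2, 2, 2)); a[1:4] <- TRUE
  b <- array(FALSE, dim = c(2, 2, 2)); b[3:6] <- TRUE
  same <- coloc_stats(a, a)
  expect_equal(same$M1, 1)
  expect_equal(same$dice, 1)
  disj <- coloc_stats(a, !a)
  expect_equal(disj$M1, 0)
  expect_equal(disj$dice, 0)
  part <- coloc_stats(a, b)          # |A| = |B| = 4, overlap 2
  expect_equal(part$M1, 0.5)
  expect_equal(part$dice, 0.5)
  empty <- coloc_stats(array(FALSE, c(2, 2, 2)), b)
  expect_equal(empty$M1, 0)
  expect_equal(empty$dice, 0)
})

test_that("Dice and M1 are bounded and Dice is symmetric over 1000 random pairs", {
  set.seed(99)
  for (i in 1:1000) {
    d <- c(3, 3, 3)
    a <- array(runif(27) < 0.4, dim = d)
    b <- array(runif(27) < 0.4, dim = d)
    ab <- coloc_stats(a, b)
    ba <- coloc_stats(b, a)
    expect_true(ab$M1 >= 0 && ab$M1 <= 1)
    expect_true(ab$dice >= 0 && ab$dice <= 1)
    expect_identical(ab$dice, ba$dice)
  }
})

test_that("a dark chromatin blob is non-NP, a fluorescent accumulation is NP", {
  # two 1.39-1.41 blobs: one "chromatin" blob without fluorescence, one
  # nanoparticle accumulation co-located with fluorescence
  vox <- array(1.372, dim = c(5, 9, 9))
  vox[2:3, 2:3, 2:3] <- 1.395        # chromatin, 8 voxels
  vox[2:3, 6:7, 6:7] <- 1.40         # nanoparticles, 8 voxels
  st <- ri_stack(vox, c(400, 200, 200))
  det <- detect_band(st, toy_mask(st))
  expect_equal(det$n_components, 2)
  fl <- array(FALSE, dim = dim(vox))
  fl[2:3, 6:7, 6:7] <- TRUE
  cl <- classify_components(det, fl)
  expect_setequal(cl$label, c("non-NP", "NP"))
  expect_equal(cl$label[cl$fluor_overlap == 1], "NP")
  expect_equal(cl$label[cl$fluor_overlap == 0], "non-NP")
})

test_that("phantom NP accumulations classify as NP with near-total overlap", {
  cfg <- phantom_config_tiny(ri_noise_sd = 0, fluor_bg_sd = 0)
  sc <- generate_scene(cfg, 0.5, seed = 23)
  st <- render_stacks(sc)
  m <- segment_cell(st$ri)
  det <- detect_band(st$ri, m)       # min_component_vox = 5: accumulations
  fl_pos <- sc$np_mask               # ground-truth fluorescence positives
  cl <- classify_components(det, fl_pos)
  expect_gt(nrow(cl), 0)
  expect_true(all(cl$label == "NP"))
  # accumulations may annex the odd isolated cytoplasmic high-RI voxel,
  # so overlap is near 1 but not always exactly 1
  expect_true(all(cl$fluor_overlap >= 0.8))
  acc_mask <- det$labels > 0 &
    array(det$labels %in% cl$id, dim = dim(det$labels))
  expect_gte(coloc_stats(acc_mask, fl_pos)$M1, 0.97)

  # boundary convention: exactly min_overlap counts as NP
  vox <- array(1.37, dim = c(1, 4, 1)); vox[1, 1:2, 1] <- 1.40
  st2 <- ri_stack(vox, c(400, 200, 200))
  det2 <- detect_band(st2, toy_mask(st2),
                      detection_params(min_component_vox = 2))
  half <- array(FALSE, dim = dim(vox)); half[1, 1, 1] <- TRUE
  cl2 <- classify_components(det2, half, min_overlap = 0.5)
  expect_equal(cl2$label, "NP")
})

test_that("per-cell fluorescence is the in-mask mean", {
  vox <- array(5.1, dim = c(2, 3, 3))
  fl <- fluor_stack(vox, c(400, 200, 200))
  m <- cell_mask(array(TRUE, dim = dim(vox)))
  expect_equal(per_cell_fluorescence(fl, m), 5.1)
})

test_that("group_compare matches closed-form pooled t and reduces PLSD to t", {
  gs <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c(0, 0.5), each = 3))
  expect_equal(gs$t_tests$t, 0)
  expect_equal(gs$t_tests$p, 1)

  # hand-computed pooled t for {1,2,3} vs {4,5,6}: sp2 = 1, t = -3/sqrt(2/3)
  gs2 <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c(0, 0.5), each = 3))
  t_hand <- (4 + 5 + 6 - 1 - 2 - 3) / 3 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(gs2$t_tests$t, t_hand, tolerance = 1e-12)
  expect_equal(gs2$t_tests$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # with exactly two groups Fisher PLSD is the pooled t-test
  expect_equal(gs2$plsd$p, gs2$t_tests$p, tolerance = 1e-12)
  expect_equal(abs(gs2$plsd$t), abs(gs2$t_tests$t), tolerance = 1e-12)
  # ANOVA with 2 groups: F = t^2
  expect_equal(gs2$anova$F, t_hand^2, tolerance = 1e-12)

  expect_error(group_compare(c(1, 1, 2, 2), rep(0, 4)), "at least 2")
  expect_error(group_compare(c(1, 1, 2, 2), c(0, 0, 1, 1)),
               "zero within-group variance")
  # SEM definition
  gs3 <- group_compare(c(1, 3, 2, 6), c(0, 0, 1, 1))
  expect_equal(gs3$summary$sem, c(sd(c(1, 3)) / sqrt(2),
                                  sd(c(2, 6)) / sqrt(2)))
})
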