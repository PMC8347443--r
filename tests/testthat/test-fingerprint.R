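# RI fingerprints: binning, normalization, statistics, dose-shift report.

test_that("degenerate and hand-computed fingerprints are exact", {
  st <- toy_stack(rep(1.3725, 10))
  fp <- compute_fingerprint(st, toy_mask(st))
  expect_equal(nrow(fp), 1)
  expect_equal(fp$bin_lo, 1.3725)
  expect_equal(fp$percent, 100)

  st4 <- toy_stack(c(1.365, 1.365, 1.3725, 1.390))
  fp4 <- compute_fingerprint(st4, toy_mask(st4))
  b <- round(fp4$bin_lo, 6)
  expect_equal(fp4$percent[b == 1.365], 50)
  expect_equal(fp4$percent[b == 1.3725], 25)
  expect_equal(fp4$percent[b == 1.3900], 25)
  expect_equal(sum(fp4$percent), 100)
  # interior zero bins are kept: grid is contiguous
  expect_equal(nrow(fp4), (1.390 - 1.365) / 0.0025 + 1)
})

test_that("fingerprints match a brute-force tally on random toys", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:100, 1)
    v <- 1.333 + runif(n) * 0.08
    st <- toy_stack(v)
    fp <- compute_fingerprint(st, toy_mask(st))
    want <- brute_force_fingerprint(v, 0.0025)
    expect_equal(fp$percent[match(round(want$bin_lo, 6),
                                  round(fp$bin_lo, 6))],
                 want$percent, tolerance = 1e-12)
    expect_equal(sum(fp$percent), 100, tolerance = 1e-6)
  }
})

test_that("fingerprints are invariant under cell-size duplication", {
  set.seed(3)
  v <- 1.36 + runif(40) * 0.03
  a <- compute_fingerprint(toy_stack(v), toy_mask(toy_stack(v)))
  dup <- toy_stack(rep(v, 2))
  b <- compute_fingerprint(dup, toy_mask(dup))
  expect_equal(a$bin_lo, b$bin_lo)
  expect_equal(a$percent, b$percent)
})

test_that("fingerprint_stats reduces hand-built cases correctly", {
  st <- toy_stack(rep(1.3725, 4))
  fp1 <- compute_fingerprint(st, toy_mask(st))
  s1 <- fingerprint_stats(fp1, band = c(1.37, 1.375))
  expect_equal(s1$frac_below_mode, 0)
  expect_equal(s1$frac_in_band, 100)
  expect_equal(s1$peak_height, 100)

  # three bins at 30 / 50 / 20 percent
  v <- c(rep(1.3650, 30), rep(1.3675, 50), rep(1.3700, 20))
  fp3 <- compute_fingerprint(toy_stack(v), toy_mask(toy_stack(v)))
  s3 <- fingerprint_stats(fp3)
  expect_equal(s3$mode_ri, 1.3675 + 0.00125)
  expect_equal(s3$frac_below_mode, 30)
  expect_equal(s3$peak_height, 50)
  expect_equal(s3$ri_min, 1.3650)
  expect_equal(s3$ri_max, 1.3700)
})

test_that("modal ties break toward the lower bin", {
  v <- c(rep(1.3650, 5), rep(1.3675, 5), rep(1.37, 2))
  fp <- compute_fingerprint(toy_stack(v), toy_mask(toy_stack(v)))
  s <- fingerprint_stats(fp)
  expect_equal(s$mode_ri, 1.3650 + 0.00125)
  expect_equal(s$frac_below_mode, 0)
})

test_that("cohort averaging weights cells equally and checks binning", {
  a <- compute_fingerprint(toy_stack(rep(1.365, 4)),
                           toy_mask(toy_stack(rep(1.365, 4))))
  b <- compute_fingerprint(toy_stack(rep(1.370, 8)),
                           toy_mask(toy_stack(rep(1.370, 8))))
  m <- mean_fingerprint(list(a, b))
  expect_equal(sum(m$percent), 100, tolerance = 1e-9)
  expect_equal(m$percent[m$bin_lo == 1.365], 50)  # not voxel-weighted
  odd <- compute_fingerprint(toy_stack(rep(1.365, 4)),
                             toy_mask(toy_stack(rep(1.365, 4))),
                             bin_width = 0.005)
  expect_error(mean_fingerprint(list(a, odd)), "binning")
})

test_that("identical cohorts give an all-zero shift report", {
  v <- c(rep(1.3675, 3), rep(1.37, 5), rep(1.3725, 2))
  fp <- compute_fingerprint(toy_stack(v), toy_mask(toy_stack(v)))
  rep0 <- compare_fingerprints(fp, fp)
  expect_equal(rep0$delta_peak_height, 0)
  expect_equal(rep0$delta_transition_band, 0)
  expect_equal(rep0$delta_high_ri_frac, 0)
  expect_equal(rep0$signed_area_right_of_mode, 0)
  odd <- compute_fingerprint(toy_stack(v), toy_mask(toy_stack(v)),
                             bin_width = 0.005)
  expect_error(compare_fingerprints(fp, odd), "binning mismatch")
})

test_that("empty mask is rejected", {
  st <- toy_stack(rep(1.37, 5))
  expect_error(cell_mask(array(FALSE, dim(st$voxels))), "empty")
})
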