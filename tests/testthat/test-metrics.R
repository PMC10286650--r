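test_that("dice handles identity, disjoint, half-overlap and empty cases", {
  a <- mask3d(array(0L, c(8, 8, 8)), c(2, 2, 2))
  a$voxels[2:3, 2:3, 2] <- 1L               # 2x2 square, 4 voxels
  b <- mask3d(array(0L, c(8, 8, 8)), c(2, 2, 2))
  b$voxels[2:3, 3:4, 2] <- 1L               # shifted by 1: overlap 2
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 2 * 2 / (4 + 4)) # 0.5 by enumeration
  d <- mask3d(array(0L, c(8, 8, 8)), c(2, 2, 2)); d$voxels[6, 6, 6] <- 1L
  expect_equal(dice(a, d), 0)
  e <- mask3d(array(0L, c(8, 8, 8)), c(2, 2, 2))
  expect_warning(v <- dice(e, e), "both masks empty")
  expect_equal(v, 1)
  expect_error(dice(a, mask3d(array(0L, c(4, 4, 4)), c(2, 2, 2))), "grid")
})

test_that("dice is symmetric and translation invariant", {
  set.seed(11)
  interior_mask <- function() {   # foreground away from the borders so a
    v <- array(0L, c(16, 16, 16)) # small shift cannot clip it
    v[5:12, 5:12, 5:12] <- as.integer(stats::runif(8^3) < 0.3)
    mask3d(v, c(2, 2, 2))
  }
  a <- interior_mask(); b <- interior_mask()
  expect_identical(dice(a, b), dice(b, a))
  sh <- c(2L, -1L, 3L)
  a2 <- mask3d(pancparts:::shift_array(a$voxels, sh), a$spacing, a$affine)
  b2 <- mask3d(pancparts:::shift_array(b$voxels, sh), b$spacing, b$affine)
  expect_identical(sum(a2$voxels), sum(a$voxels))
  expect_equal(dice(a2, b2), dice(a, b))
})

test_that("hd95 matches hand-computable cases", {
  a <- mask3d(array(0L, c(8, 8, 8)), c(2.5, 2, 1))
  a$voxels[2, 2, 2] <- 1L
  b <- mask3d(array(0L, c(8, 8, 8)), c(2.5, 2, 1))
  b$voxels[4, 2, 2] <- 1L                   # 2 voxels x 2.5 mm = 5 mm apart
  expect_equal(hd95(a, a), 0)
  expect_equal(hd95(a, b), 5)
  e <- mask3d(array(0L, c(8, 8, 8)), c(2.5, 2, 1))
  expect_error(hd95(a, e), "empty")
})

test_that("hd95 equals the brute-force oracle on random masks", {
  set.seed(99)
  for (rep in 1:20) {
    sp <- sample(c(1, 1.5, 2, 2.5), 3, replace = TRUE)
    a <- random_mask(c(16L, 16L, 16L), spacing = sp, p = 0.15)
    b <- random_mask(c(16L, 16L, 16L), spacing = sp, p = 0.15)
    if (sum(a$voxels) == 0 || sum(b$voxels) == 0) next
    expect_equal(hd95(a, b), hd95_oracle(a, b), tolerance = 1e-9)
    expect_equal(hd95(a, b), hd95(b, a), tolerance = 1e-9)
  }
})

test_that("volumes convert voxel counts to mL", {
  e <- mask3d(array(0L, c(4, 4, 4)), c(2, 2, 2))
  expect_equal(volume_ml(e), 0)
  m <- mask3d(array(1L, c(10, 10, 10)), c(2, 2, 2))
  expect_equal(volume_ml(m), 8.0)                    # 1000 x 8 mm^3
  m2 <- mask3d(array(c(rep(1L, 125), rep(0L, 75)), c(10, 10, 2)),
               c(2.23, 2.23, 4.5))
  expect_equal(volume_ml(m2), 125 * 2.23 * 2.23 * 4.5 / 1000,
               tolerance = 1e-12)                    # 2.797 mL
})

test_that("Bland-Altman reproduces closed forms", {
  z <- bland_altman(cbind(1:3, 1:3))
  expect_equal(z$bias, 0); expect_equal(z$loa_low, 0); expect_equal(z$loa_high, 0)
  ba <- bland_altman(cbind(c(2, 1), c(1, 2)))        # differences +1, -1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  expect_error(bland_altman(cbind(1, 2)), "n >= 2")
})

test_that("compare_parts matches per-part metric calls and flags absences", {
  ph <- generate_phantom(phantom_spec(seed = 15))
  # a rater-perturbation pair: move the boundary planes 4 mm along the tube
  gt <- ph$labels
  cl <- ph$centerline
  s <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  mkplane <- function(ss) {
    i <- which.min(abs(s - ss))
    d <- cl[min(i + 5, 1000), ] - cl[max(i - 5, 1), ]
    plane3d(cl[i, ], d / sqrt(sum(d^2)))
  }
  pt <- annotate_parts(ph$mask, mkplane(ph$boundaries[1] + 4),
                       mkplane(ph$boundaries[2] + 4))
  cp <- compare_parts(pt$parts, gt)
  expect_true(all(cp$present))
  for (i in 1:3) {
    ma <- part_mask(pt$parts, i); mb <- part_mask(gt, i)
    expect_equal(cp$dsc[i], dice(ma, mb))
    expect_equal(cp$hd95_mm[i], hd95(ma, mb))
    expect_equal(cp$dvol_ml[i], volume_ml(ma) - volume_ml(mb))
  }
  # self-comparison: perfect agreement
  self <- compare_parts(gt, gt)
  expect_equal(self$dsc, c(1, 1, 1))
  expect_equal(self$hd95_mm, c(0, 0, 0))
  expect_equal(self$dvol_ml, c(0, 0, 0))
  # remove the tail from one input: flagged absent, not scored
  no_tail <- gt
  no_tail$labels[no_tail$labels == 3L] <- 2L
  cp2 <- compare_parts(gt, no_tail)
  expect_false(cp2$present[3])
  expect_true(is.na(cp2$dsc[3]))
})

test_that("rank-test wrappers dispatch to the standard routines", {
  set.seed(3)
  x <- rnorm(12); y <- x + rnorm(12, 0.5, 0.2)
  a <- signed_rank_test(x, y)
  b <- stats::wilcox.test(x, y, paired = TRUE)
  expect_equal(a$p.value, b$p.value)
  u <- rank_sum_test(x, y)
  expect_equal(u$p.value, stats::wilcox.test(x, y)$p.value)
})
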