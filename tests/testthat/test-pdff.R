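# builds a labeled box volume and slice geometries for reslicing tests
make_labeled_box <- function() {
  lab <- array(0L, c(20, 20, 20))
  lab[4:17, 4:17, 4:17] <- 1L
  lab[4:17, 4:17, 10:13] <- 2L
  lab[4:17, 4:17, 14:17] <- 3L
  parts_labels(lab, c(2, 2, 2))
}

test_that("an axis-aligned coincident slice reslices to the exact 3D plane", {
  parts <- make_labeled_box()
  k <- 11L   # 0-based slice index 11 -> world z = 22
  aff <- diag(4); aff[1, 1] <- 2; aff[2, 2] <- 2; aff[3, 4] <- 22
  slice <- pdff_slice(matrix(10, 20, 20), c(2, 2, 6), aff)
  lab2d <- reslice_labels(parts, slice)
  expect_identical(lab2d, parts$labels[, , k + 1L])
})

test_that("a slice outside the volume is all background", {
  parts <- make_labeled_box()
  aff <- diag(4); aff[1, 1] <- 2; aff[2, 2] <- 2; aff[3, 4] <- 500
  slice <- pdff_slice(matrix(10, 16, 16), c(2, 2, 6), aff)
  lab2d <- reslice_labels(parts, slice)
  expect_true(all(lab2d == 0L))
  rep <- regional_pdff(lab2d, slice)
  for (p in names(rep)) expect_equal(rep[[p]]$reason, "not_in_slice")
})

test_that("oblique reslicing matches a per-pixel world-coordinate oracle", {
  parts <- make_labeled_box()
  set.seed(10)
  for (rep in 1:10) {
    # random oblique geometry through the box center
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    b1 <- c(-ax[2], ax[1], 0)
    if (sqrt(sum(b1^2)) < 1e-6) b1 <- c(0, -ax[3], ax[2])
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- c(ax[2] * b1[3] - ax[3] * b1[2],
            ax[3] * b1[1] - ax[1] * b1[3],
            ax[1] * b1[2] - ax[2] * b1[1])
    ps <- 2.5
    orig <- c(20, 20, 20) + stats::rnorm(3, sd = 4) - ps * 8 * (b1 + b2)
    aff <- cbind(c(b1 * ps, 0), c(b2 * ps, 0), c(ax * 6, 0), c(orig, 1))
    slice <- pdff_slice(matrix(10, 16, 16), c(ps, ps, 6), aff)
    got <- reslice_labels(parts, slice)
    # oracle: loop pixels, world -> voxel by hand, round, look up
    want <- matrix(0L, 16, 16)
    inv <- solve(parts$affine)
    for (i in 0:15) for (j in 0:15) {
      w <- aff %*% c(i, j, 0, 1)
      v <- round((inv %*% w)[1:3]) + 1
      if (all(v >= 1) && all(v <= 20))
        want[i + 1, j + 1] <- parts$labels[v[1], v[2], v[3]]
    }
    expect_identical(got, want)
  }
})

test_that("a 25-pixel part is excluded as small_segment", {
  lab <- matrix(0L, 16, 16)
  lab[2:6, 2:6] <- 1L   # 25 pixels <= 30
  pdff <- pdff_slice(matrix(10, 16, 16), c(2.5, 2.5, 6))
  rep <- regional_pdff(lab, pdff)
  expect_equal(rep$head$reason, "small_segment")
  expect_equal(rep$head$raw_n, 25L)
  expect_true(is.na(rep$head$median))
})

test_that("high-fat pixels are removed and the opened core median reported", {
  # 8x8 block of 10% PDFF with two interior pixels at 60%
  lab <- matrix(0L, 16, 16)
  lab[4:11, 4:11] <- 2L                      # 64 px body
  vals <- matrix(10, 16, 16)
  vals[6, 6] <- 60; vals[8, 9] <- 60
  pdff <- pdff_slice(vals, c(2.5, 2.5, 6))
  rep <- regional_pdff(lab, pdff)
  expect_true(is.na(rep$body$reason))
  expect_equal(rep$body$median, 10)
  # hand-applied steps: 64 raw; the two 60% pixels removed; opening of the
  # 62-pixel mask with the 3x3 cross keeps a non-empty core
  expect_equal(rep$body$raw_n, 64L)
  expect_lte(rep$body$qc_n, 62L)
  expect_gt(rep$body$qc_n, 0L)
})

test_that("a width-1 line survives no opening and is emptied_by_qc", {
  lab <- matrix(0L, 16, 48)
  lab[8, 4:43] <- 3L                         # 40 px, 1 px wide
  pdff <- pdff_slice(matrix(10, 16, 48), c(2.5, 2.5, 6))
  rep <- regional_pdff(lab, pdff)
  expect_equal(rep$tail$raw_n, 40L)
  expect_equal(rep$tail$reason, "emptied_by_qc")
  expect_true(is.na(rep$tail$median))
})

test_that("QC keeps only a subset of raw pixels and medians ignore order", {
  set.seed(8)
  lab <- matrix(0L, 24, 24)
  lab[3:20, 3:20] <- sample(1:3, 18 * 18, replace = TRUE)
  vals <- matrix(stats::runif(24 * 24, 0, 60), 24, 24)
  pdff <- pdff_slice(vals, c(2.5, 2.5, 6))
  rep <- regional_pdff(lab, pdff)
  for (p in names(rep)) {
    e <- rep[[p]]
    expect_lte(e$qc_n, e$raw_n)
    if (is.na(e$reason)) expect_true(is.finite(e$median))
  }
  # part-id relabeling leaves each part's numbers unchanged
  lab_swapped <- lab
  lab_swapped[lab == 1L] <- 3L
  lab_swapped[lab == 3L] <- 1L
  rep2 <- regional_pdff(lab_swapped, pdff)
  expect_equal(rep2$tail$median, rep$head$median)
  expect_equal(rep2$head$median, rep$tail$median)
})

test_that("merged whole-pancreas label can pass QC where each part fails", {
  # three parts of 20 px each (each <= 30 alone) forming a compact 60-px
  # block of 8% PDFF
  lab <- matrix(0L, 16, 16)
  lab[4:13, 4:5] <- 1L    # 20 px
  lab[4:13, 6:7] <- 2L    # 20 px
  lab[4:13, 8:9] <- 3L    # 20 px
  pdff <- pdff_slice(matrix(8, 16, 16), c(2.5, 2.5, 6))
  rep <- regional_pdff(lab, pdff)
  for (p in names(rep)) expect_equal(rep[[p]]$reason, "small_segment")
  whole <- whole_pancreas_pdff(lab, pdff)
  expect_true(is.na(whole$reason))
  expect_equal(whole$median, 8)
  # empty labels -> excluded
  expect_equal(whole_pancreas_pdff(matrix(0L, 16, 16), pdff)$reason,
               "not_in_slice")
  # a single part: whole equals that part's result
  lab1 <- matrix(0L, 16, 16); lab1[3:12, 3:12] <- 1L
  r1 <- regional_pdff(lab1, pdff)
  w1 <- whole_pancreas_pdff(lab1, pdff)
  expect_equal(w1$median, r1$head$median)
  expect_equal(w1$qc_n, r1$head$qc_n)
})

test_that("grid mismatches are rejected", {
  pdff <- pdff_slice(matrix(10, 8, 8), c(2.5, 2.5, 6))
  expect_error(regional_pdff(matrix(0L, 9, 8), pdff), "grid")
  expect_error(whole_pancreas_pdff(matrix(0L, 8, 9), pdff), "grid")
})
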