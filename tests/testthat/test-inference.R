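make_parts_template_small <- function() cached_parts_template(5, 101, 2)

test_that("subsegmenting the template mask itself reproduces the parts", {
  pt <- make_parts_template_small()
  res <- subsegment_template(pt$template_mask, pt)
  expect_identical(res$parts$labels, pt$parts$labels)
  cp <- compare_parts(res$parts, pt$parts)
  expect_equal(cp$dsc, c(1, 1, 1))
  expect_equal(cp$hd95_mm, c(0, 0, 0))
  expect_equal(res$warped_parts_coverage, 1)
})

test_that("template subsegmentation partitions held-out phantoms", {
  pt <- make_parts_template_small()
  co <- generate_cohort(phantom_spec(), 3, seed = 555)
  for (p in co) {
    res <- subsegment_template(p$mask, pt, reg_config_groupwise())
    expect_true(is_partition(res$parts, p$mask))
    expect_true(res$warped_parts_coverage >= 0 &&
                res$warped_parts_coverage <= 1)
  }
})

test_that("voxels outside the warped template get nearest labels", {
  pt <- make_parts_template_small()
  # subject = template mask dilated by one voxel: strictly larger, so the
  # extra shell must be labeled by the nearest-label rule
  v <- pt$template_mask$voxels
  dil <- pancparts:::c_edt_labels(v, c(1, 1, 1))$dist2 <= 1
  subject <- mask3d(dil * 1L, pt$template_mask$spacing,
                    pt$template_mask$affine)
  res <- subsegment_template(subject, pt)
  expect_true(is_partition(res$parts, subject))
  # all three parts survive and the label total matches the dilated mask
  for (l in 1:3) expect_gt(sum(res$parts$labels == l), 0)
  expect_equal(sum(res$parts$labels > 0L), sum(subject$voxels))
})

test_that("template subsegmentation is deterministic", {
  pt <- make_parts_template_small()
  ph <- generate_cohort(phantom_spec(), 2, seed = 777)[[1]]
  r1 <- subsegment_template(ph$mask, pt, reg_config_groupwise())
  r2 <- subsegment_template(ph$mask, pt, reg_config_groupwise())
  expect_identical(r1$parts$labels, r2$parts$labels)
})

test_that("k-means on a uniform tube cuts at thirds, matching the 1-D oracle", {
  cyl <- make_cylinder(dims = c(96L, 24L, 24L), spacing = c(2, 2, 2),
                       length_mm = 160, radius_mm = 8)
  res <- subsegment_kmeans(cyl, seed = 0, orientation = c(1, 0, 0))
  idx <- which(cyl$voxels == 1L, arr.ind = TRUE)
  x <- voxel_to_world(cyl, idx - 1)[, 1]
  lab <- res$parts$labels[which(cyl$voxels == 1L)]
  # boundaries between consecutive labels along x
  b12 <- (max(x[lab == 1L]) + min(x[lab == 2L])) / 2
  b23 <- (max(x[lab == 2L]) + min(x[lab == 3L])) / 2
  # exact 1-D 3-means on the x coordinates (profile is uniform in x)
  or <- kmeans3_1d_oracle(x)
  ob12 <- (or$boundaries[1] + or$next_after[1]) / 2
  ob23 <- (or$boundaries[2] + or$next_after[2]) / 2
  expect_lte(abs(b12 - ob12), 2)   # within one 2 mm voxel
  expect_lte(abs(b23 - ob23), 2)
  # thirds of a uniform [-80, 80] segment: cuts near -26.7 and +26.7
  expect_lte(abs(b12 - (-160 / 6)), 2 + 160 / 96)
  expect_lte(abs(b23 - (160 / 6)), 2 + 160 / 96)
  # parts are contiguous intervals
  expect_lt(max(x[lab == 1L]), min(x[lab == 2L]))
  expect_lt(max(x[lab == 2L]), min(x[lab == 3L]))
})

test_that("k-means is deterministic under a fixed seed and partitions", {
  ph <- generate_phantom(phantom_spec(seed = 31))
  r1 <- subsegment_kmeans(ph$mask, seed = 3)
  r2 <- subsegment_kmeans(ph$mask, seed = 3)
  expect_identical(r1$parts$labels, r2$parts$labels)
  expect_true(is_partition(r1$parts, ph$mask))
})

test_that("three separated blobs map to one part each, ordered along the axis", {
  dims <- c(48L, 16L, 16L); sp <- c(2, 2, 2)
  vox <- array(0L, dims)
  centers <- list(c(8, 8, 8), c(24, 8, 8), c(40, 8, 8))
  for (ci in seq_along(centers)) {
    cc <- centers[[ci]]
    for (i in -2:2) for (j in -2:2) for (k in -2:2)
      if (i^2 + j^2 + k^2 <= 4)
        vox[cc[1] + i, cc[2] + j, cc[3] + k] <- 1L
  }
  m <- mask3d(vox, sp)
  res <- subsegment_kmeans(m, seed = 1, orientation = c(1, 0, 0))
  idx <- which(vox == 1L, arr.ind = TRUE)
  lab <- res$parts$labels[which(vox == 1L)]
  # brute-force check: each blob entirely one label, ordered by x
  blob <- cut(idx[, 1], c(0, 16, 32, 48), labels = FALSE)
  expect_true(all(tapply(lab, blob, function(v) length(unique(v))) == 1))
  expect_equal(as.integer(tapply(lab, blob, unique)), c(1L, 2L, 3L),
               ignore_attr = TRUE)
})

test_that("template labeling beats k-means on the head of curved phantoms", {
  pt <- make_parts_template_small()
  co <- generate_cohort(phantom_spec(), 3, seed = 999)
  for (p in co) {
    rt <- subsegment_template(p$mask, pt, reg_config_groupwise())
    rk <- subsegment_kmeans(p$mask, seed = 0)
    dsc_t <- dice(part_mask(rt$parts, 1), part_mask(p$labels, 1))
    dsc_k <- dice(part_mask(rk$parts, 1), part_mask(p$labels, 1))
    expect_gt(dsc_t, dsc_k)
  }
})

test_that("k-means orients automatically with the bulky head first", {
  ph <- generate_phantom(phantom_spec(seed = 41))
  res <- subsegment_kmeans(ph$mask, seed = 5, orientation = "auto")
  # ground-truth head (label 1) should overlap predicted head more than
  # predicted tail
  gt_head <- ph$labels$labels == 1L
  expect_gt(sum(gt_head & res$parts$labels == 1L),
            sum(gt_head & res$parts$labels == 3L))
})

test_that("degenerate k-means inputs are rejected", {
  m <- mask3d(array(0L, c(8, 8, 8)), c(2, 2, 2))
  m$voxels[1:2] <- 1L
  expect_error(subsegment_kmeans(m, 0, c(1, 0, 0)), "at least 3")
  expect_error(subsegment_kmeans(make_sphere(radius_mm = 14), 0, "auto"),
               "not elongated")
})
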