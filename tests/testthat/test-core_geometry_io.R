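test_that("mask and label constructors enforce their invariants", {
  expect_error(mask3d(array(0.5, c(4, 4, 4))), "0 or 1")
  expect_error(mask3d(array(0L, c(4, 4))), "3D")
  expect_error(mask3d(array(0L, c(4, 4, 4)), spacing = c(2, -1, 2)), "positive")
  expect_error(mask3d(array(0L, c(4, 4, 4)), affine = matrix(0, 4, 4)),
               "invertible")
  expect_error(parts_labels(array(4L, c(4, 4, 4))), "\\{0,1,2,3\\}")
  expect_error(prob_template(array(1.2, c(4, 4, 4))), "\\[0, 1\\]")
  expect_error(plane3d(c(0, 0, 0), c(0, 0, 0)), "nonzero")
  expect_equal(sqrt(sum(plane3d(c(0, 0, 0), c(1, 2, 2))$normal^2)), 1,
               tolerance = 1e-12)
})

test_that("voxel-to-world agrees with hand computation on corner voxels", {
  aff <- matrix(c(0, -2, 0, 5,
                  2,  0, 0, -3,
                  0,  0, 2.5, 7,
                  0,  0, 0, 1), 4, 4, byrow = TRUE)
  m <- mask3d(array(0L, c(8, 10, 6)), spacing = c(2, 2, 2.5), affine = aff)
  # by hand: world = (-2*j + 5, 2*i - 3, 2.5*k + 7)
  expect_equal(drop(voxel_to_world(m, c(0, 0, 0))), c(5, -3, 7),
               tolerance = 1e-6)
  expect_equal(drop(voxel_to_world(m, c(7, 0, 0))), c(5, 11, 7),
               tolerance = 1e-6)
  expect_equal(drop(voxel_to_world(m, c(7, 9, 5))), c(-13, 11, 19.5),
               tolerance = 1e-6)
  ijk <- matrix(c(3, 4, 2), 1)
  expect_equal(world_to_voxel(m, voxel_to_world(m, ijk)), ijk,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("masks round-trip through NIfTI bit-exactly and threshold at >0.5", {
  withr::local_file("m.nii.gz")
  set.seed(42)
  m <- random_mask(c(12L, 10L, 8L), spacing = c(1.5, 2, 2.5))
  write_mask(m, "m.nii.gz")
  m2 <- read_mask("m.nii.gz")
  expect_identical(m2$voxels, m$voxels)
  expect_equal(m2$spacing, m$spacing, tolerance = 1e-6)
  expect_equal(m2$affine, m$affine, tolerance = 1e-6)

  # empty volume
  withr::local_file("e.nii.gz")
  write_mask(mask3d(array(0L, c(4, 4, 4))), "e.nii.gz")
  expect_equal(sum(read_mask("e.nii.gz")$voxels), 0)

  # 0/255 encoding: foreground where 255, per the >0.5 threshold rule
  withr::local_file("b.nii.gz")
  v255 <- m$voxels * 255L
  img <- RNifti::asNifti(v255)
  RNifti::pixdim(img) <- m$spacing
  RNifti::writeNifti(img, "b.nii.gz", datatype = "uint8")
  mb <- read_mask("b.nii.gz")
  expect_identical(mb$voxels, (v255 > 0.5) * 1L)

  expect_error(read_mask("does-not-exist.nii.gz"), "does not exist")
})

test_that("label maps round-trip including oblique affines", {
  withr::local_file("l.nii.gz")
  set.seed(7)
  lab <- array(sample(0:3, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  th <- 0.3
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  aff <- rbind(cbind(rot %*% diag(c(1.1, 1.3, 2)), c(4, -2, 9)), c(0, 0, 0, 1))
  l <- parts_labels(lab, spacing = c(1.1, 1.3, 2), affine = aff)
  write_labels(l, "l.nii.gz")
  l2 <- read_labels("l.nii.gz")
  expect_identical(l2$labels, l$labels)
  expect_equal(sort(unique(as.vector(l2$labels))), sort(unique(as.vector(lab))))
  expect_equal(l2$affine, aff, tolerance = 1e-6)
})

test_that("template and PDFF slice I/O round-trip", {
  withr::local_file(c("t.nii.gz", "p.nii.gz"))
  set.seed(1)
  tv <- array(runif(5 * 5 * 5), c(5, 5, 5))
  tm <- prob_template(tv, c(2, 2, 2))
  write_template(tm, "t.nii.gz")
  expect_equal(read_template("t.nii.gz")$values, tv, tolerance = 1e-6)

  pv <- matrix(runif(8 * 6, 0, 40), 8, 6)
  pv[2, 3] <- NA
  ps <- pdff_slice(pv, c(2.5, 2.5, 6))
  write_pdff_slice(ps, "p.nii.gz")
  ps2 <- read_pdff_slice("p.nii.gz")
  expect_equal(ps2$values, pv, tolerance = 1e-5)
  expect_true(is.na(ps2$values[2, 3]))
})

test_that("pdff_slice enforces the plausibility bound and marks missing", {
  expect_error(pdff_slice(matrix(c(10, 150), 1)), "plausible")
  s <- pdff_slice(matrix(c(10, Inf, -5, NaN), 2))
  expect_equal(sum(is.na(s$values)), 2)
})

test_that("DICOM geometry fields build a correctly placed slice", {
  # axial slice, identity orientation: LPS (x,y) negate into RAS
  vals <- matrix(0, 4, 4)
  s <- pdff_slice_from_dicom_geometry(vals,
                                      image_position_patient = c(-10, -20, 30),
                                      image_orientation_patient = c(1, 0, 0, 0, 1, 0),
                                      pixel_spacing = c(2.5, 2.5),
                                      slice_thickness = 6)
  # pixel (0,0) at IPP: LPS (-10,-20,30) -> RAS (10, 20, 30)
  w00 <- s$affine %*% c(0, 0, 0, 1)
  expect_equal(drop(w00)[1:3], c(10, 20, 30), tolerance = 1e-9)
  # stepping one column (first index) moves along the row direction (+x LPS
  # = -x RAS) by the column spacing
  w10 <- s$affine %*% c(1, 0, 0, 1)
  expect_equal(drop(w10)[1:3], c(10 - 2.5, 20, 30), tolerance = 1e-9)
})
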