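# NIfTI readers/writers for masks, label maps, templates and PDFF slices.
# All 3D volumes use NIfTI-1 through RNifti; 2D slices are stored as
# single-slice 3D volumes. The voxel-to-world affine is the NIfTI sform
# (0-based voxel indices, RAS mm) which matches the package convention.

read_nifti_vol <- function(path, expect = c("volume", "slice")) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop("cannot read '", path, "': file does not exist")
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  nd <- length(dim(a))
  if (nd == 4L && dim(a)[4] == 1L) {
    a <- array(a, dim(a)[1:3])
    nd <- 3L
  }
  if (expect == "volume") {
    if (nd != 3L)
      stop("expected a 3D volume in '", path, "', got ", nd, "D")
  } else {
    if (nd == 2L) a <- array(a, c(dim(a), 1L))
    else if (nd != 3L || dim(a)[3] != 1L)
      stop("expected a single-slice image in '", path, "'")
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  sp <- RNifti::pixdim(img)
  sp <- as.numeric(c(sp, rep(1, 3)))[1:3]
  list(data = a, spacing = sp, affine = aff)
}

write_nifti_vol <- function(data, spacing, affine, path, datatype) {
  img <- RNifti::asNifti(data)   # datatype applied at write time: asNifti
  RNifti::pixdim(img) <- spacing # with a datatype yields an immutable
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))  # internal image
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a whole-organ binary mask from NIfTI
#'
#' Stored values above 0.5 map to foreground, so 0/1, 0/255 and interpolated
#' encodings are all accepted.
#'
#' @param path path to a .nii or .nii.gz file containing a 3D volume.
#' @return a \code{\link{mask3d}}.
#' @export
read_mask <- function(path) {
  v <- read_nifti_vol(path)
  mask3d((v$data > 0.5) * 1L, v$spacing, v$affine)
}

#' Write a binary mask to NIfTI
#' @param mask a \code{\link{mask3d}}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask3d"))
  write_nifti_vol(mask$voxels, mask$spacing, mask$affine, path, "uint8")
}

#' Read a head/body/tail label map from NIfTI
#' @param path path to a .nii/.nii.gz with integer labels in \{0,1,2,3\}.
#' @return a \code{\link{parts_labels}}.
#' @export
read_labels <- function(path) {
  v <- read_nifti_vol(path)
  parts_labels(array(as.integer(round(v$data)), dim(v$data)), v$spacing, v$affine)
}

#' Write a label map to NIfTI (smallest unsigned integer type)
#' @param labels a \code{\link{parts_labels}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "parts_labels"))
  write_nifti_vol(labels$labels, labels$spacing, labels$affine, path, "uint8")
}

#' Read a probabilistic template from NIfTI
#' @param path path to a .nii/.nii.gz with values in [0,1].
#' @return a \code{\link{prob_template}}.
#' @export
read_template <- function(path) {
  v <- read_nifti_vol(path)
  vals <- pmin(pmax(v$data, 0), 1)  # clamp float32 round-off at the ends
  prob_template(vals, v$spacing, v$affine)
}

#' Write a probabilistic template to NIfTI (32-bit float)
#' @param template a \code{\link{prob_template}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "prob_template"))
  write_nifti_vol(template$values, template$spacing, template$affine, path, "float")
}

#' Read a 2D PDFF slice stored as a single-slice NIfTI
#'
#' Non-finite stored values are treated as missing pixels.
#'
#' @param path path to a .nii/.nii.gz whose third dimension is 1.
#' @return a \code{\link{pdff_slice}}.
#' @export
read_pdff_slice <- function(path) {
  v <- read_nifti_vol(path, expect = "slice")
  pdff_slice(v$data[, , 1L], v$spacing, v$affine)
}

#' Write a PDFF slice as a single-slice NIfTI
#' @param slice a \code{\link{pdff_slice}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdff_slice <- function(slice, path) {
  stopifnot(inherits(slice, "pdff_slice"))
  vals <- slice$values
  vals[!is.finite(vals)] <- NaN
  write_nifti_vol(array(vals, c(dim(vals), 1L)), slice$spacing, slice$affine,
                  path, "float")
}

#' Build PDFF slice geometry from DICOM Reference Coordinate System fields
#'
#' Constructs the pixel-to-world affine of a single-slice quantitative map
#' from the standard DICOM geometry attributes, without needing a DICOM
#' parser. DICOM positions/orientations are LPS; they are converted to the
#' RAS world frame used by the NIfTI volumes (x and y negated).
#'
#' @param values 2D matrix of PDFF percent values (rows = columns along the
#'   DICOM row direction, i.e. \code{values[i+1, j+1]} is the pixel at
#'   0-based column i, row j).
#' @param image_position_patient length-3 ImagePositionPatient (LPS mm).
#' @param image_orientation_patient length-6 ImageOrientationPatient
#'   (row direction cosines then column direction cosines, LPS).
#' @param pixel_spacing length-2 PixelSpacing: (row spacing, column spacing)
#'   in mm, i.e. spacing between rows first, per the DICOM attribute.
#' @param slice_thickness slice thickness in mm (default 1).
#' @return a \code{\link{pdff_slice}} in the RAS world frame.
#' @export
pdff_slice_from_dicom_geometry <- function(values, image_position_patient,
                                           image_orientation_patient,
                                           pixel_spacing,
                                           slice_thickness = 1) {
  ipp <- as.numeric(image_position_patient)
  iop <- as.numeric(image_orientation_patient)
  ps <- as.numeric(pixel_spacing)
  stopifnot(length(ipp) == 3L, length(iop) == 6L, length(ps) == 2L)
  row_dir <- iop[1:3]   # direction of increasing column index
  col_dir <- iop[4:6]   # direction of increasing row index
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  lps_to_ras <- diag(c(-1, -1, 1, 1))
  affine_lps <- cbind(c(row_dir * ps[2], 0),
                      c(col_dir * ps[1], 0),
                      c(normal * slice_thickness, 0),
                      c(ipp, 1))
  pdff_slice(values, spacing = c(ps[2], ps[1], slice_thickness),
             affine = lps_to_ras %*% affine_lps)
}
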