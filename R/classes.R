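#' @useDynLib pancparts, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

PART_LABELS <- c(head = 1L, body = 2L, tail = 3L)

#' Whole-organ binary mask on a voxel grid
#'
#' A 3D binary segmentation together with its voxel spacing (mm) and a 4x4
#' voxel-to-world affine (scanner RAS coordinates, mm). Voxel indices are
#' 0-based and refer to voxel centers, so world coordinates of voxel
#' \code{(i,j,k)} are \code{affine \%*\% c(i,j,k,1)}.
#'
#' @param voxels 3D array of 0/1 (integer or logical).
#' @param spacing numeric length-3, strictly positive voxel size in mm.
#' @param affine 4x4 invertible voxel-to-world matrix; default axis-aligned
#'   with the given spacing and origin at voxel (0,0,0).
#' @return An object of class \code{mask3d}.
#' @export
mask3d <- function(voxels, spacing = c(1, 1, 1), affine = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("mask3d: `voxels` must be a 3D array, got ", length(dim(voxels)), "D")
  if (!all(voxels %in% c(0, 1)))
    stop("mask3d: voxel values must be exactly 0 or 1")
  storage.mode(voxels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("mask3d: spacing must be 3 strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- check_affine(affine)
  structure(list(voxels = voxels, spacing = spacing, affine = affine),
            class = "mask3d")
}

#' Head/body/tail label map
#'
#' Integer label volume sharing a grid with a whole-organ mask:
#' 0 = background, 1 = head, 2 = body, 3 = tail.
#'
#' @param labels 3D array with values in \{0,1,2,3\}.
#' @inheritParams mask3d
#' @return An object of class \code{parts_labels}.
#' @export
parts_labels <- function(labels, spacing = c(1, 1, 1), affine = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("parts_labels: `labels` must be a 3D array")
  if (!all(labels %in% 0:3))
    stop("parts_labels: label values must lie in {0,1,2,3}")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("parts_labels: spacing must be 3 strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- check_affine(affine)
  structure(list(labels = labels, spacing = spacing, affine = affine),
            class = "parts_labels")
}

#' Probabilistic shape template
#'
#' Real-valued (0-1) population-average shape on a fixed grid, produced by
#' groupwise registration; binarizable at a threshold (conventionally 0.5).
#'
#' @param values 3D array of reals in [0, 1].
#' @inheritParams mask3d
#' @return An object of class \code{prob_template}.
#' @export
prob_template <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("prob_template: `values` must be a 3D array")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("prob_template: values must be finite and within [0, 1]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("prob_template: spacing must be 3 strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- check_affine(affine)
  structure(list(values = values, spacing = spacing, affine = affine),
            class = "prob_template")
}

#' 2D quantitative PDFF slice
#'
#' Single-slice proton density fat fraction map in percent units, with its
#' own scanner-coordinate geometry. The affine maps 0-based pixel indices
#' \code{(i,j)} (plus an implicit third index 0) to world mm, its third
#' column being the slice normal scaled by the slice thickness.
#'
#' @param values 2D numeric matrix, percent; \code{NA}/non-finite entries are
#'   treated as missing. Plausibility bound: non-missing values must lie in
#'   [-10, 110] (reconstruction noise tolerated).
#' @param spacing length-3: in-plane pixel size (mm, 2) and slice thickness.
#' @param affine 4x4 pixel-to-world matrix.
#' @return An object of class \code{pdff_slice}.
#' @export
pdff_slice <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ok <- is.finite(values)
  if (any(values[ok] < -10 | values[ok] > 110))
    stop("pdff_slice: non-missing PDFF values outside the plausible [-10, 110]% range")
  values[!ok] <- NA_real_
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("pdff_slice: spacing must be 3 strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- check_affine(affine)
  structure(list(values = values, spacing = spacing, affine = affine),
            class = "pdff_slice")
}

#' Oriented plane in world coordinates
#'
#' @param point length-3 world point on the plane (mm).
#' @param normal length-3 normal; normalized to unit length (must be nonzero).
#' @return An object of class \code{plane3d}.
#' @export
plane3d <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(point) != 3L || length(normal) != 3L)
    stop("plane3d: point and normal must have length 3")
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn < 1e-12)
    stop("plane3d: normal must be a nonzero vector")
  structure(list(point = point, normal = normal / nn), class = "plane3d")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  storage.mode(affine) <- "double"
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop("affine must be invertible")
  affine
}

grid_dim <- function(x) dim(vol_of(x))

vol_of <- function(x) {
  switch(class(x)[1],
         mask3d = x$voxels,
         parts_labels = x$labels,
         prob_template = x$values,
         stop("unsupported volume type: ", class(x)[1]))
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " must share shape and affine")
  invisible(TRUE)
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param x a volume object (\code{mask3d}, \code{parts_labels},
#'   \code{prob_template}) or a 4x4 affine.
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(x, ijk) {
  affine <- if (is.matrix(x)) check_affine(x) else x$affine
  ijk <- rbind_pts(ijk)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @export
world_to_voxel <- function(x, xyz) {
  affine <- if (is.matrix(x)) check_affine(x) else x$affine
  xyz <- rbind_pts(xyz)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  storage.mode(p) <- "double"
  p
}

#' Foreground centroid in world coordinates
#' @param mask a \code{mask3d}.
#' @return length-3 world mm coordinates of the foreground center of mass.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask_centroid: empty mask")
  colMeans(voxel_to_world(mask, idx - 1))
}

n_foreground <- function(mask) sum(vol_of(mask) != 0L)

#' Check that labels partition a mask
#'
#' The partition property: labels are nonzero exactly where the mask is 1.
#' @param labels a \code{parts_labels}.
#' @param mask a \code{mask3d} on the same grid.
#' @return logical scalar.
#' @export
is_partition <- function(labels, mask) {
  stop_if_grid_mismatch(labels, mask, "labels and mask")
  all((labels$labels > 0L) == (mask$voxels == 1L))
}

#' @export
print.mask3d <- function(x, ...) {
  cat("<mask3d> ", paste(dim(x$voxels), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, ", n_foreground(x), " foreground (",
      signif(volume_ml(x), 4), " mL)\n", sep = "")
  invisible(x)
}

#' @export
print.parts_labels <- function(x, ...) {
  counts <- vapply(PART_LABELS, function(l) sum(x$labels == l), integer(1))
  cat("<parts_labels> ", paste(dim(x$labels), collapse = "x"),
      " voxels; head/body/tail = ", paste(counts, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @export
print.prob_template <- function(x, ...) {
  cat("<prob_template> ", paste(dim(x$values), collapse = "x"),
      " voxels, values in [", signif(min(x$values), 3), ", ",
      signif(max(x$values), 3), "]\n", sep = "")
  invisible(x)
}

#' Extract one part as a binary mask
#' @param labels a \code{parts_labels}.
#' @param part 1 (head), 2 (body) or 3 (tail), or the part name.
#' @return a \code{mask3d} of that part.
#' @export
part_mask <- function(labels, part) {
  if (is.character(part)) part <- PART_LABELS[[match.arg(part, names(PART_LABELS))]]
  mask3d((labels$labels == as.integer(part)) * 1L, labels$spacing, labels$affine)
}

#' Signed distance of world points to an oriented plane
#' @param plane a \code{plane3d}.
#' @param xyz n x 3 world coordinates (mm).
#' @return numeric vector of signed distances (positive on the normal side).
#' @export
plane_signed_distance <- function(plane, xyz) {
  xyz <- rbind_pts(xyz)
  drop((xyz - matrix(plane$point, nrow(xyz), 3, byrow = TRUE)) %*% plane$normal)
}
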