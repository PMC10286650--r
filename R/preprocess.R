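# Preprocessing: bring heterogeneous input masks onto the common isotropic,
# centroid-aligned grid that groupwise registration requires.

#' Resample a binary mask to isotropic spacing
#'
#' The binary volume is linearly interpolated onto the new grid and
#' thresholded at 0.5 (volume-preserving for smooth shapes). The output grid
#' spans the input field of view along the same voxel axes.
#'
#' @param mask a \code{\link{mask3d}}.
#' @param target_spacing scalar target voxel size in mm (default 2).
#' @return a \code{\link{mask3d}} with isotropic spacing.
#' @export
resample_isotropic <- function(mask, target_spacing = 2) {
  stopifnot(inherits(mask, "mask3d"))
  if (target_spacing <= 0) stop("target_spacing must be > 0")
  if (n_foreground(mask) == 0L)
    warning("resample_isotropic: empty mask")
  scale <- target_spacing / mask$spacing
  if (all(abs(scale - 1) < 1e-12)) return(mask)
  odim <- pmax(1L, as.integer(ceiling(dim(mask$voxels) * mask$spacing / target_spacing)))
  A <- cbind(diag(scale), c(0, 0, 0))
  vals <- c_resample_affine(array(as.double(mask$voxels), dim(mask$voxels)),
                            A, odim, 0L)
  affine <- mask$affine %*% diag(c(scale, 1))
  mask3d((vals >= 0.5) * 1L, rep(target_spacing, 3), affine)
}

#' Resample a label map with the nearest-label rule
#' @param labels a \code{\link{parts_labels}}.
#' @inheritParams resample_isotropic
#' @return a \code{\link{parts_labels}}; the output value set is a subset of
#'   the input value set.
#' @export
resample_labels_isotropic <- function(labels, target_spacing = 2) {
  stopifnot(inherits(labels, "parts_labels"))
  if (target_spacing <= 0) stop("target_spacing must be > 0")
  scale <- target_spacing / labels$spacing
  if (all(abs(scale - 1) < 1e-12)) return(labels)
  odim <- pmax(1L, as.integer(ceiling(dim(labels$labels) * labels$spacing / target_spacing)))
  A <- cbind(diag(scale), c(0, 0, 0))
  vals <- c_resample_affine(array(as.double(labels$labels), dim(labels$labels)),
                            A, odim, 1L)
  affine <- labels$affine %*% diag(c(scale, 1))
  parts_labels(array(as.integer(vals), odim), rep(target_spacing, 3), affine)
}

#' Jointly resample a mask and its labels, preserving the partition
#'
#' The mask is resampled with linear interpolation + 0.5 threshold, the
#' labels with the nearest-label rule; any disagreement (foreground voxels
#' left unlabeled by the nearest-label pass) is repaired by assigning the
#' nearest labeled voxel's label, so the partition property holds exactly on
#' the output.
#'
#' @param mask a \code{\link{mask3d}}.
#' @param labels the matching \code{\link{parts_labels}}.
#' @inheritParams resample_isotropic
#' @return list(mask, labels) on the new grid.
#' @export
resample_pair_isotropic <- function(mask, labels, target_spacing = 2) {
  stop_if_grid_mismatch(mask, labels, "mask and labels")
  m2 <- resample_isotropic(mask, target_spacing)
  l2 <- resample_labels_isotropic(labels, target_spacing)
  lab <- l2$labels
  lab[m2$voxels == 0L] <- 0L
  miss <- m2$voxels == 1L & lab == 0L
  if (any(miss)) {
    lab[miss] <- nearest_label_fill(lab, m2$spacing)[miss]
  }
  list(mask = m2, labels = parts_labels(lab, m2$spacing, m2$affine))
}

# label for every voxel from its nearest labeled voxel, ties broken by the
# lowest label index (head < body < tail)
nearest_label_fill <- function(lab, spacing) {
  dists <- lapply(1:3, function(l)
    c_edt_labels(array(as.integer(lab == l), dim(lab)), spacing)$dist2)
  best <- array(1L, dim(lab))
  bestd <- dists[[1]]
  for (l in 2:3) {
    better <- dists[[l]] < bestd   # strict: ties keep the lower label
    best[better] <- as.integer(l)
    bestd[better] <- dists[[l]][better]
  }
  best[!is.finite(bestd)] <- 0L
  best
}

#' Align mask centroids by integer-voxel translation
#'
#' Every mask is shifted by a whole number of voxels so its foreground
#' centroid lands on the reference mask's centroid (within half a voxel;
#' the sub-voxel residual is absorbed by registration). Integer shifts keep
#' the masks exactly binary.
#'
#' @param masks list of \code{\link{mask3d}} on identical grids, all
#'   non-empty.
#' @param reference_index index of the reference mask (default 1).
#' @return list with \code{masks} (aligned) and \code{translations}
#'   (n x 3 matrix, mm in world axes; zero row for the reference).
#' @export
centroid_align <- function(masks, reference_index = 1L) {
  stopifnot(length(masks) >= 1L)
  for (i in seq_along(masks)) {
    if (!inherits(masks[[i]], "mask3d"))
      stop("centroid_align: element ", i, " is not a mask3d")
    if (n_foreground(masks[[i]]) == 0L)
      stop("centroid_align: mask ", i, " is empty")
    if (i > 1L && !same_grid(masks[[1L]], masks[[i]]))
      stop("centroid_align: mask ", i, " is not on the shared grid")
  }
  ref <- masks[[reference_index]]
  cref <- colMeans(which(ref$voxels == 1L, arr.ind = TRUE))
  shifts <- matrix(0, length(masks), 3)
  out <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    ci <- colMeans(which(masks[[i]]$voxels == 1L, arr.ind = TRUE))
    sh <- as.integer(round(cref - ci))
    out[[i]] <- mask3d(shift_array(masks[[i]]$voxels, sh),
                       masks[[i]]$spacing, masks[[i]]$affine)
    shifts[i, ] <- drop(masks[[i]]$affine[1:3, 1:3] %*% sh)
  }
  list(masks = out, translations = shifts)
}

shift_array <- function(a, sh) {
  d <- dim(a)
  out <- array(0L, d)
  src <- lapply(1:3, function(c) {
    i <- seq_len(d[c]) - sh[c]
    i[i >= 1 & i <= d[c]]
  })
  dst <- lapply(1:3, function(c) src[[c]] + sh[c])
  if (any(vapply(src, length, 1L) == 0L)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Preprocess a cohort of masks for template construction
#'
#' Resamples every mask to isotropic spacing, pads all to a shared shape,
#' aligns centroids to the reference subject by integer-voxel translation,
#' and crops to the smallest box containing every aligned foreground plus an
#' 8-voxel background margin.
#'
#' @param masks list of \code{\link{mask3d}}.
#' @param target_spacing isotropic spacing in mm (default 2).
#' @param reference_index subject whose centroid defines the common frame.
#' @param margin background margin in voxels (default 8).
#' @return list with \code{masks} (on the common grid) and
#'   \code{translations} (mm, from \code{\link{centroid_align}}).
#' @export
preprocess_cohort <- function(masks, target_spacing = 2, reference_index = 1L,
                              margin = 8L) {
  iso <- lapply(masks, resample_isotropic, target_spacing = target_spacing)
  shape <- apply(vapply(iso, function(m) dim(m$voxels), integer(3)), 1, max)
  padded <- lapply(iso, function(m) {
    a <- array(0L, shape)
    d <- dim(m$voxels)
    a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- m$voxels
    mask3d(a, m$spacing, m$affine)
  })
  al <- centroid_align(padded, reference_index)
  # common bounding box over all aligned foregrounds + margin
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (m in al$masks) {
    idx <- which(m$voxels == 1L, arr.ind = TRUE)
    lo <- pmin(lo, apply(idx, 2, min))
    hi <- pmax(hi, apply(idx, 2, max))
  }
  lo <- pmax(1, lo - margin); hi <- pmin(shape, hi + margin)
  cropped <- lapply(al$masks, function(m) {
    aff <- m$affine
    aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% (lo - 1)
    mask3d(m$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
           m$spacing, aff)
  })
  list(masks = cropped, translations = al$translations)
}
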