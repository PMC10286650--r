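# Segmentation agreement metrics: Dice, 95th-percentile Hausdorff distance,
# part volumes and Bland-Altman limits of agreement.

#' Dice similarity coefficient
#'
#' \code{2 |A intersect B| / (|A| + |B|)}. Two empty masks are defined as
#' perfect agreement (1) with a warning.
#'
#' @param a,b \code{\link{mask3d}} on a common grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b, "dice inputs")
  sa <- sum(a$voxels); sb <- sum(b$voxels)
  if (sa + sb == 0) {
    warning("dice: both masks empty; returning 1 (agreement on absence)")
    return(1)
  }
  2 * sum(a$voxels == 1L & b$voxels == 1L) / (sa + sb)
}

# 6-connectivity boundary: foreground voxels with at least one face
# neighbor that is background or outside the grid
boundary6 <- function(vox) {
  d <- dim(vox)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vox
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_min <- pmin(pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)],
                 pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)],
                 pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)],
                 pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)],
                 pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]],
                 pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)])
  core == 1L & nb_min == 0L
}

#' 95th-percentile Hausdorff distance
#'
#' Boundary voxels (6-connectivity erosion difference) of each mask; the
#' directed nearest-boundary distances from A to B and from B to A are
#' pooled and their 95th percentile (linear interpolation between order
#' statistics) returned, in mm. Distances are computed with an exact
#' anisotropic Euclidean distance transform.
#'
#' @param a,b non-empty \code{\link{mask3d}} on a common grid.
#' @param probs percentile (default 0.95).
#' @return distance in mm.
#' @export
hd95 <- function(a, b, probs = 0.95) {
  stop_if_grid_mismatch(a, b, "hd95 inputs")
  if (sum(a$voxels) == 0 || sum(b$voxels) == 0)
    stop("hd95: empty input mask")
  ba <- boundary6(a$voxels)
  bb <- boundary6(b$voxels)
  dta <- sqrt(c_edt_labels(array(as.integer(ba), dim(ba)), a$spacing)$dist2)
  dtb <- sqrt(c_edt_labels(array(as.integer(bb), dim(bb)), b$spacing)$dist2)
  pooled <- c(dtb[ba], dta[bb])   # A->B and B->A directed distances
  unname(stats::quantile(pooled, probs, type = 7))
}

#' Foreground volume in mL
#'
#' Foreground voxel count times the voxel volume (|det| of the affine's
#' linear part), converted from mm^3 to mL.
#'
#' @param mask a \code{\link{mask3d}}.
#' @return volume in mL.
#' @export
volume_ml <- function(mask) {
  stopifnot(inherits(mask, "mask3d"))
  sum(mask$voxels) * abs(det(mask$affine[1:3, 1:3])) / 1000
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean of paired differences (first minus second); the limits
#' of agreement are bias +/- 1.96 times the sample SD (n-1 denominator) of
#' the differences.
#'
#' @param pairs n x 2 matrix (or data frame) of paired measurements, n >= 2.
#' @return object of class \code{bland_altman}: list(bias, loa_low,
#'   loa_high, n).
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L || ncol(pairs) != 2L)
    stop("bland_altman: need an n x 2 matrix with n >= 2")
  d <- pairs[, 1] - pairs[, 2]
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, n = nrow(pairs)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n=%d): bias %.4g [LoA %.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Per-part agreement between two label maps
#'
#' Dice, 95\% Hausdorff distance (mm) and volume difference (mL, A - B) for
#' each part present (non-empty) in both inputs; parts empty in either are
#' flagged absent and not scored.
#'
#' @param a,b \code{\link{parts_labels}} on a common grid.
#' @return data frame with columns part, present, dsc, hd95_mm, dvol_ml.
#' @export
compare_parts <- function(a, b) {
  stop_if_grid_mismatch(a, b, "compare_parts inputs")
  rows <- lapply(names(PART_LABELS), function(p) {
    ma <- part_mask(a, p); mb <- part_mask(b, p)
    if (sum(ma$voxels) == 0 || sum(mb$voxels) == 0)
      return(data.frame(part = p, present = FALSE, dsc = NA_real_,
                        hd95_mm = NA_real_, dvol_ml = NA_real_))
    data.frame(part = p, present = TRUE,
               dsc = dice(ma, mb), hd95_mm = hd95(ma, mb),
               dvol_ml = volume_ml(ma) - volume_ml(mb))
  })
  do.call(rbind, rows)
}

#' Paired and unpaired rank tests for part-level quantities
#'
#' Thin wrappers over \code{stats::wilcox.test}: the Wilcoxon signed-rank
#' test for paired measurements and the Mann-Whitney U test for two groups.
#'
#' @param x,y numeric vectors.
#' @param ... passed to \code{stats::wilcox.test}.
#' @return an \code{htest} object.
#' @export
signed_rank_test <- function(x, y, ...) {
  stats::wilcox.test(x, y, paired = TRUE, ...)
}

#' @rdname signed_rank_test
#' @export
rank_sum_test <- function(x, y, ...) {
  stats::wilcox.test(x, y, paired = FALSE, ...)
}
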