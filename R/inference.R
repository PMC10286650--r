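# Subsegmentation of a new whole-organ mask: template registration with
# label propagation, and the spatial k-means baseline.

#' Subsegment a mask by template registration and label propagation
#'
#' The subject is centroid-aligned to the template, registered to the
#' binarized template, the parts template is warped back to subject space
#' through the inverse transform (nearest-label), and every subject
#' foreground voxel receives the warped label at its location or, where the
#' warped labels are background, the label of the nearest labeled warped
#' voxel (Euclidean distance in mm, ties to the lowest label index). The
#' result partitions the subject mask exactly.
#'
#' @param subject non-empty \code{\link{mask3d}} on the template grid
#'   (resample with \code{\link{resample_isotropic}} first if needed).
#' @param parts_template a \code{\link{annotate_parts}} result.
#' @param config a \code{\link{reg_config}}.
#' @return object of class \code{subseg_result}: list with \code{parts}
#'   (\code{\link{parts_labels}} on the subject grid),
#'   \code{warped_parts_coverage} (fraction of subject foreground directly
#'   covered by warped template labels), \code{method = "template"} and
#'   \code{diagnostics} (registration metadata).
#' @export
subsegment_template <- function(subject, parts_template,
                                config = reg_config()) {
  stopifnot(inherits(subject, "mask3d"),
            inherits(parts_template, "parts_template"))
  tmask <- parts_template$template_mask
  if (!identical(dim(subject$voxels), dim(tmask$voxels)))
    stop("subsegment_template: subject must be on the template grid (",
         paste(dim(tmask$voxels), collapse = "x"), ")")
  if (n_foreground(subject) == 0L) stop("subsegment_template: empty subject")

  # centroid initialization: integer-voxel shift of the subject onto the
  # template centroid, undone on the way back
  cs <- colMeans(which(subject$voxels == 1L, arr.ind = TRUE))
  ct <- colMeans(which(tmask$voxels == 1L, arr.ind = TRUE))
  sh <- as.integer(round(ct - cs))
  sub_al <- mask3d(shift_array(subject$voxels, sh), subject$spacing,
                   subject$affine)

  tr <- register_diffeo(sub_al, tmask, config)
  warped <- apply_transform(tr, parts_template$parts, "inverse")
  lab <- warped$labels
  fg <- sub_al$voxels == 1L
  covered <- sum(fg & lab > 0L) / sum(fg)
  lab[!fg] <- 0L
  miss <- fg & lab == 0L
  if (any(miss)) {
    fill <- nearest_label_fill(warped$labels, subject$spacing)
    lab[miss] <- fill[miss]
  }
  lab <- shift_array(lab, -sh)
  parts <- parts_labels(lab, subject$spacing, subject$affine)
  stopifnot(is_partition(parts, subject))
  structure(list(parts = parts, warped_parts_coverage = covered,
                 method = "template",
                 diagnostics = c(tr$meta, list(centroid_shift_voxels = sh))),
            class = "subseg_result")
}

#' Subsegment a mask by spatial k-means (baseline)
#'
#' k = 3 clustering of the foreground voxels' world coordinates (mm), with
#' k-means++ initialization and Lloyd iterations. Clusters are relabeled
#' head/body/tail by ascending projection of their centroids onto the
#' head-to-tail orientation axis.
#'
#' @param subject \code{\link{mask3d}} with at least 3 foreground voxels.
#' @param seed integer seed for the k-means++ initialization.
#' @param orientation length-3 world vector pointing head to tail, or
#'   \code{"auto"}: the first principal axis of the foreground, signed so
#'   that the bulkier end (larger mean cross-sectional spread over the first
#'   25\% of projections) is the head.
#' @return a \code{subseg_result} with \code{method = "kmeans"} and k-means
#'   inertia/iteration diagnostics.
#' @export
subsegment_kmeans <- function(subject, seed = 0L, orientation = "auto") {
  stopifnot(inherits(subject, "mask3d"))
  idx <- which(subject$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) < 3L)
    stop("subsegment_kmeans: need at least 3 foreground voxels")
  xyz <- voxel_to_world(subject, idx - 1)
  axis <- if (identical(orientation, "auto")) principal_head_tail_axis(xyz)
          else {
            v <- as.numeric(orientation)
            v / sqrt(sum(v^2))
          }
  set.seed(seed)
  centers <- kmeanspp_init(xyz, 3L)
  km <- suppressWarnings(stats::kmeans(xyz, centers = centers,
                                       iter.max = 300L, algorithm = "Lloyd"))
  proj <- drop(km$centers %*% axis)
  rank_lab <- match(seq_len(3L), order(proj))   # cluster -> part by axis order
  lab <- array(0L, dim(subject$voxels))
  lab[idx] <- rank_lab[km$cluster]
  parts <- parts_labels(lab, subject$spacing, subject$affine)
  stopifnot(is_partition(parts, subject))
  structure(list(parts = parts, warped_parts_coverage = 1,
                 method = "kmeans",
                 diagnostics = list(inertia = km$tot.withinss,
                                    iterations = km$iter,
                                    axis = axis)),
            class = "subseg_result")
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center drawn with probability proportional to the squared
# distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

principal_head_tail_axis <- function(xyz, min_elongation = 1.5) {
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  sdev <- pc$sdev
  if (sdev[1] / max(sdev[2], 1e-12) < min_elongation)
    stop("automatic orientation failed: shape is not elongated ",
         "(principal-axis ratio ", signif(sdev[1] / sdev[2], 3), " < ",
         min_elongation, "); supply an orientation vector")
  axis <- pc$rotation[, 1]
  proj <- drop(scale(xyz, center = TRUE, scale = FALSE) %*% axis)
  qs <- stats::quantile(proj, c(0.25, 0.75))
  perp <- function(sel) {
    sub <- scale(xyz[sel, , drop = FALSE], center = TRUE, scale = FALSE)
    p <- drop(sub %*% axis)
    sqrt(mean(rowSums(sub^2) - p^2))
  }
  lo_spread <- perp(proj <= qs[1])
  hi_spread <- perp(proj >= qs[2])
  if (hi_spread > lo_spread) axis <- -axis  # head (bulkier) at low projection
  axis
}

#' @export
print.subseg_result <- function(x, ...) {
  cat("<subseg_result> method=", x$method, ", coverage=",
      signif(x$warped_parts_coverage, 4), "\n  ", sep = "")
  print(x$parts)
  invisible(x)
}
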