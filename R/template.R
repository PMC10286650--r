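# Offline groupwise template construction, plane-based parts annotation and
# centerline utilities.

#' Build a probabilistic shape template by groupwise registration
#'
#' The initial average is the voxelwise mean of the centroid-aligned masks.
#' At each iteration every mask is registered to the current average, the
#' per-subject velocity fields are centered by subtracting their pointwise
#' mean (unbiased groupwise averaging: the average deformation across the
#' cohort is the identity, so the template does not drift toward any one
#' subject or toward the union of shapes), and the average is replaced by
#' the voxelwise mean of the masks warped by the centered velocities. On
#' identical inputs the registrations are exact identities, so the template
#' equals the common mask (a fixed point).
#'
#' @param masks list (>= 2) of preprocessed \code{\link{mask3d}} on a common
#'   grid, all non-empty.
#' @param n_iterations groupwise iterations (default 4).
#' @param config a \code{\link{reg_config}} for the pairwise registrations.
#' @param align if TRUE (default) centroid-align the masks first.
#' @return list with \code{template} (\code{\link{prob_template}}) and
#'   \code{transforms} (per-subject \code{diffeo_transform} from the final
#'   iteration, mapping each mask into template space).
#' @export
build_template <- function(masks, n_iterations = 4L,
                           config = reg_config_groupwise(),
                           align = TRUE) {
  if (length(masks) < 2L) stop("build_template: need at least 2 masks")
  for (i in seq_along(masks))
    if (n_foreground(masks[[i]]) == 0L)
      stop("build_template: mask ", i, " is empty")
  if (align) masks <- centroid_align(masks)$masks
  n <- length(masks)
  dims <- dim(masks[[1]]$voxels)
  arrs <- lapply(masks, function(m) array(as.double(m$voxels), dim(m$voxels)))
  # shared box for velocity centering and warping
  fg_any <- Reduce(`|`, lapply(arrs, function(a) a > 0))
  ubox <- union_bbox(fg_any, margin = 8L, dims = dims)
  avg <- Reduce(`+`, arrs) / n
  sp <- masks[[1]]$spacing; aff <- masks[[1]]$affine
  transforms <- vector("list", n)
  # later groupwise iterations warm-start from the previous velocity and
  # need only a short polish schedule
  warm_config <- config
  warm_config$iterations <- pmax(10L, config$iterations %/% 3L)
  for (it in seq_len(n_iterations)) {
    tmpl <- prob_template(pmin(pmax(avg, 0), 1), sp, aff)
    vels <- vector("list", n)
    for (i in seq_len(n)) {
      tr <- register_diffeo(masks[[i]], tmpl,
                            if (it == 1L) config else warm_config,
                            init = transforms[[i]], compute_fields = FALSE)
      transforms[[i]] <- tr
      vels[[i]] <- crop_box4(embed_field(tr$vel, tr$box, dims), ubox)
    }
    vbar <- Reduce(`+`, vels) / n
    warped <- vector("list", n)
    for (i in seq_len(n)) {
      vc <- vels[[i]] - vbar
      transforms[[i]]$vel <- vc
      transforms[[i]]$box <- ubox
      phi <- c_exp_field(vc, config$n_squarings)
      w <- arrs[[i]]
      w[ubox[[1]], ubox[[2]], ubox[[3]]] <-
        c_warp(crop_box(arrs[[i]], ubox), phi, 0L)
      warped[[i]] <- w
    }
    avg <- Reduce(`+`, warped) / n
  }
  # materialize displacement fields for the returned (centered) transforms
  for (i in seq_len(n)) {
    tr <- transforms[[i]]
    tr$forward <- field_to_mm(c_exp_field(tr$vel, tr$n_squarings), sp)
    tr$inverse <- field_to_mm(c_exp_field(-tr$vel, tr$n_squarings), sp)
    transforms[[i]] <- tr
  }
  list(template = prob_template(pmin(pmax(avg, 0), 1), sp, aff),
       transforms = transforms)
}

#' Binarize a probabilistic template
#'
#' Foreground where the template value is >= the threshold (inclusive, so
#' the conventional 0.5 cut is deterministic at ties).
#'
#' @param template a \code{\link{prob_template}}.
#' @param threshold in (0, 1); default 0.5.
#' @return a \code{\link{mask3d}}.
#' @export
binarize <- function(template, threshold = 0.5) {
  stopifnot(inherits(template, "prob_template"))
  if (threshold <= 0 || threshold >= 1)
    stop("binarize: threshold must lie strictly between 0 and 1")
  mask3d((template$values >= threshold) * 1L, template$spacing, template$affine)
}

#' Annotate a template mask into head/body/tail with two boundary planes
#'
#' Plane normals point from head toward tail. Head voxels lie on the
#' negative side of the head-body plane, tail voxels on the positive side of
#' the body-tail plane, and the body is what remains.
#'
#' @param template_mask binarized template (\code{\link{mask3d}}).
#' @param plane_hb head-body boundary \code{\link{plane3d}}.
#' @param plane_bt body-tail boundary \code{\link{plane3d}}.
#' @param provenance optional list recorded with the result (cohort size,
#'   iterations, threshold).
#' @return object of class \code{parts_template}: list(template_mask, parts,
#'   planes, provenance).
#' @export
annotate_parts <- function(template_mask, plane_hb, plane_bt,
                           provenance = list()) {
  stopifnot(inherits(template_mask, "mask3d"),
            inherits(plane_hb, "plane3d"), inherits(plane_bt, "plane3d"))
  idx <- which(template_mask$voxels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("annotate_parts: empty template mask")
  xyz <- voxel_to_world(template_mask, idx - 1)
  d_hb <- plane_signed_distance(plane_hb, xyz)
  d_bt <- plane_signed_distance(plane_bt, xyz)
  is_head <- d_hb < 0
  is_tail <- d_bt >= 0
  if (any(is_head & is_tail))
    stop("annotate_parts: inconsistent planes (head and tail regions overlap);",
         " check plane order and normal directions")
  lab <- array(0L, dim(template_mask$voxels))
  lab[idx] <- 2L
  lab[idx[is_head, , drop = FALSE]] <- 1L
  lab[idx[is_tail, , drop = FALSE]] <- 3L
  for (p in names(PART_LABELS))
    if (!any(lab == PART_LABELS[[p]]))
      stop("annotate_parts: the ", p, " part is empty; move the planes")
  structure(list(template_mask = template_mask,
                 parts = parts_labels(lab, template_mask$spacing,
                                      template_mask$affine),
                 planes = list(head_body = plane_hb, body_tail = plane_bt),
                 provenance = provenance),
            class = "parts_template")
}

#' @export
print.parts_template <- function(x, ...) {
  cat("<parts_template>\n  "); print(x$template_mask)
  cat("  "); print(x$parts)
  invisible(x)
}

depth_map <- function(mask) {
  bg <- array(as.integer(mask$voxels == 0L), dim(mask$voxels))
  if (!any(bg == 1L)) stop("depth_map: mask fills the whole grid")
  sqrt(c_edt_labels(bg, mask$spacing)$dist2)
}

#' Extract the centerline of an elongated mask
#'
#' The two geodesic extremities of the 26-connected foreground graph are
#' found by two farthest-point sweeps; a geodesic path between them with
#' edge costs penalized by the distance-to-boundary map pulls the path onto
#' the medial axis. Because the extremities lie on the organ surface at the
#' tips, each end of the path is then trimmed while its depth is still
#' climbing toward the local tube radius, so the centerline starts and ends
#' at the end-cap centers (on the axis) rather than on the surface.
#' Finally the path is moving-average smoothed (window 5). The head end
#' (the bulkier end by local depth) comes first; supply \code{orientation}
#' (a world vector pointing head to tail) to override.
#'
#' @param mask single-component elongated \code{\link{mask3d}}.
#' @param orientation optional length-3 world vector, head toward tail.
#' @param min_elongation masks whose extremity geodesic distance is less
#'   than this multiple of twice the maximum inscribed radius are rejected
#'   as near-spherical (default 1.5).
#' @return n x 3 matrix of ordered world points (head end first), with the
#'   arc length in attribute \code{"arc_length"}.
#' @export
compute_centerline <- function(mask, orientation = NULL, min_elongation = 1.5) {
  stopifnot(inherits(mask, "mask3d"))
  if (n_foreground(mask) == 0L) stop("compute_centerline: empty mask")
  comp <- c_cc26(array(mask$voxels, dim(mask$voxels)))
  if (max(comp) > 1L)
    stop("compute_centerline: mask has ", max(comp),
         " connected components; expected a single component")
  dep <- depth_map(mask)
  dep[mask$voxels == 0L] <- 0
  start <- which.max(dep)   # most interior voxel
  g1 <- c_geodesic(mask$voxels, mask$spacing, dep, start, -1L, 0)
  e1 <- as.integer(g1$target)
  g2 <- c_geodesic(mask$voxels, mask$spacing, dep, e1, -1L, 0)
  e2 <- as.integer(g2$target)
  extremal_dist <- g2$dist[e2]
  elong <- extremal_dist / (2 * max(dep))
  if (elong < min_elongation)
    stop("compute_centerline: shape is not elongated enough (elongation ",
         signif(elong, 3), " < ", min_elongation, ")")
  gp <- c_geodesic(mask$voxels, mask$spacing, dep, e1, e2, 2)
  path_idx <- arrayInd(gp$path, dim(mask$voxels))
  pts <- voxel_to_world(mask, path_idx - 1)
  dep_path <- dep[gp$path]
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  keep <- trim_cap_climb(dep_path, arc)
  pts <- pts[keep[1]:keep[2], , drop = FALSE]
  dep_path <- dep_path[keep[1]:keep[2]]
  pts <- movavg_rows(pts, 5L)
  # orient head first
  n <- nrow(pts)
  q <- max(2L, round(n * 0.25))
  flip <- mean(dep_path[seq_len(q)]) < mean(dep_path[seq(n - q + 1L, n)])
  if (!is.null(orientation)) {
    proj <- drop(pts %*% as.numeric(orientation))
    flip <- proj[1] > proj[n]
  }
  if (flip) pts <- pts[n:1, , drop = FALSE]
  attr(pts, "arc_length") <- polyline_length(pts)
  pts
}

# indices (first, last) after removing the surface-to-axis climb at both
# ends. On the climb from a surface tip toward the cap center the depth
# grows at a slope of ~1 per mm of path; past the cap center it follows the
# gentle radius taper. Each end is trimmed while the smoothed depth slope
# exceeds 0.35 (well above any anatomical taper, well below the cap climb),
# searching at most the first/last quarter of the path.
trim_cap_climb <- function(dep_path, arc, slope_thr = 0.35) {
  n <- length(dep_path)
  if (n < 10L) return(c(1L, n))
  d <- stats::filter(dep_path, rep(1 / 3, 3), sides = 2)
  d[is.na(d)] <- dep_path[is.na(d)]
  w <- 2L   # slope over a ~2-step (4-6 mm) forward window
  slope_at <- function(i, dir) {
    j <- i + dir * w
    j <- min(max(j, 1L), n)
    if (abs(arc[j] - arc[i]) < 1e-9) return(0)
    (d[j] - d[i]) / abs(arc[j] - arc[i])
  }
  lim <- max(2L, round(0.25 * n))
  first <- 1L
  while (first < lim && slope_at(first, 1L) > slope_thr) first <- first + 1L
  last <- n
  while (last > n - lim && slope_at(last, -1L) > slope_thr) last <- last - 1L
  c(first, last)
}

movavg_rows <- function(p, w) {
  n <- nrow(p)
  if (n <= w) return(p)
  h <- w %/% 2
  out <- p
  for (i in seq_len(n)) {
    a <- max(1L, i - h); b <- min(n, i + h)
    out[i, ] <- colMeans(p[a:b, , drop = FALSE])
  }
  out
}

#' Annotate a template mask by arc-length fractions of its centerline
#'
#' Numeric stand-in for the manual annotation step: boundary planes are
#' placed orthogonal to the template's centerline, the head-body plane at
#' \code{head_fraction} of the centerline length and the body-tail plane at
#' the midpoint of the remaining length (see
#' \code{\link{midpoint_body_tail_boundary}}).
#'
#' The centerline from \code{\link{compute_centerline}} spans the end-cap
#' centers, so arc-length fractions along it correspond directly to the
#' anatomical fractions used for the ground-truth phantom labels.
#'
#' @param template_mask binarized template (\code{\link{mask3d}}).
#' @param head_fraction arc-length fraction of the head-body boundary
#'   (default 0.40).
#' @param provenance optional provenance list stored with the result.
#' @return a \code{parts_template} (see \code{\link{annotate_parts}}).
#' @export
annotate_by_arclength <- function(template_mask, head_fraction = 0.40,
                                  provenance = list()) {
  stopifnot(head_fraction > 0, head_fraction < 1)
  cl <- compute_centerline(template_mask)
  n <- nrow(cl)
  seg <- sqrt(rowSums(diff(cl)^2))
  s <- c(0, cumsum(seg))
  L <- s[n]
  hb_s <- head_fraction * L
  bt_s <- midpoint_body_tail_boundary(cl, hb_s)
  pt_at <- function(ss) cl[which.min(abs(s - ss)), ]
  dir_at <- function(ss) {
    i <- which.min(abs(s - ss))
    d <- cl[min(i + 5L, n), ] - cl[max(i - 5L, 1L), ]
    d / sqrt(sum(d^2))
  }
  annotate_parts(template_mask,
                 plane3d(pt_at(hb_s), dir_at(hb_s)),
                 plane3d(pt_at(bt_s), dir_at(bt_s)),
                 provenance = c(provenance,
                                list(head_fraction = head_fraction,
                                     arc_length = L)))
}

#' Arc length of an ordered polyline
#' @param pts n x 3 matrix of world points.
#' @return total length in mm.
#' @export
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Body-tail boundary as the midpoint of the remaining length
#'
#' Given the arc-length position of the head-body boundary along a
#' centerline, the body-tail boundary is placed at the midpoint between that
#' boundary and the tail tip: \code{hb + (total - hb) / 2}. This mirrors the
#' anatomical convention that the body-tail boundary is the lengthwise
#' midpoint of the combined body and tail.
#'
#' @param centerline ordered world points (head first), e.g. from
#'   \code{\link{compute_centerline}}.
#' @param head_body_arclength arc length (mm) of the head-body boundary;
#'   must satisfy \code{0 <= hb < total}.
#' @return arc length (mm) of the body-tail boundary.
#' @export
midpoint_body_tail_boundary <- function(centerline, head_body_arclength) {
  total <- polyline_length(centerline)
  if (!is.finite(head_body_arclength) || head_body_arclength < 0 ||
      head_body_arclength >= total)
    stop("midpoint_body_tail_boundary: head_body_arclength must lie in [0, ",
         signif(total, 6), ")")
  head_body_arclength + (total - head_body_arclength) / 2
}
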