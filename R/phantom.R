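# Synthetic pancreas phantom: an elongated, curved, tapering tube with known
# ground-truth head/body/tail labels, standing in for whole-pancreas
# segmentations so the full pipeline is testable without imaging data.

#' Specification of a synthetic pancreas phantom
#'
#' The phantom is a curved tube: a cubic spline through 5 control points
#' (densely resampled to 1000 polyline samples) with a radius profile that
#' linearly tapers head -> body -> tail. Ground-truth labels are assigned by
#' nearest-centerline-sample arc length: head below
#' \code{head_fraction * L}, and the body-tail boundary at the midpoint of
#' the remaining length, \code{head_fraction * L + (L - head_fraction * L)/2}
#' (the conventional anatomical definition of the body-tail boundary as the
#' lengthwise midpoint of the combined body+tail).
#'
#' Defaults emulate a pancreas-like organ scaled to fit a 64^3 grid at 2 mm
#' isotropic spacing: ~85 mm centerline, bulky head tapering to a thin tail.
#'
#' @param grid_shape voxels per axis (default 64^3).
#' @param spacing voxel size mm (default 2 mm isotropic).
#' @param centerline_length target centerline arc length, mm.
#' @param curvature_amplitude lateral bowing of the centerline, mm.
#' @param radius_head,radius_body,radius_tail tube radii, mm; the radius
#'   profile interpolates head (arc length 0) -> body (mid-arc) -> tail (end).
#' @param head_fraction arc-length fraction at the head-body boundary.
#' @param noise_sd standard deviation (mm) of Gaussian perturbation applied
#'   to the spline control points.
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return an object of class \code{phantom_spec} (a named list).
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(2, 2, 2),
                         centerline_length = 85,
                         curvature_amplitude = 12,
                         radius_head = 10.5,
                         radius_body = 8,
                         radius_tail = 5.5,
                         head_fraction = 0.40,
                         noise_sd = 1.5,
                         seed = 1L) {
  radii <- c(radius_head, radius_body, radius_tail)
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("phantom_spec: radii must be strictly positive")
  if (!is.finite(head_fraction) || head_fraction <= 0 || head_fraction >= 1)
    stop("phantom_spec: head_fraction must lie strictly between 0 and 1")
  if (centerline_length <= 0) stop("phantom_spec: centerline_length must be positive")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 centerline_length = centerline_length,
                 curvature_amplitude = curvature_amplitude,
                 radius_head = radius_head, radius_body = radius_body,
                 radius_tail = radius_tail,
                 head_fraction = head_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_centerline <- function(spec) {
  # 5 control points along x with sinusoidal bowing in y and a gentler
  # S-curve in z, perturbed by noise_sd, then rescaled so the dense polyline
  # arc length equals centerline_length exactly and centered at world 0.
  set.seed(spec$seed)
  tt <- seq(0, 1, length.out = 5)
  ctrl <- cbind((tt - 0.5) * spec$centerline_length,
                spec$curvature_amplitude * sin(pi * tt),
                0.3 * spec$curvature_amplitude * sin(2 * pi * tt))
  ctrl <- ctrl + matrix(stats::rnorm(15, sd = spec$noise_sd), 5, 3)
  ts <- seq(0, 1, length.out = 1000)
  pts <- vapply(1:3, function(c)
    stats::spline(tt, ctrl[, c], xout = ts, method = "natural")$y,
    numeric(1000))
  seg <- sqrt(rowSums(diff(pts)^2))
  pts <- pts * (spec$centerline_length / sum(seg))
  pts <- sweep(pts, 2, colMeans(pts))
  pts
}

phantom_radii <- function(spec, s, total) {
  # piecewise-linear radius profile: head radius at s=0, body radius at
  # mid-arc, tail radius at s=total
  mid <- total / 2
  ifelse(s <= mid,
         spec$radius_head + (spec$radius_body - spec$radius_head) * s / mid,
         spec$radius_body + (spec$radius_tail - spec$radius_body) * (s - mid) / mid)
}

#' Generate one synthetic pancreas phantom
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{mask} (\code{\link{mask3d}}), \code{labels}
#'   (\code{\link{parts_labels}} ground truth), \code{centerline}
#'   (1000 x 3 matrix of ordered world points, head to tail) and
#'   \code{arc_length} (mm).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  pts <- phantom_centerline(spec)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  radii <- phantom_radii(spec, s, total)

  dims <- spec$grid_shape
  sp <- spec$spacing
  origin <- -(dims - 1) / 2 * sp   # grid centered on world 0
  lo <- origin + 2 * sp            # 2-voxel margin
  hi <- origin + (dims - 1) * sp - 2 * sp
  for (t in seq_len(nrow(pts))) {
    if (any(pts[t, ] - radii[t] < lo) || any(pts[t, ] + radii[t] > hi))
      stop("phantom tube exits the grid at centerline point ", t,
           " (world ", paste(signif(pts[t, ], 4), collapse = ", "), " mm)")
  }

  vox <- c_tube_voxelize(dims, sp, origin, pts, radii)
  affine <- diag(c(sp, 1)); affine[1:3, 4] <- origin
  mask <- mask3d(vox$mask, sp, affine)

  hb <- spec$head_fraction * total
  bt <- hb + (total - hb) / 2
  svox <- s[pmax(vox$nearest, 1L)]        # arc length of nearest sample
  lab <- array(0L, dims)
  fg <- vox$mask == 1L
  lab[fg] <- ifelse(svox[fg] < hb, 1L, ifelse(svox[fg] < bt, 2L, 3L))
  labels <- parts_labels(lab, sp, affine)
  list(mask = mask, labels = labels, centerline = pts, arc_length = total,
       boundaries = c(head_body = hb, body_tail = bt))
}

#' Generate a cohort of phantoms with inter-subject variation
#'
#' Each subject gets independently jittered radii (uniform +/-15%) and an
#' independently perturbed centerline (Gaussian \code{noise_sd} on control
#' points, via a per-subject seed). Deterministic under \code{seed}.
#'
#' @param base_spec a \code{\link{phantom_spec}} giving the population mean.
#' @param n number of subjects (>= 2).
#' @param seed integer cohort seed.
#' @return list of length \code{n}; each element as in
#'   \code{\link{generate_phantom}} plus the realized \code{spec}.
#' @export
generate_cohort <- function(base_spec, n, seed = 1L) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (n < 2) stop("generate_cohort: n must be >= 2")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  jit <- matrix(stats::runif(3 * n, 0.85, 1.15), n, 3)
  lapply(seq_len(n), function(i) {
    sp_i <- base_spec
    sp_i$radius_head <- base_spec$radius_head * jit[i, 1]
    sp_i$radius_body <- base_spec$radius_body * jit[i, 2]
    sp_i$radius_tail <- base_spec$radius_tail * jit[i, 3]
    sp_i$seed <- sub_seeds[i]
    ph <- generate_phantom(sp_i)
    ph$spec <- sp_i
    ph
  })
}
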