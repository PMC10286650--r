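# Diffeomorphic registration of binary shapes. The algorithm is a
# stationary-velocity diffeomorphic demons scheme on Gaussian-smoothed
# binary images: the velocity field is exponentiated by scaling and
# squaring, giving an invertible warp whose inverse is the exponential of
# the negated velocity (exact for stationary fields). Multi-resolution
# (coarse to fine); similarity is the mean squared difference of the
# smoothed images. Fields are computed and stored on the union foreground
# bounding box (plus margin); the transform is the identity outside it.

#' Registration settings
#'
#' @param level_factors downsampling factors, coarse to fine.
#' @param iterations maximum demons iterations per level.
#' @param sigma_image Gaussian smoothing (voxels) applied to the binary
#'   inputs before matching.
#' @param sigma_fluid Gaussian smoothing (voxels) of each demons update.
#' @param sigma_elastic Gaussian smoothing (voxels) of the velocity field.
#' @param n_squarings scaling-and-squaring steps in the field exponential.
#' @param tol relative similarity change below which an iteration counts as
#'   stationary; 5 consecutive stationary iterations stop a level.
#' @return list of class \code{reg_config}.
#' @export
reg_config <- function(level_factors = c(4L, 2L, 1L),
                       iterations = c(60L, 40L, 20L),
                       sigma_image = 1,
                       sigma_fluid = 1,
                       sigma_elastic = 1,
                       n_squarings = 4L,
                       tol = 1e-5) {
  stopifnot(length(level_factors) == length(iterations))
  structure(list(level_factors = as.integer(level_factors),
                 iterations = as.integer(iterations),
                 sigma_image = sigma_image, sigma_fluid = sigma_fluid,
                 sigma_elastic = sigma_elastic,
                 n_squarings = as.integer(n_squarings), tol = tol),
            class = "reg_config")
}

#' @rdname reg_config
#' @param ... passed to \code{reg_config}.
#' @details \code{reg_config_groupwise} is the schedule used during
#'   groupwise template construction: it stops at half resolution, since the
#'   population average only needs approximate correspondence and is
#'   binarized afterwards; inference registrations use the full three-level
#'   schedule.
#' @export
reg_config_groupwise <- function(...) {
  reg_config(level_factors = c(4L, 2L), iterations = c(60L, 30L), ...)
}

as_intensity <- function(x) {
  v <- vol_of(x)
  array(as.double(v), dim(v))
}

downsample_vol <- function(v, f) {
  if (f == 1L) return(v)
  odim <- pmax(1L, as.integer(ceiling(dim(v) / f)))
  c_resample_affine(v, cbind(diag(rep(as.double(f), 3)), c(0, 0, 0)), odim, 0L)
}

resample_field <- function(vel, f_from, f_to, odim) {
  # velocity sampled on a factor-f_from grid, displacements in that grid's
  # voxel units; resample to a factor-f_to grid and rescale the values
  scale <- f_from / f_to
  out <- array(0, c(odim, 3L))
  A <- cbind(diag(rep(1 / scale, 3)), c(0, 0, 0))
  for (c in 1:3)
    out[, , , c] <- c_resample_affine(vel[, , , c, drop = TRUE], A, odim, 0L) * scale
  out
}

union_bbox <- function(fg, margin, dims) {
  idx <- which(fg, arr.ind = TRUE)
  lo <- pmax(1L, apply(idx, 2, min) - margin)
  hi <- pmin(dims, apply(idx, 2, max) + margin)
  lapply(1:3, function(c) lo[c]:hi[c])
}

crop_box <- function(a, box) a[box[[1]], box[[2]], box[[3]], drop = FALSE]

embed_field <- function(u, box, full_dims) {
  if (identical(dim(u)[1:3], as.integer(full_dims))) return(u)
  out <- array(0, c(full_dims, 3L))
  out[box[[1]], box[[2]], box[[3]], ] <- u
  out
}

#' Register one shape to another with an invertible diffeomorphic warp
#'
#' Computes a transform mapping \code{moving} onto \code{fixed}. The result
#' carries the forward displacement field (on the fixed grid: a fixed-grid
#' point x samples the moving image at x + u_fwd(x)) and the inverse field
#' (on the moving grid), both in mm along the grid axes. If registration
#' fails to improve overlap the identity transform is returned with
#' \code{improved = FALSE} (the warp is never worse than no warp).
#'
#' @param moving,fixed \code{\link{mask3d}} or \code{\link{prob_template}}
#'   on the same grid, both non-empty.
#' @param config a \code{\link{reg_config}}.
#' @param init optional \code{diffeo_transform} from a previous registration
#'   of the same moving image; its velocity field warm-starts the coarsest
#'   level.
#' @param compute_fields if FALSE, skip exponentiating the velocity into
#'   displacement fields (and the overlap guard); used internally by the
#'   groupwise loop, which centers velocities before exponentiating.
#' @return object of class \code{diffeo_transform}: list with
#'   \code{forward}, \code{inverse} (4D arrays, mm, on the stored
#'   \code{box}), \code{box}, \code{dims}, \code{spacing}, \code{affine},
#'   the velocity field \code{vel} (voxel units), and \code{meta}
#'   (iterations, final similarity, convergence and improvement flags, Dice
#'   before/after).
#' @export
register_diffeo <- function(moving, fixed, config = reg_config(),
                            init = NULL, compute_fields = TRUE) {
  stop_if_grid_mismatch(moving, fixed, "moving and fixed")
  M_full <- as_intensity(moving)
  F_full <- as_intensity(fixed)
  if (sum(M_full) == 0 || sum(F_full) == 0)
    stop("register_diffeo: empty input image")
  full_dims <- dim(M_full)
  # the velocity is only nonzero near the shapes: iterate on the union
  # foreground bounding box plus margin, identity outside
  box <- union_bbox(M_full > 0.01 | F_full > 0.01, margin = 8L,
                    dims = full_dims)
  M <- crop_box(M_full, box)
  F <- crop_box(F_full, box)
  dims <- dim(M)
  Ms <- c_gauss3(M, config$sigma_image)
  Fs <- c_gauss3(F, config$sigma_image)

  nl <- length(config$level_factors)
  vel <- NULL
  vel_factor <- NA_integer_
  if (!is.null(init)) {
    stopifnot(inherits(init, "diffeo_transform"))
    vfull <- embed_field(init$vel, init$box, full_dims)
    vel <- crop_box4(vfull, box)
    vel_factor <- 1L
  }
  iters <- integer(0)
  converged <- TRUE
  mse <- NA_real_
  for (li in seq_len(nl)) {
    f <- config$level_factors[li]
    Fl <- downsample_vol(Fs, f)
    Ml <- downsample_vol(Ms, f)
    ldim <- dim(Fl)
    v0 <- if (is.null(vel)) numeric(0)
          else resample_field(vel, vel_factor, f, ldim)
    res <- c_demons_level(Fl, Ml, as.numeric(v0), config$iterations[li],
                          config$sigma_fluid, config$sigma_elastic,
                          config$n_squarings, config$tol)
    vel <- array(res$vel, c(ldim, 3L))
    vel_factor <- f
    iters <- c(iters, res$iterations)
    mse <- res$mse
    if (li == nl) converged <- res$converged || res$iterations < config$iterations[li]
  }
  if (vel_factor != 1L)   # schedule stopped coarse: bring velocity to full res
    vel <- resample_field(vel, vel_factor, 1L, dims)
  sp <- moving$spacing
  fwd_mm <- NULL; inv_mm <- NULL
  dsc0 <- NA_real_; dsc1 <- NA_real_; improved <- NA
  if (compute_fields) {
    fwd_vox <- c_exp_field(vel, config$n_squarings)
    inv_vox <- c_exp_field(-vel, config$n_squarings)
    bin <- function(v) (v >= 0.5) * 1L
    dsc0 <- dice_arrays(bin(M), bin(F))
    warped <- c_warp(M, fwd_vox, 0L)
    dsc1 <- dice_arrays(bin(warped), bin(F))
    improved <- dsc1 >= dsc0
    if (!improved) {   # contract: never degrade overlap
      fwd_vox[] <- 0; inv_vox[] <- 0; vel[] <- 0
      dsc1 <- dsc0
    }
    fwd_mm <- field_to_mm(fwd_vox, sp)
    inv_mm <- field_to_mm(inv_vox, sp)
  }
  structure(list(forward = fwd_mm, inverse = inv_mm,
                 vel = vel, box = box, dims = full_dims,
                 spacing = sp, affine = moving$affine,
                 n_squarings = config$n_squarings,
                 meta = list(iterations = iters, similarity = mse,
                             converged = converged, improved = improved,
                             dice_before = dsc0, dice_after = dsc1)),
            class = "diffeo_transform")
}

field_to_mm <- function(u, sp) {
  for (c in 1:3) u[, , , c] <- u[, , , c] * sp[c]
  u
}

crop_box4 <- function(u, box) u[box[[1]], box[[2]], box[[3]], , drop = FALSE]

dice_arrays <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# voxel-unit displacement field on the transform's crop box
disp_to_vox <- function(transform, which = c("forward", "inverse")) {
  which <- match.arg(which)
  u <- transform[[which]]
  for (c in 1:3) u[, , , c] <- u[, , , c] / transform$spacing[c]
  u
}

#' Per-voxel displacement field of a transform on the full grid
#'
#' @param transform a \code{diffeo_transform}.
#' @param which "forward" or "inverse".
#' @return 4D array (grid dims x 3) of displacements in mm (zero, i.e.
#'   identity, outside the registration bounding box).
#' @export
displacement_field <- function(transform, which = c("forward", "inverse")) {
  which <- match.arg(which)
  embed_field(transform[[which]], transform$box, transform$dims)
}

# warp a full-grid volume through the (cropped) field: outside the box the
# transform is the identity
warp_full <- function(transform, vol, which, interp) {
  u <- disp_to_vox(transform, which)
  out <- vol
  out[transform$box[[1]], transform$box[[2]], transform$box[[3]]] <-
    c_warp(crop_box(vol, transform$box), u, interp)
  out
}

#' Apply a diffeomorphic transform to a volume
#'
#' \code{direction = "forward"} resamples a moving-grid image onto the fixed
#' grid (as used when building the template); \code{direction = "inverse"}
#' brings a fixed-grid image (e.g. the parts template) back onto the moving
#' grid. Label maps use the nearest-label rule and therefore never acquire
#' values absent from the input; binary masks are linearly interpolated and
#' re-thresholded at 0.5.
#'
#' @param transform a \code{\link{register_diffeo}} result.
#' @param image \code{\link{mask3d}}, \code{\link{parts_labels}} or
#'   \code{\link{prob_template}} on the matching grid.
#' @param direction "forward" or "inverse".
#' @param interpolation "auto" (by type), "linear" or "nearest".
#' @return warped volume of the same class.
#' @export
apply_transform <- function(transform, image,
                            direction = c("forward", "inverse"),
                            interpolation = c("auto", "linear", "nearest")) {
  direction <- match.arg(direction)
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(transform, "diffeo_transform"))
  if (!identical(dim(vol_of(image)), transform$dims))
    stop("apply_transform: image grid does not match the transform grid")
  if (interpolation == "auto")
    interpolation <- if (inherits(image, "parts_labels")) "nearest" else "linear"
  v <- array(as.double(vol_of(image)), dim(vol_of(image)))
  w <- warp_full(transform, v, direction,
                 if (interpolation == "nearest") 1L else 0L)
  switch(class(image)[1],
         mask3d = mask3d((w >= 0.5) * 1L, image$spacing, image$affine),
         parts_labels = parts_labels(array(as.integer(w), dim(w)),
                                     image$spacing, image$affine),
         prob_template = prob_template(pmin(pmax(w, 0), 1),
                                       image$spacing, image$affine))
}

#' Round-trip displacement of forward-then-inverse
#'
#' Magnitude, in voxels, of the composed forward-then-inverse map's residual
#' displacement at each voxel of the registration box; the maximum over a
#' foreground mask is the invertibility diagnostic (should stay below
#' 1 voxel). Outside the box the transform is the identity and the residual
#' is exactly zero.
#'
#' @param transform a \code{diffeo_transform}.
#' @param mask optional \code{\link{mask3d}} restricting where the maximum
#'   is taken (default: the whole box).
#' @return list(max_voxels, field) where field is the per-voxel residual
#'   magnitude in voxels on the full grid.
#' @export
roundtrip_displacement <- function(transform, mask = NULL) {
  uf <- disp_to_vox(transform, "forward")
  ui <- disp_to_vox(transform, "inverse")
  w <- c_compose(ui, uf)   # x + uf(x) + ui(x + uf(x))
  mag <- sqrt(w[, , , 1]^2 + w[, , , 2]^2 + w[, , , 3]^2)
  full <- array(0, transform$dims)
  full[transform$box[[1]], transform$box[[2]], transform$box[[3]]] <- mag
  sel <- if (is.null(mask)) TRUE else mask$voxels == 1L
  list(max_voxels = max(full[sel]), field = full)
}

#' Jacobian determinants of the forward map
#'
#' @param transform a \code{diffeo_transform}.
#' @return 3D array (full grid) of determinants of d(x + u(x))/dx in voxel
#'   units (1 outside the registration box); positivity everywhere on the
#'   foreground means orientation is preserved.
#' @export
jacobian_determinant <- function(transform) {
  jd <- c_jacobian_det(disp_to_vox(transform, "forward"))
  full <- array(1, transform$dims)
  full[transform$box[[1]], transform$box[[2]], transform$box[[3]]] <- jd
  full
}
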