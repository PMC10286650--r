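# Fixtures built in code: simple analytic shapes and the plane-annotation
# harness used across tests.

# axis-aligned solid cylinder along x, radius in mm, grid centered on 0
make_cylinder <- function(dims = c(64L, 32L, 32L), spacing = c(2, 2, 2),
                          length_mm = 100, radius_mm = 10) {
  origin <- -(dims - 1) / 2 * spacing
  ii <- (seq_len(dims[1]) - 1) * spacing[1] + origin[1]
  jj <- (seq_len(dims[2]) - 1) * spacing[2] + origin[2]
  kk <- (seq_len(dims[3]) - 1) * spacing[3] + origin[3]
  vox <- array(0L, dims)
  r2 <- outer(jj^2, kk^2, `+`)
  disk <- r2 < radius_mm^2
  inx <- abs(ii) <= length_mm / 2
  for (i in which(inx)) vox[i, , ] <- disk * 1L
  aff <- diag(c(spacing, 1)); aff[1:3, 4] <- origin
  mask3d(vox, spacing, aff)
}

make_sphere <- function(dims = c(32L, 32L, 32L), spacing = c(2, 2, 2),
                        radius_mm = 12, center_mm = c(0, 0, 0)) {
  origin <- -(dims - 1) / 2 * spacing
  ii <- (seq_len(dims[1]) - 1) * spacing[1] + origin[1] - center_mm[1]
  jj <- (seq_len(dims[2]) - 1) * spacing[2] + origin[2] - center_mm[2]
  kk <- (seq_len(dims[3]) - 1) * spacing[3] + origin[3] - center_mm[3]
  d2 <- outer(outer(ii^2, jj^2, `+`), kk^2, `+`)
  aff <- diag(c(spacing, 1)); aff[1:3, 4] <- origin
  mask3d((d2 < radius_mm^2) * 1L, spacing, aff)
}

random_mask <- function(dims = c(16L, 16L, 16L), spacing = c(2, 2, 2),
                        p = 0.2) {
  vox <- array(as.integer(stats::runif(prod(dims)) < p), dims)
  mask3d(vox, spacing)
}

# annotate a template mask with planes orthogonal to its centerline
# (numeric stand-in for the manual annotation step)
annotate_from_centerline <- function(tmask, head_fraction = 0.40) {
  annotate_by_arclength(tmask, head_fraction)
}

# annotated parts template from a phantom cohort, cached so several test
# blocks can share one construction
.pt_cache <- new.env(parent = emptyenv())
cached_parts_template <- function(n = 5, seed = 101, n_iterations = 2) {
  key <- paste(n, seed, n_iterations, sep = "_")
  if (!exists(key, envir = .pt_cache)) {
    co <- generate_cohort(phantom_spec(), n, seed = seed)
    tb <- build_template(lapply(co, `[[`, "mask"),
                         n_iterations = n_iterations)
    assign(key, annotate_by_arclength(binarize(tb$template)),
           envir = .pt_cache)
  }
  get(key, envir = .pt_cache)
}

# brute-force O(n^2) oracle for the pooled 95th-percentile Hausdorff
# distance: boundary voxels by 6-connectivity, all-pairs world distances
hd95_oracle <- function(a, b, probs = 0.95) {
  bnd <- function(m) {
    vox <- m$voxels
    d <- dim(vox)
    idx <- which(vox == 1L, arr.ind = TRUE)
    on_b <- apply(idx, 1, function(v) {
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        w <- v; w[ax] <- w[ax] + dd
        if (any(w < 1L) || any(w > d)) return(TRUE)
        if (vox[w[1], w[2], w[3]] == 0L) return(TRUE)
      }
      FALSE
    })
    sweep(idx[on_b, , drop = FALSE] - 1, 2, m$spacing, `*`)
  }
  pa <- bnd(a); pb <- bnd(b)
  dmat <- as.matrix(stats::dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                               nrow(pa) + seq_len(nrow(pb)),
                                               drop = FALSE]
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  unname(stats::quantile(pooled, probs, type = 7))
}

# exact 1-D 3-means by dynamic programming over sorted points: returns the
# optimal cluster boundaries (as indices into the sorted vector)
kmeans3_1d_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {   # cost of cluster x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  best <- Inf; cut <- c(NA, NA)
  for (c1 in 1:(n - 2)) for (c2 in (c1 + 1):(n - 1)) {
    v <- sse(1, c1) + sse(c1 + 1, c2) + sse(c2 + 1, n)
    if (v < best) { best <- v; cut <- c(c1, c2) }
  }
  list(cost = best, boundaries = c(x[cut[1]], x[cut[2]]),
       next_after = c(x[cut[1] + 1], x[cut[2] + 1]))
}
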