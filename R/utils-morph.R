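# 3-D array primitives: shifts, separable Gaussian smoothing, binary
# morphology with a 6-connected structuring element, connected components.
# All operate on plain R arrays; masks are logical arrays.

# Shift a 3-D array by integer offsets (dx, dy, dz), filling with `fill`.
shift3d <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) {
    i <- seq_len(n) - s
    i[i >= 1L & i <= n]
  }
  xs <- src(d[1], dx); ys <- src(d[2], dy); zs <- src(d[3], dz)
  if (!length(xs) || !length(ys) || !length(zs)) return(out)
  out[xs + dx, ys + dy, zs + dz] <- a[xs, ys, zs]
  out
}

# Truncated discrete Gaussian kernel, unit mass.
gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one axis of a 3-D array with a symmetric kernel,
# zero-padded boundaries. Implemented as a banded matrix product.
conv_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a * kernel)
  d <- dim(a)
  n <- d[axis]
  h <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - h - 1L
    idx <- seq_len(n)
    keep <- idx + off >= 1L & idx + off <= n
    K[cbind(idx[keep], idx[keep] + off)] <- kernel[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = n)
  res <- array(m, dim(ap))
  aperm(res, order(perm))
}

# Separable Gaussian smoothing; `sigma` is per-axis in voxel units
# (recycled to length 3).
smooth3d <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    if (sigma[ax] > 0) a <- conv_axis(a, gauss_kernel1d(sigma[ax]), ax)
  }
  a
}

neighbour_offsets6 <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

dilate6 <- function(mask) {
  out <- mask
  for (i in seq_len(6)) {
    o <- neighbour_offsets6()[i, ]
    out <- out | shift3d(mask, o[1], o[2], o[3], fill = FALSE)
  }
  out
}

erode6 <- function(mask) {
  out <- mask
  for (i in seq_len(6)) {
    o <- neighbour_offsets6()[i, ]
    out <- out & shift3d(mask, o[1], o[2], o[3], fill = TRUE)
  }
  # voxels on the array border lose their outside neighbours; treat outside
  # as background so border voxels erode
  d <- dim(mask)
  out[c(1, d[1]), , ] <- FALSE
  out[, c(1, d[2]), ] <- FALSE
  out[, , c(1, d[3])] <- FALSE
  out & mask
}

# In-mask voxels with at least one 6-neighbour outside the mask (or on the
# array border): the digital boundary of the mask.
boundary_voxels <- function(mask) mask & !erode6(mask)

# Label 6-connected components by repeated geodesic dilation from seeds.
# Returns an integer array (0 = background). Fine for the phantom-scale
# arrays this package works at.
connected_components6 <- function(mask) {
  lab <- array(0L, dim(mask))
  remaining <- mask
  nextlab <- 0L
  while (any(remaining)) {
    nextlab <- nextlab + 1L
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1L]] <- TRUE
    repeat {
      grown <- dilate6(seed) & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    lab[seed] <- nextlab
    remaining <- remaining & !seed
  }
  lab
}

largest_component6 <- function(mask) {
  if (!any(mask)) return(mask)
  bb <- mask_bbox(mask, margin = 0L)
  lab <- connected_components6(crop_to_bbox(mask, bb))
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  out <- array(FALSE, dim(mask))
  out[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <-
    lab == which.max(sizes)
  out
}

is_single_component6 <- function(mask) {
  if (!any(mask)) return(FALSE)
  bb <- mask_bbox(mask, margin = 0L)
  max(connected_components6(crop_to_bbox(mask, bb))) == 1L
}

# Bounding box of a mask with an optional margin, clipped to the array.
mask_bbox <- function(mask, margin = 0L) {
  stopifnot(any(mask))
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - margin, 1L)
  hi <- pmin(apply(w, 2, max) + margin, d)
  list(lo = lo, hi = hi)
}

crop_to_bbox <- function(a, bbox) {
  a[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2], bbox$lo[3]:bbox$hi[3],
    drop = FALSE]
}
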