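# First-order (histogram), gradient and moment features.

#' Histogram features (15 values)
#'
#' Mean, SD, Min, Max and percentiles are computed in HU on the raw in-mask
#' intensities; percentiles use linear interpolation between order
#' statistics. Skewness is the third standardized central moment and excess
#' kurtosis the fourth minus 3 (population moments). Energy and entropy are
#' computed on the G-level discretized histogram, making them independent of
#' the HU scale: Energy = sum(p^2), Entropy = -sum(p log2 p). A constant VOI
#' returns skewness/kurtosis 0 with the degenerate flag set.
#'
#' @param voi A [volume_with_mask()] object with at least 2 mask voxels.
#' @param dvoi Optional precomputed [discretize()] result.
#' @param G Gray levels for the discretized histogram when `dvoi` is `NULL`.
#' @return Named numeric vector of 15 features, with a logical
#'   `"degenerate"` attribute.
#' @export
histogram_features <- function(voi, dvoi = NULL, G = 32L) {
  stopifnot(inherits(voi, "volume_with_mask"))
  x <- voi$intensities[voi$mask]
  n <- length(x)
  if (n < 2L) stop("histogram features need at least 2 mask voxels")
  if (is.null(dvoi)) dvoi <- discretize(voi, G)
  m <- mean(x)
  s <- stats::sd(x)
  degenerate <- s == 0
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else {
    m2 <- mean((x - m)^2)
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3
  }
  p <- tabulate(dvoi$levels[voi$mask], nbins = dvoi$G) / n
  p_pos <- p[p > 0]
  q <- stats::quantile(x, c(.10, .25, .50, .75, .90, .95), names = FALSE,
                       type = 7)
  out <- c(m, s, skew, kurt, sum(p_pos^2), -sum(p_pos * log2(p_pos)),
           min(x), max(x), n, q)
  names(out) <- radiomic_feature_names("histogram")
  attr(out, "degenerate") <- degenerate
  out
}

#' Gradient features (2 values)
#'
#' Mean and SD of the 3-D gradient magnitude over in-mask voxels, in HU/mm.
#' Gradients are central differences scaled by the voxel spacing (one-sided
#' at the array border). Note that in-mask voxels adjacent to the mask
#' boundary see the background intensity through the difference stencil,
#' exactly as a gradient computed on the full CT volume would.
#'
#' @param voi A [volume_with_mask()] object whose mask spans at least 2
#'   voxels along every axis.
#' @return Named numeric vector `Texture_Grad_Mean`, `Texture_Grad_SD`.
#' @export
gradient_features <- function(voi) {
  stopifnot(inherits(voi, "volume_with_mask"))
  ext <- apply(which(voi$mask, arr.ind = TRUE), 2, function(i) diff(range(i))) + 1L
  if (any(ext < 2L)) stop("mask must span at least 2 voxels along every axis")
  g2 <- array(0, dim(voi$intensities))
  for (ax in 1:3) {
    g2 <- g2 + (diff_axis(voi$intensities, ax) / voi$spacing_mm[ax])^2
  }
  gm <- sqrt(g2)[voi$mask]
  out <- c(mean(gm), stats::sd(gm))
  names(out) <- radiomic_feature_names("gradient")
  out
}

# Central difference along one axis ((f[i+1]-f[i-1])/2), one-sided at the
# two array faces.
diff_axis <- function(a, axis) {
  fwd <- shift3d(a, -(axis == 1), -(axis == 2), -(axis == 3))
  bwd <- shift3d(a, (axis == 1), (axis == 2), (axis == 3))
  d <- (fwd - bwd) / 2
  n <- dim(a)[axis]
  slice_assign <- function(target, i, value) {
    if (axis == 1) target[i, , ] <- value
    else if (axis == 2) target[, i, ] <- value
    else target[, , i] <- value
    target
  }
  slice_get <- function(x, i) {
    if (axis == 1) x[i, , , drop = FALSE]
    else if (axis == 2) x[, i, , drop = FALSE]
    else x[, , i, drop = FALSE]
  }
  d <- slice_assign(d, 1L, slice_get(a, 2L) - slice_get(a, 1L))
  d <- slice_assign(d, n, slice_get(a, n) - slice_get(a, n - 1L))
  d
}

#' Moment features J1, J2, J3 (3 values)
#'
#' The three rotation invariants of the intensity-weighted, volume-normalized
#' central second-moment matrix of the VOI in physical (mm) coordinates:
#' J1 = trace, J2 = sum of the three principal 2x2 minors, J3 = determinant.
#' Weights are the in-mask intensities; if their total is not positive the
#' intensities are min-shifted to be non-negative (uniform weights if still
#' degenerate) and the result is flagged.
#'
#' @param voi A [volume_with_mask()] object.
#' @return Named numeric vector `Texture_Moment_J1/J2/J3` with a
#'   `"shifted_weights"` attribute.
#' @export
moment_features <- function(voi) {
  stopifnot(inherits(voi, "volume_with_mask"))
  idx <- which(voi$mask, arr.ind = TRUE)
  xyz <- sweep(idx, 2, voi$spacing_mm, `*`)
  w <- voi$intensities[voi$mask]
  shifted <- FALSE
  if (sum(w) <= 0) {
    shifted <- TRUE
    w <- w - min(w)
    if (sum(w) <= 0) w <- rep(1, length(w))
  }
  w <- w / sum(w)
  ctr <- colSums(xyz * w)
  cc <- sweep(xyz, 2, ctr)
  M <- crossprod(cc * w, cc)  # sum_i w_i (r_i - rbar)(r_i - rbar)^T
  j1 <- sum(diag(M))
  j2 <- M[1, 1] * M[2, 2] - M[1, 2]^2 +
        M[1, 1] * M[3, 3] - M[1, 3]^2 +
        M[2, 2] * M[3, 3] - M[2, 3]^2
  j3 <- det(M)
  out <- c(j1, j2, j3)
  names(out) <- radiomic_feature_names("moment")
  attr(out, "shifted_weights") <- shifted
  out
}
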