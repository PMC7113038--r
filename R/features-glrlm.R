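# Gray-level run-length matrix (GLRLM) texture features.

#' Gray-level run-length matrix for one direction
#'
#' Scans every lattice line parallel to the integer direction `offset` and
#' counts maximal runs of consecutive in-mask voxels sharing the same gray
#' level. Out-of-mask voxels break runs.
#'
#' @param dvoi A [discretize()] result.
#' @param offset Integer direction vector of length 3 (components in
#'   -1/0/1, not all zero).
#' @return Matrix `r(i, j)` of run counts: rows = gray level `1..G`,
#'   columns = run length `1..Jmax`.
#' @export
glrlm_matrix <- function(dvoi, offset, coords = NULL) {
  stopifnot(inherits(dvoi, "discretized_voi"))
  offset <- as.integer(offset)
  if (length(offset) != 3L || all(offset == 0L))
    stop("'offset' must be a non-zero integer 3-vector")
  lev <- dvoi$levels
  d <- dim(lev)
  if (is.null(coords)) coords <- arrayInd(seq_along(lev), d)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  # position along the line (strictly increasing by |offset|^2 per step)
  t <- x * offset[1] + y * offset[2] + z * offset[3]
  # three pairwise cross-products are invariant along a line of direction
  # `offset`; encoded together they key the line a voxel belongs to
  k1 <- x * offset[2] - y * offset[1]
  k2 <- x * offset[3] - z * offset[1]
  k3 <- y * offset[3] - z * offset[2]
  B <- 2L * max(d) + 1L
  line <- (k1 + B) + (k2 + B) * (2 * B) + (k3 + B) * (4 * B * B)
  ord <- order(line, t)
  v <- as.vector(lev)[ord]
  g <- line[ord]
  n <- length(v)
  same <- c(FALSE, g[-1] == g[-n] & !is.na(v[-1]) & !is.na(v[-n]) &
                    v[-1] == v[-n])
  run_id <- cumsum(!same)
  starts <- which(!same)
  run_val <- v[starts]
  run_len <- tabulate(run_id)
  keep <- !is.na(run_val)
  run_val <- run_val[keep]
  run_len <- run_len[keep]
  if (!length(run_val)) return(matrix(0, dvoi$G, 1))
  jmax <- max(run_len)
  R <- matrix(0, dvoi$G, jmax)
  counts <- tabulate((run_len - 1L) * dvoi$G + run_val, nbins = dvoi$G * jmax)
  R[] <- counts
  R
}

# The 13 spec'd features of a single run-length matrix.
glrlm_features_one <- function(R, n_voxels) {
  i <- row(R); j <- col(R)
  Nr <- sum(R)
  if (Nr == 0) return(rep(0, 13))
  sre <- sum(R / j^2) / Nr
  lre <- sum(R * j^2) / Nr
  lgre <- sum(R / i^2) / Nr
  hgre <- sum(R * i^2) / Nr
  srlge <- sum(R / (i^2 * j^2)) / Nr
  srhge <- sum(R * i^2 / j^2) / Nr
  lrlge <- sum(R * j^2 / i^2) / Nr
  lrhge <- sum(R * i^2 * j^2) / Nr
  gnun <- sum(rowSums(R)^2) / Nr^2
  rlnun <- sum(colSums(R)^2) / Nr^2
  rp <- Nr / n_voxels
  pj <- colSums(R) / Nr
  muj <- sum(seq_along(pj) * pj)
  rv <- sum((seq_along(pj) - muj)^2 * pj)
  q <- R[R > 0] / Nr
  re <- -sum(q * log2(q))
  c(sre, lre, lgre, hgre, srlge, srhge, lrlge, lrhge, gnun, rlnun, rp, rv, re)
}

#' GLRLM features (13 values)
#'
#' Run-length matrices are computed independently for each of the 13 unique
#' 3-D directions and the 13 features are averaged over directions. With
#' `r(i, j)` the count of runs at gray level `i` and length `j`, `N_r` the
#' total number of runs in a direction and `N_p` the number of in-mask
#' voxels: SRE = sum(r/j^2)/N_r, LRE = sum(r j^2)/N_r, LGRE = sum(r/i^2)/N_r,
#' HGRE = sum(r i^2)/N_r, plus the four joint emphases SRLGE/SRHGE/LRLGE/
#' LRHGE; GNUN = sum_i (sum_j r)^2 / N_r^2 and RLNUN = sum_j (sum_i r)^2 /
#' N_r^2 (normalized nonuniformities); RP = N_r / N_p; RV = variance of run
#' length under the run distribution; RE = -sum (r/N_r) log2(r/N_r).
#'
#' @param dvoi A [discretize()] result.
#' @return Named numeric vector of 13 features with a `"degenerate"`
#'   attribute.
#' @export
glrlm_features <- function(dvoi) {
  n_voxels <- sum(!is.na(dvoi$levels))
  # restrict to the mask bounding box: runs cannot cross NA voxels, so
  # cropping changes nothing but the amount of work
  mask <- !is.na(dvoi$levels)
  bb <- mask_bbox(mask, margin = 0L)
  dcrop <- dvoi
  dcrop$levels <- crop_to_bbox(dvoi$levels, bb)
  coords <- arrayInd(seq_along(dcrop$levels), dim(dcrop$levels))
  offs <- texture_offsets3d()
  acc <- matrix(0, nrow(offs), 13)
  for (r in seq_len(nrow(offs))) {
    R <- glrlm_matrix(dcrop, offs[r, ], coords = coords)
    acc[r, ] <- glrlm_features_one(R, n_voxels)
  }
  out <- colMeans(acc)
  names(out) <- radiomic_feature_names("glrlm")
  attr(out, "degenerate") <- dvoi$degenerate
  out
}
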