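# Gray-level co-occurrence matrix (GLCM) texture features.

#' The 13 unique distance-1 direction offsets in 3-D
#'
#' Half of the 26-neighbourhood: one representative per +/- direction pair.
#' Symmetrized accumulation over these offsets makes the pooled GLCM closed
#' under the full octahedral (90-degree rotation and reflection) group.
#'
#' @return Integer matrix 13 x 3.
#' @export
texture_offsets3d <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0),
        c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

#' Pooled, symmetrized GLCM of a discretized VOI
#'
#' Co-occurrence counts of in-mask voxel pairs at each distance-1 offset,
#' symmetrized (both pair orders) and pooled over all 13 unique directions,
#' then normalized to a joint probability matrix `p(i, j)`.
#'
#' @param dvoi A [discretize()] result.
#' @return A `G x G` matrix summing to 1 (all zeros if the VOI has no valid
#'   neighbouring pair).
#' @export
glcm_matrix <- function(dvoi) {
  stopifnot(inherits(dvoi, "discretized_voi"))
  lev <- dvoi$levels
  G <- dvoi$G
  d <- dim(lev)
  counts <- numeric(G * G)
  offs <- texture_offsets3d()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    rng <- function(n, s) if (1 + max(0, s) > n + min(0, s)) integer(0)
                          else seq(1 + max(0, s), n + min(0, s))
    xs <- rng(d[1], o[1]); ys <- rng(d[2], o[2]); zs <- rng(d[3], o[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    a <- lev[xs, ys, zs, drop = FALSE]
    b <- lev[xs - o[1], ys - o[2], zs - o[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ia <- a[ok]; ib <- b[ok]
    counts <- counts + tabulate((ia - 1L) * G + ib, nbins = G * G) +
                       tabulate((ib - 1L) * G + ia, nbins = G * G)
  }
  P <- matrix(counts, G, G)
  tot <- sum(P)
  if (tot > 0) P <- P / tot
  P
}

#' GLCM features (13 values)
#'
#' Computed from the direction-pooled symmetric GLCM `p(i, j)`:
#' ASM = sum p^2; IDM = sum p / (1 + (i-j)^2); Homogeneity =
#' sum p / (1 + |i-j|); Contrast = sum (i-j)^2 p; Correlation =
#' sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j) (0 with a flag when a
#' marginal variance vanishes); Autocor = sum i j p; Entropy =
#' -sum p log2 p; cluster prominence/shade/tendency CP/CS/CT =
#' sum (i + j - mu_i - mu_j)^k p for k = 4, 3, 2; SumEntropy on the
#' diagonal-sum distribution p_{x+y}; DiffAverage and DiffEntropy on the
#' absolute-difference distribution p_{|x-y|}.
#'
#' A degenerate (single-level) VOI returns the constant-texture values
#' (ASM = 1, Contrast = 0, Entropy = 0, ...) with the `"degenerate"`
#' attribute set.
#'
#' @param dvoi A [discretize()] result.
#' @return Named numeric vector of 13 features.
#' @export
glcm_features <- function(dvoi) {
  P <- glcm_matrix(dvoi)
  G <- dvoi$G
  i <- row(P); j <- col(P)
  pi_ <- rowSums(P)
  mu_i <- sum(seq_len(G) * pi_)
  sd_i <- sqrt(sum((seq_len(G) - mu_i)^2 * pi_))
  # symmetric matrix: both marginals coincide
  degenerate_corr <- sd_i == 0
  pos <- P > 0
  asm <- sum(P^2)
  idm <- sum(P / (1 + (i - j)^2))
  homog <- sum(P / (1 + abs(i - j)))
  contrast <- sum((i - j)^2 * P)
  corr <- if (degenerate_corr) 0 else
    sum((i - mu_i) * (j - mu_i) * P) / (sd_i * sd_i)
  autocor <- sum(i * j * P)
  entropy <- -sum(P[pos] * log2(P[pos]))
  dev <- i + j - 2 * mu_i
  cp <- sum(dev^4 * P)
  cs <- sum(dev^3 * P)
  ct <- sum(dev^2 * P)
  # p_{x+y}(k), k = 2..2G
  psum <- tapply(as.vector(P), as.vector(i + j), sum)
  psum <- psum[psum > 0]
  sum_entropy <- -sum(psum * log2(psum))
  # p_{|x-y|}(k), k = 0..G-1
  pdiff <- tapply(as.vector(P), as.vector(abs(i - j)), sum)
  dvals <- as.numeric(names(pdiff))
  diff_avg <- sum(dvals * pdiff)
  pdiff_pos <- pdiff[pdiff > 0]
  diff_entropy <- -sum(pdiff_pos * log2(pdiff_pos))
  out <- c(asm, idm, homog, contrast, corr, autocor, entropy, cp, cs, ct,
           sum_entropy, diff_avg, diff_entropy)
  names(out) <- radiomic_feature_names("glcm")
  attr(out, "degenerate") <- dvoi$degenerate || degenerate_corr
  out
}
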