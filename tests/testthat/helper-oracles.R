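# Independent brute-force oracles and small fixture builders shared by the
# tests. Everything here is deliberately naive (plain loops, direct
# formulas) and independent of the package's vectorized implementations.

make_voi <- function(vals, dims = c(length(vals), 1L, 1L),
                     mask = NULL, spacing = c(1, 1, 1)) {
  a <- array(vals, dims)
  if (is.null(mask)) mask <- array(TRUE, dims)
  volume_with_mask(a, mask, spacing)
}

random_voi <- function(dims, seed, mask_prob = 1, lo = 0, hi = 100) {
  set.seed(seed)
  a <- array(runif(prod(dims), lo, hi), dims)
  m <- array(runif(prod(dims)) < mask_prob, dims)
  if (sum(m) < 2) m[seq_len(2)] <- TRUE
  volume_with_mask(a, m, c(1, 1, 1))
}

digital_ball <- function(r_vox, pad = 3L, value = 1) {
  n <- 2L * (r_vox + pad) + 1L
  ctr <- (n + 1) / 2
  idx <- arrayInd(seq_len(n^3), c(n, n, n))
  m <- array(rowSums(sweep(idx, 2, ctr)^2) <= r_vox^2, c(n, n, n))
  volume_with_mask(array(value, c(n, n, n)), m, c(1, 1, 1))
}

# 90-degree grid rotations
rot_z <- function(a) { b <- aperm(a, c(2, 1, 3)); b[rev(seq_len(dim(b)[1])), , , drop = FALSE] }
rot_x <- function(a) { b <- aperm(a, c(1, 3, 2)); b[, rev(seq_len(dim(b)[2])), , drop = FALSE] }
rot_y <- function(a) { b <- aperm(a, c(3, 2, 1)); b[, , rev(seq_len(dim(b)[3])), drop = FALSE] }

rotate_voi <- function(voi, rot) {
  volume_with_mask(rot(voi$intensities), rot(voi$mask), voi$spacing_mm)
}

# ---- GLCM oracle: explicit loop over voxels and offsets -------------------

oracle_glcm_matrix <- function(dvoi) {
  lev <- dvoi$levels
  G <- dvoi$G
  d <- dim(lev)
  P <- matrix(0, G, G)
  offs <- texture_offsets3d()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (is.na(lev[x, y, z])) next
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
        next
      if (is.na(lev[x2, y2, z2])) next
      i <- lev[x, y, z]; j <- lev[x2, y2, z2]
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  }
  if (sum(P) > 0) P <- P / sum(P)
  P
}

oracle_glcm_features <- function(dvoi) {
  P <- oracle_glcm_matrix(dvoi)
  G <- nrow(P)
  asm <- 0; idm <- 0; hom <- 0; con <- 0; autoc <- 0; ent <- 0
  cp <- 0; cs <- 0; ct <- 0
  mu <- 0
  for (i in 1:G) for (j in 1:G) mu <- mu + i * P[i, j]
  sg2 <- 0
  for (i in 1:G) for (j in 1:G) sg2 <- sg2 + (i - mu)^2 * P[i, j]
  corr_num <- 0
  psum <- numeric(2 * G); pdiff <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    asm <- asm + p^2
    idm <- idm + p / (1 + (i - j)^2)
    hom <- hom + p / (1 + abs(i - j))
    con <- con + (i - j)^2 * p
    autoc <- autoc + i * j * p
    if (p > 0) ent <- ent - p * log2(p)
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    corr_num <- corr_num + (i - mu) * (j - mu) * p
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  corr <- if (sg2 > 0) corr_num / sg2 else 0
  se <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  da <- sum((seq_along(pdiff) - 1) * pdiff)
  de <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))
  out <- c(asm, idm, hom, con, corr, autoc, ent, cp, cs, ct, se, da, de)
  names(out) <- radiomic_feature_names("glcm")
  out
}

# ---- GLRLM oracle: walk every lattice line voxel by voxel -----------------

oracle_glrlm_matrix <- function(dvoi, offset) {
  lev <- dvoi$levels
  d <- dim(lev)
  inside <- function(p) all(p >= 1) && all(p <= d)
  runs_i <- integer(0); runs_j <- integer(0)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    if (inside(p - offset)) next        # not a line start
    # walk the whole line, collecting runs
    cur_val <- NA_integer_; cur_len <- 0L
    q <- p
    while (inside(q)) {
      v <- lev[q[1], q[2], q[3]]
      if (!is.na(v) && !is.na(cur_val) && v == cur_val) {
        cur_len <- cur_len + 1L
      } else {
        if (!is.na(cur_val)) { runs_i <- c(runs_i, cur_val); runs_j <- c(runs_j, cur_len) }
        cur_val <- v; cur_len <- 1L
      }
      q <- q + offset
    }
    if (!is.na(cur_val)) { runs_i <- c(runs_i, cur_val); runs_j <- c(runs_j, cur_len) }
  }
  if (!length(runs_i)) return(matrix(0, dvoi$G, 1))
  R <- matrix(0, dvoi$G, max(runs_j))
  for (k in seq_along(runs_i)) R[runs_i[k], runs_j[k]] <- R[runs_i[k], runs_j[k]] + 1
  R
}

oracle_glrlm_features_one <- function(R, n_voxels) {
  Nr <- sum(R)
  if (Nr == 0) return(rep(0, 13))
  G <- nrow(R); J <- ncol(R)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  re <- 0
  for (i in 1:G) for (j in 1:J) {
    r <- R[i, j]
    if (r == 0) next
    sre <- sre + r / j^2; lre <- lre + r * j^2
    lgre <- lgre + r / i^2; hgre <- hgre + r * i^2
    srlge <- srlge + r / (i^2 * j^2); srhge <- srhge + r * i^2 / j^2
    lrlge <- lrlge + r * j^2 / i^2; lrhge <- lrhge + r * i^2 * j^2
    re <- re - (r / Nr) * log2(r / Nr)
  }
  gn <- sum(rowSums(R)^2) / Nr^2
  rln <- sum(colSums(R)^2) / Nr^2
  pj <- colSums(R) / Nr
  muj <- sum(seq_len(J) * pj)
  rv <- sum((seq_len(J) - muj)^2 * pj)
  c(sre / Nr, lre / Nr, lgre / Nr, hgre / Nr, srlge / Nr, srhge / Nr,
    lrlge / Nr, lrhge / Nr, gn, rln, Nr / n_voxels, rv, re)
}

oracle_glrlm_features <- function(dvoi) {
  n_voxels <- sum(!is.na(dvoi$levels))
  offs <- texture_offsets3d()
  acc <- matrix(0, nrow(offs), 13)
  for (r in seq_len(nrow(offs)))
    acc[r, ] <- oracle_glrlm_features_one(oracle_glrlm_matrix(dvoi, offs[r, ]),
                                          n_voxels)
  out <- colMeans(acc)
  names(out) <- radiomic_feature_names("glrlm")
  out
}

# ---- Youden oracle: exhaustive direct counting ----------------------------

oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- (s[-1] + s[-length(s)]) / 2
  best <- NULL
  for (cc in cand) {
    sens <- mean(scores[labels == 1] > cc)
    spec <- mean(scores[labels == 0] <= cc)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden ||
        (j == best$youden && cc > best$cutoff))
      best <- list(cutoff = cc, sensitivity = sens, specificity = spec,
                   youden = j)
  }
  best
}

# ---- permutation oracle for the paired AUC comparison ---------------------

oracle_delong_permutation <- function(scores1, scores2, labels, B = 5000,
                                      seed = 1) {
  obs <- abs(auc_concordance(scores2, labels) -
             auc_concordance(scores1, labels))
  set.seed(seed)
  n <- length(labels)
  hits <- 0L
  for (b in seq_len(B)) {
    swap <- runif(n) < 0.5
    s1 <- ifelse(swap, scores2, scores1)
    s2 <- ifelse(swap, scores1, scores2)
    d <- abs(auc_concordance(s2, labels) - auc_concordance(s1, labels))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  hits / B
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

tiny_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(26L, 26L, 26L), radii_mm = c(8, 7, 6.5), ...)
}
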