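# Gray-level discretization of the VOI, the prerequisite for GLCM/GLRLM.

#' Discretize in-mask intensities into G gray levels
#'
#' Equal-width binning over the in-mask intensity range `[min, max]`: bin i
#' covers `[min + (i-1)w, min + iw)` with `w = (max - min)/G`, and the
#' maximum value is assigned level `G` (the last bin is closed). A VOI with
#' constant in-mask intensity yields a single-level result flagged as
#' degenerate.
#'
#' @param voi A [volume_with_mask()] object.
#' @param G Number of gray levels (>= 2). Default 32.
#' @return An object of class `discretized_voi`: list with `levels` (integer
#'   array, `NA` outside the mask), `G`, `bin_edges` (length `G + 1`, HU) and
#'   `degenerate` flag.
#' @export
discretize <- function(voi, G = 32L) {
  stopifnot(inherits(voi, "volume_with_mask"))
  G <- as.integer(G)
  if (G < 2L) stop("'G' must be at least 2")
  if (sum(voi$mask) < 2L) stop("mask must contain at least 2 voxels")
  vals <- voi$intensities[voi$mask]
  lo <- min(vals); hi <- max(vals)
  lev <- array(NA_integer_, dim(voi$mask))
  if (hi <= lo) {
    lev[voi$mask] <- 1L
    return(structure(list(levels = lev, G = G,
                          bin_edges = rep(lo, G + 1L), degenerate = TRUE),
                     class = "discretized_voi"))
  }
  w <- (hi - lo) / G
  l <- pmin(floor((vals - lo) / w) + 1, G)
  lev[voi$mask] <- as.integer(l)
  structure(list(levels = lev, G = G,
                 bin_edges = seq(lo, hi, length.out = G + 1L),
                 degenerate = FALSE),
            class = "discretized_voi")
}
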