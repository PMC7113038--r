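# Front-end: compute the full 58-feature vector for one VOI or a cohort.

#' Extract all 58 radiomic features from a VOI
#'
#' Computes the full catalogue (15 histogram, 2 gradient, 13 GLCM, 13 GLRLM,
#' 3 moment, 11 shape, 1 fractal) in canonical order. Before feature
#' computation the volume is cropped to the mask bounding box plus a fixed
#' margin, which makes every feature exactly invariant to translating the
#' VOI within the grid.
#'
#' @param voi A [volume_with_mask()] object.
#' @param G Gray-level count used for texture discretization (default 32).
#' @param crop_margin Margin (voxels) retained around the mask bounding box.
#' @return Named numeric vector of length 58 with attributes `"flags"`
#'   (character vector of degeneracy flags raised by sub-computations) and
#'   `"G"`.
#' @export
extract_features <- function(voi, G = 32L, crop_margin = 4L) {
  stopifnot(inherits(voi, "volume_with_mask"))
  bb <- mask_bbox(voi$mask, margin = crop_margin)
  voi <- volume_with_mask(crop_to_bbox(voi$intensities, bb),
                          crop_to_bbox(voi$mask, bb), voi$spacing_mm)
  flags <- character(0)
  dvoi <- discretize(voi, G)
  if (dvoi$degenerate) flags <- c(flags, "degenerate_texture")
  histo <- with_feature_context(histogram_features(voi, dvoi), "histogram")
  grad <- with_feature_context(gradient_features(voi), "gradient")
  glcm <- with_feature_context(glcm_features(dvoi), "glcm")
  glrlm <- with_feature_context(glrlm_features(dvoi), "glrlm")
  mom <- with_feature_context(moment_features(voi), "moment")
  if (isTRUE(attr(mom, "shifted_weights"))) flags <- c(flags, "shifted_moment_weights")
  shp <- with_feature_context(shape_features(voi), "shape")
  if (isTRUE(attr(shp, "thin_mask"))) flags <- c(flags, "thin_mask")
  fractal <- with_feature_context(fractal_dimension(voi), "fractal")
  out <- c(histo, grad, glcm, glrlm, mom, shp,
           Fractal_Dimension = unname(fractal))
  stopifnot(identical(names(out), radiomic_feature_names()))
  attributes(out) <- list(names = names(out), flags = flags, G = G)
  out
}

# Re-raise sub-operation errors with the feature category in the message.
with_feature_context <- function(expr, category) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("feature extraction failed in %s features: %s",
                 category, conditionMessage(e)), call. = FALSE)
  })
}

#' Extract features for a list of VOIs into a feature table
#'
#' @param vois Named or unnamed list of [volume_with_mask()] objects.
#' @param subject_ids Optional subject identifiers (defaults to list names
#'   or a running index).
#' @param G Gray-level count passed to [extract_features()].
#' @return Data frame with `subject_id` and 58 feature columns in canonical
#'   order.
#' @export
extract_cohort_features <- function(vois, subject_ids = NULL, G = 32L) {
  stopifnot(is.list(vois), length(vois) > 0L)
  if (is.null(subject_ids))
    subject_ids <- names(vois) %||% as.character(seq_along(vois))
  mat <- t(vapply(vois, function(v) as.numeric(extract_features(v, G = G)),
                  numeric(58L)))
  colnames(mat) <- radiomic_feature_names()
  cbind(data.frame(subject_id = subject_ids, stringsAsFactors = FALSE),
        as.data.frame(mat))
}
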