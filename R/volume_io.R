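# Volume + mask container and standard-format I/O (NIfTI, CSV, JSON).

#' Create a volume-with-mask object
#'
#' The basic container of the pipeline: a 3-D scalar intensity field in
#' Hounsfield units, its voxel spacing in millimetres, and a co-registered
#' binary tumor mask (the volume of interest, VOI) on the same grid.
#'
#' @param intensities 3-D numeric array of CT intensities (HU).
#' @param mask 3-D logical (or 0/1) array of the same dimensions; must
#'   contain at least one voxel.
#' @param spacing_mm Numeric vector of length 3, strictly positive voxel
#'   size per axis in mm.
#' @return An object of class `volume_with_mask` (a list with elements
#'   `intensities`, `mask`, `spacing_mm`).
#' @export
volume_with_mask <- function(intensities, mask, spacing_mm) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3-D array")
  if (length(dim(mask)) != 3L || !identical(dim(mask), dim(intensities)))
    stop("geometry error: 'mask' and 'intensities' must have identical dimensions")
  mask <- array(as.logical(mask > 0.5), dim(intensities))
  if (!any(mask)) stop("validation error: mask is empty")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 strictly positive numbers")
  structure(list(intensities = intensities, mask = mask,
                 spacing_mm = spacing_mm),
            class = "volume_with_mask")
}

#' @export
print.volume_with_mask <- function(x, ...) {
  d <- dim(x$intensities)
  cat("<volume_with_mask>\n")
  cat(sprintf("  grid: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x ")))
  r <- range(x$intensities[x$mask])
  cat(sprintf("  mask: %d voxels (%.1f mm^3), in-mask HU range [%.1f, %.1f]\n",
              sum(x$mask), sum(x$mask) * prod(x$spacing_mm), r[1], r[2]))
  invisible(x)
}

#' Write a volume and its mask as NIfTI files
#'
#' @param voi A [volume_with_mask()] object.
#' @param image_path,mask_path Output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_volume_pair <- function(voi, image_path, mask_path) {
  stopifnot(inherits(voi, "volume_with_mask"))
  img <- RNifti::asNifti(voi$intensities)
  RNifti::pixdim(img) <- voi$spacing_mm
  RNifti::writeNifti(img, image_path)
  msk <- RNifti::asNifti(array(as.integer(voi$mask), dim(voi$mask)))
  RNifti::pixdim(msk) <- voi$spacing_mm
  RNifti::writeNifti(msk, mask_path, datatype = "uint8")
  invisible(c(image = image_path, mask = mask_path))
}

#' Read a co-registered volume/mask pair from NIfTI files
#'
#' Validates the geometry: the two images must have identical dimensions and
#' voxel spacings agreeing to 1e-3 mm. The mask is binarized by `> 0.5`.
#'
#' @param image_path Path to the intensity NIfTI (HU).
#' @param mask_path Path to the binary mask NIfTI on the same grid.
#' @return A [volume_with_mask()] object.
#' @export
read_volume_pair <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(msk)))
    stop("geometry error: image and mask dimensions differ")
  sp_i <- RNifti::pixdim(img)[1:3]
  sp_m <- RNifti::pixdim(msk)[1:3]
  if (any(abs(sp_i - sp_m) > 1e-3))
    stop("geometry error: image and mask voxel spacings differ by more than 1e-3 mm")
  u <- unique(round(as.numeric(msk), 6))
  if (length(setdiff(u, c(0, 1))) > 0 && any(as.numeric(msk) > 1.5))
    stop("validation error: mask is not binary (multi-label masks are rejected)")
  volume_with_mask(array(as.numeric(img), dim(img)),
                   array(as.numeric(msk) > 0.5, dim(msk)),
                   sp_i)
}

cohort_required_columns <- function() {
  c("subject_id", "label", "age", "sex", "smoking", "egfr")
}

#' Read a cohort table from CSV
#'
#' Expects at least the columns `subject_id`, `label` (0/1 PD-L1 status by
#' TPS >= 50%), `age` (years), `sex` (`"male"`/`"female"`), `smoking`
#' (`"current"`/`"past"`/`"never"`) and `egfr` (0/1 mutation present). Any
#' radiomic feature columns are preserved. Missing values are flagged in the
#' `"missing_cells"` attribute.
#'
#' @param path CSV path (header row, RFC-4180).
#' @return A data frame of class `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(x)
}

#' Validate (and classify) a cohort data frame
#'
#' @param x Data frame with the required cohort columns.
#' @return `x` with class `cohort_table` and a `missing_cells` attribute.
#' @export
validate_cohort_table <- function(x) {
  req <- cohort_required_columns()
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("cohort table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  if (!all(x$label %in% c(0, 1)))
    stop("validation error: 'label' must be 0/1 (PD-L1 negative/positive)")
  x$label <- as.integer(x$label)
  bad_sex <- !x$sex %in% c("male", "female")
  if (any(bad_sex)) stop("validation error: 'sex' must be 'male' or 'female'")
  if (!all(x$smoking %in% c("current", "past", "never")))
    stop("validation error: 'smoking' must be current/past/never")
  if (!all(x$egfr %in% c(0, 1)))
    stop("validation error: 'egfr' must be 0/1")
  miss <- which(is.na(as.matrix(x)), arr.ind = TRUE)
  attr(x, "missing_cells") <- miss
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Write a cohort table to CSV
#'
#' @param x Cohort data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a radiomic feature table to CSV in catalogue order
#'
#' Columns are ordered as identifier columns (`subject_id`, and `label` if
#' present) followed by the 58 features of [radiomic_catalogue()] in
#' canonical order. All 58 must be present.
#'
#' @param x Data frame with `subject_id` and the 58 feature columns.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(x, path) {
  feats <- radiomic_feature_names()
  missing_cols <- setdiff(feats, names(x))
  if (length(missing_cols))
    stop("feature table lacks ", length(missing_cols),
         " catalogue features, e.g. ", missing_cols[1])
  lead <- intersect(c("subject_id", "label"), names(x))
  utils::write.csv(x[, c(lead, feats)], path, row.names = FALSE)
  invisible(path)
}

#' Read a radiomic feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Data frame with identifier columns and the 58 features.
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(radiomic_feature_names(), names(x))
  if (length(missing_cols))
    stop("feature table lacks ", length(missing_cols), " catalogue features")
  x
}
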