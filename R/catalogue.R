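#' The 58-feature radiomic catalogue
#'
#' Fixed catalogue of the 58 radiomic features computed by
#' [extract_features()], in canonical column order: 15 histogram features,
#' 2 gradient features, 13 gray-level co-occurrence matrix (GLCM) features,
#' 13 gray-level run-length matrix (GLRLM) features, 3 moment invariants,
#' 11 shape features and 1 fractal feature.
#'
#' @return A data frame with columns `name` and `category` (one row per
#'   feature, 58 rows, in canonical order).
#' @export
#' @examples
#' table(radiomic_catalogue()$category)
radiomic_catalogue <- function() {
  histo <- c("Mean", "SD", "Skewness", "ExcessKurtosis", "Energy", "Entropy",
             "Min", "Max", "VoxelCount", "Percentile_10", "Percentile_25",
             "Percentile_50", "Percentile_75", "Percentile_90", "Percentile_95")
  grad <- c("Mean", "SD")
  glcm <- c("ASM", "IDM", "Homogeneity", "Contrast", "Correlation", "Autocor",
            "Entropy", "CP", "CS", "CT", "SumEntropy", "DiffAverage",
            "DiffEntropy")
  glrlm <- c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
             "GNUN", "RLNUN", "RP", "RV", "RE")
  moment <- c("J1", "J2", "J3")
  shape <- c("Volume", "SurfaceArea", "Sphericity", "Compactness", "Roundness",
             "Circularity", "Longest1stAxis", "Longest2ndAxis",
             "PCA1stMajorSD", "PCA2ndMajorSD", "PCA3rdMajorSD")
  nm <- c(paste0("Texture_Histo_", histo[1:9]),
          paste0("Texture_", histo[10:15]),
          paste0("Texture_Grad_", grad),
          paste0("Texture_GLCM_", glcm),
          paste0("Texture_GLRLM_", glrlm),
          paste0("Texture_Moment_", moment),
          paste0("Shape_", shape),
          "Fractal_Dimension")
  cat <- rep(c("histogram", "gradient", "glcm", "glrlm", "moment", "shape",
               "fractal"),
             times = c(15L, 2L, 13L, 13L, 3L, 11L, 1L))
  data.frame(name = nm, category = cat, stringsAsFactors = FALSE)
}

#' Names of the 58 radiomic features
#'
#' @param category Optional category filter, one of `"histogram"`,
#'   `"gradient"`, `"glcm"`, `"glrlm"`, `"moment"`, `"shape"`, `"fractal"`.
#' @return Character vector of feature names in canonical order.
#' @export
radiomic_feature_names <- function(category = NULL) {
  cat <- radiomic_catalogue()
  if (is.null(category)) return(cat$name)
  category <- match.arg(category, unique(cat$category))
  cat$name[cat$category == category]
}
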