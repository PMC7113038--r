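# Interobserver agreement: two-way ICC for continuous measurements,
# weighted kappa for ordinal readings, and the ICC-based feature filter.

icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
      labels = c("poor", "moderate", "good", "excellent"), right = FALSE)
}

#' Two-way intraclass correlation coefficient for two readers
#'
#' Single-measure ICC from the two-way ANOVA mean squares of a
#' subjects-by-readers table. The default is the two-way random-effects,
#' absolute-agreement form ICC(2,1) =
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`; the consistency
#' form ICC(3,1) = `(MSR - MSE) / (MSR + (k-1) MSE)` is available for
#' sensitivity analyses. Raw values can be negative; the reported `icc`
#' is clamped at zero (negative reliabilities are treated as zero for
#' filtering). A table with zero total variance is perfect trivial
#' agreement: ICC 1 with a flag.
#'
#' @param reader1,reader2 Numeric vectors of the same length (>= 3 subjects).
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @return An object of class `icc_result`: list with `icc` (clamped),
#'   `raw_icc`, `band`, `n_subjects`, `type`, `degenerate`.
#' @export
icc_two_way <- function(reader1, reader2, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(reader1) != length(reader2))
    stop("reader vectors must have the same length")
  n <- length(reader1)
  if (n < 3L) stop("ICC needs at least 3 subjects")
  if (anyNA(reader1) || anyNA(reader2) ||
      any(!is.finite(c(reader1, reader2))))
    stop("reader values must be finite")
  x <- cbind(reader1, reader2)
  k <- 2L
  gm <- mean(x)
  if (all(x == x[1])) {
    res <- list(icc = 1, raw_icc = 1, band = factor("excellent",
                levels = levels(icc_band(0))), n_subjects = n, type = type,
                degenerate = TRUE)
    class(res) <- "icc_result"
    return(res)
  }
  subj_means <- rowMeans(x)
  rdr_means <- colMeans(x)
  msr <- k * sum((subj_means - gm)^2) / (n - 1)
  msc <- n * sum((rdr_means - gm)^2) / (k - 1)
  sse <- sum((x - outer(subj_means, rep(1, k)) -
                outer(rep(1, n), rdr_means) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  raw <- if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  res <- list(icc = max(raw, 0), raw_icc = raw,
              band = icc_band(max(raw, 0)), n_subjects = n, type = type,
              degenerate = FALSE)
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single measure): %.4f [%s], n = %d%s\n",
              x$type, x$icc, as.character(x$band), x$n_subjects,
              if (x$raw_icc < 0) sprintf(" (raw %.4f clamped to 0)", x$raw_icc)
              else ""))
  invisible(x)
}

#' Weighted kappa for two readers of an ordinal scale
#'
#' Chance-corrected agreement with distance-based disagreement weights
#' `d_ij = |i - j| / (R - 1)` (linear, default) or its square (quadratic):
#' `kappa = 1 - sum(d * observed) / sum(d * expected)` where `expected` is
#' the product of the marginals. Returns `NA` with a flag when both readers
#' use a single category (agreement is then undefined).
#'
#' @param reader1,reader2 Integer codes in `1..n_categories`.
#' @param n_categories Number of ordinal categories `R` (default: largest
#'   observed code).
#' @param weights `"linear"` or `"quadratic"`.
#' @return List with `kappa`, `band` (poor/fair/moderate/good/excellent at
#'   0.2/0.4/0.6/0.8), `n`, `degenerate`.
#' @export
weighted_kappa <- function(reader1, reader2, n_categories = NULL,
                           weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(reader1) != length(reader2))
    stop("reader vectors must have the same length")
  r1 <- as.integer(reader1); r2 <- as.integer(reader2)
  R <- as.integer(n_categories %||% max(r1, r2))
  if (any(c(r1, r2) < 1L) || any(c(r1, r2) > R))
    stop("codes must lie in 1..n_categories")
  if (length(unique(c(r1, r2))) == 1L) {
    return(list(kappa = NA_real_, band = NA_character_, n = length(r1),
                degenerate = TRUE))
  }
  O <- table(factor(r1, 1:R), factor(r2, 1:R)) / length(r1)
  E <- outer(rowSums(O), colSums(O))
  d <- abs(outer(1:R, 1:R, `-`)) / (R - 1)
  if (weights == "quadratic") d <- d^2
  denom <- sum(d * E)
  if (denom == 0)
    return(list(kappa = NA_real_, band = NA_character_, n = length(r1),
                degenerate = TRUE))
  kap <- 1 - sum(d * O) / denom
  band <- as.character(cut(kap, c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
                           labels = c("poor", "fair", "moderate", "good",
                                      "excellent"), right = FALSE))
  list(kappa = kap, band = band, n = length(r1), degenerate = FALSE)
}

#' Reliability filter: keep features with interobserver ICC above a threshold
#'
#' Computes the per-feature two-way absolute-agreement ICC between the two
#' readers' feature tables and retains the features whose clamped ICC is
#' strictly greater than `threshold` (0.75 by default, the good-reliability
#' boundary).
#'
#' @param features_reader1,features_reader2 Data frames or matrices with
#'   identical feature columns over the same subjects (non-feature columns
#'   `subject_id` / `label` are ignored).
#' @param threshold ICC retention threshold.
#' @param type ICC form, see [icc_two_way()].
#' @return List with `retained` (character vector of feature names) and
#'   `icc_table` (data frame: feature, icc, raw_icc, band).
#' @export
reliability_filter <- function(features_reader1, features_reader2,
                               threshold = 0.75,
                               type = c("agreement", "consistency")) {
  type <- match.arg(type)
  f1 <- drop_id_columns(features_reader1)
  f2 <- drop_id_columns(features_reader2)
  if (!identical(colnames(f1), colnames(f2)))
    stop("the two readers' tables must have identical feature columns")
  if (nrow(f1) != nrow(f2))
    stop("the two readers' tables must cover the same subjects")
  res <- lapply(colnames(f1), function(nm)
    icc_two_way(f1[[nm]], f2[[nm]], type = type))
  icc_table <- data.frame(
    feature = colnames(f1),
    icc = vapply(res, `[[`, numeric(1), "icc"),
    raw_icc = vapply(res, `[[`, numeric(1), "raw_icc"),
    band = vapply(res, function(r) as.character(r$band), character(1)),
    stringsAsFactors = FALSE)
  list(retained = icc_table$feature[icc_table$icc > threshold],
       icc_table = icc_table)
}

drop_id_columns <- function(x) {
  x <- as.data.frame(x)
  x[, setdiff(colnames(x), c("subject_id", "label")), drop = FALSE]
}
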