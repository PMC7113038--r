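# Rad-score signatures: linear radiomic scores, ROC/Youden cutoff analysis,
# dichotomization, and the frozen published signature.

#' Create a Rad-score signature
#'
#' A Rad-score signature is a linear combination of named radiomic features:
#' `score = intercept + sum(coef_f * feature_f)`, optionally with a
#' classification cutoff (score strictly greater than the cutoff predicts
#' PD-L1 positivity).
#'
#' @param intercept Numeric intercept.
#' @param coefficients Named numeric vector of feature weights; names must
#'   belong to the 58-feature catalogue.
#' @param cutoff Optional finite classification cutoff.
#' @param name Optional signature name.
#' @return An object of class `rad_signature`.
#' @export
rad_signature <- function(intercept, coefficients, cutoff = NULL,
                          name = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  coefficients <- unlist(coefficients)
  if (length(coefficients)) {
    if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
      stop("'coefficients' must be named")
    unknown <- setdiff(names(coefficients), radiomic_feature_names())
    if (length(unknown))
      stop("unknown feature name(s) in signature: ",
           paste(unknown, collapse = ", "))
    if (any(!is.finite(coefficients))) stop("coefficients must be finite")
  }
  if (!is.null(cutoff)) {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  }
  structure(list(intercept = unname(intercept), coefficients = coefficients,
                 cutoff = cutoff, name = name),
            class = "rad_signature")
}

#' @export
print.rad_signature <- function(x, ...) {
  cat("<rad_signature>", if (!is.null(x$name)) paste0(" ", x$name), "\n",
      sep = "")
  terms <- sprintf("%s x %s", names(x$coefficients),
                   format(x$coefficients, digits = 6, trim = TRUE))
  cat("  Rad-score =", format(x$intercept, digits = 6),
      if (length(terms)) paste("+", paste(terms, collapse = " + ")), "\n")
  if (!is.null(x$cutoff))
    cat("  positive if Rad-score >", format(x$cutoff, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.rad_signature <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Evaluate a Rad-score signature
#'
#' @param sig A [rad_signature()].
#' @param features Named numeric vector, or a data frame / matrix with one
#'   column per feature; all signature features must be present and finite.
#' @return Numeric score(s): `intercept + sum(coef * value)`.
#' @export
rad_score <- function(sig, features) {
  stopifnot(inherits(sig, "rad_signature"))
  nms <- names(sig$coefficients)
  if (is.null(dim(features))) {
    missing_f <- setdiff(nms, names(features))
    if (length(missing_f))
      stop("missing signature feature(s): ", paste(missing_f, collapse = ", "))
    vals <- features[nms]
    if (length(nms) && any(!is.finite(as.numeric(vals))))
      stop("non-finite value for signature feature(s)")
    return(unname(sig$intercept + sum(as.numeric(vals) * sig$coefficients)))
  }
  features <- as.data.frame(features)
  missing_f <- setdiff(nms, colnames(features))
  if (length(missing_f))
    stop("missing signature feature(s): ", paste(missing_f, collapse = ", "))
  if (!length(nms)) return(rep(sig$intercept, nrow(features)))
  m <- as.matrix(features[, nms, drop = FALSE])
  if (any(!is.finite(m))) stop("non-finite value for signature feature(s)")
  unname(sig$intercept + drop(m %*% sig$coefficients))
}

#' @export
predict.rad_signature <- function(object, newdata,
                                  type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- rad_score(object, newdata)
  if (type == "score") return(s)
  if (is.null(object$cutoff))
    stop("signature has no cutoff; cannot classify")
  as.integer(s > object$cutoff)
}

#' The published Rad-score signature
#'
#' The frozen four-feature signature (GLCM angular second moment, GLRLM run
#' variance, run entropy and short-run high gray-level emphasis) with its
#' reported coefficients and the reported classification cutoff -0.715,
#' shipped as a versioned JSON fixture. Note that the numeric feature values
#' this signature was derived from came from a commercial extraction tool
#' whose exact formulas are unpublished; the signature is included as a
#' worked example and serialization reference, not as a claim of numeric
#' transferability to this package's feature scales.
#'
#' @return A [rad_signature()] object.
#' @export
published_signature <- function() {
  path <- system.file("extdata", "published_signature_v1.json",
                      package = "radpdl1", mustWork = TRUE)
  read_signature_json(path)
}

#' Read / write a signature as JSON
#'
#' @param path JSON file path.
#' @return `read_signature_json()` returns a [rad_signature()];
#'   `write_signature_json()` invisibly returns `path`.
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rad_signature(x$intercept, unlist(x$coefficients),
                cutoff = x$cutoff, name = x$name)
}

#' @rdname read_signature_json
#' @param sig A [rad_signature()].
#' @export
write_signature_json <- function(sig, path) {
  stopifnot(inherits(sig, "rad_signature"))
  jsonlite::write_json(
    list(name = sig$name, intercept = sig$intercept,
         coefficients = as.list(sig$coefficients), cutoff = sig$cutoff),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' ROC-optimal (Youden) cutoff
#'
#' Scans the midpoints between consecutive distinct observed scores and
#' returns the cutoff maximizing the Youden index
#' (sensitivity + specificity - 1) for the rule `score > cutoff` =>
#' positive. Ties are broken toward the higher cutoff (higher specificity).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (both classes must be present).
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`, and
#'   the concordance `auc`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  s <- sort(unique(scores))
  if (length(s) < 2L) stop("cutoff undefined: all scores identical")
  cand <- (s[-1] + s[-length(s)]) / 2
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  sens <- vapply(cand, function(cc) sum(scores > cc & labels == 1L) / n1,
                 numeric(1))
  spec <- vapply(cand, function(cc) sum(scores <= cc & labels == 0L) / n0,
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[length(best)]            # ties -> larger cutoff
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best],
       auc = auc_concordance(scores, labels))
}

#' Dichotomize a continuous variable at a cutoff
#'
#' Rad-scores are positive when strictly greater than the cutoff
#' (`direction = "gt"`); age-type variables are coded for the low stratum
#' (`direction = "le"`, value at the cutoff included).
#'
#' @param values Finite numeric vector.
#' @param cutoff Finite cutoff.
#' @param direction `"gt"` (indicator of `value > cutoff`) or `"le"`
#'   (indicator of `value <= cutoff`).
#' @return Integer 0/1 vector.
#' @export
dichotomize <- function(values, cutoff, direction = c("gt", "le")) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(values)), is.finite(cutoff))
  if (direction == "gt") as.integer(values > cutoff)
  else as.integer(values <= cutoff)
}
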