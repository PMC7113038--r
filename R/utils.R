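# Internal numeric helpers shared across modules.

#' Concordance (ROC) AUC
#'
#' Rank-statistic AUC with midrank handling of ties: the probability that a
#' randomly chosen positive subject scores higher than a randomly chosen
#' negative one, counting ties as 1/2. Equals the c-statistic of a model whose
#' linear predictor is `scores`.
#'
#' @param scores Numeric vector of scores (higher = more likely positive).
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_concordance <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have the same length")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Coerce labels to integer 0/1; error on anything else.
check_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (!is.numeric(labels) || anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be binary (0/1), without missing values")
  as.integer(labels)
}

# Deterministic stream of child seeds derived from one master seed, so that
# per-subject / per-replicate randomness is reproducible and independent of
# evaluation order. Values stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run code with a local, restored-on-exit RNG seeded from `seed`.
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  code
}

# Stratified fold assignment: within each class, subjects are permuted and
# dealt round-robin into k folds, so each fold holds both classes whenever
# the class counts allow it.
stratified_folds <- function(labels, k) {
  labels <- check_binary_labels(labels)
  fold <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    if (length(idx) < k && length(idx) > 0L && cl == 1L)
      warning("fewer positive subjects than folds; some folds lack positives")
    fold[idx] <- (sample(seq_along(idx)) - 1L) %% k + 1L
  }
  fold
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
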