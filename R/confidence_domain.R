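# Three-domain confidence scoring. Decidability measures how far a
# predicted probability sits from the equivocal 0.5; reliability measures
# how close a query molecule sits to the model's training chemical space
# (mean Tanimoto similarity to the k nearest training fingerprints); the
# applicability domain is the conjunction of thresholds on both. The two
# scoring functions are pluggable through a small registry.

#' Decidability of a predicted probability
#'
#' `|2p - 1|`: 0 for a maximally equivocal prediction (p = 0.5), 1 for a
#' decisive one (p = 0 or 1). Symmetric about 0.5.
#'
#' @param probability Numeric vector in `[0, 1]`.
#' @return Numeric vector in `[0, 1]`.
#' @export
decidability <- function(probability) {
  assert_probability(probability)
  abs(2 * probability - 1)
}

#' Tanimoto similarity between two fingerprint matrices
#'
#' @param a,b 0/1 matrices with one fingerprint per row and equal widths.
#' @return `nrow(a)` x `nrow(b)` similarity matrix; pairs with no on-bits
#'   on either side score 0.
#' @export
tanimoto_similarity <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b))
  inter <- a %*% t(b)
  na <- rowSums(a); nb <- rowSums(b)
  denom <- outer(na, nb, "+") - inter
  sim <- ifelse(denom > 0, inter / denom, 0)
  sim
}

#' Reliability: chemical-space proximity to a training set
#'
#' Mean Tanimoto similarity between each query fingerprint and its k most
#' similar training fingerprints (k is truncated to the reference size).
#' 1 when the query is itself a training molecule (k = 1); 0 when it shares
#' no on-bits with any training molecule.
#'
#' @param query_fingerprints 0/1 matrix of query fingerprints (or a
#'   `fluid_features` object).
#' @param training_fingerprints 0/1 matrix of the model's training
#'   fingerprints (or a `fluid_features` object / `fluid_model`).
#' @param k Number of nearest training neighbours averaged (default 5).
#' @param chunk Queries processed per block, bounding the similarity
#'   matrix held in memory.
#' @return Numeric vector in `[0, 1]`, one value per query row.
#' @export
reliability <- function(query_fingerprints, training_fingerprints, k = 5,
                        chunk = 4000) {
  if (inherits(query_fingerprints, "fluid_features")) {
    query_fingerprints <- query_fingerprints$fingerprint
  }
  if (inherits(training_fingerprints, "fluid_model")) {
    training_fingerprints <- training_fingerprints$train_fingerprints
  }
  if (inherits(training_fingerprints, "fluid_features")) {
    training_fingerprints <- training_fingerprints$fingerprint
  }
  q <- as.matrix(query_fingerprints); tr <- as.matrix(training_fingerprints)
  if (nrow(tr) == 0) abort("reliability needs a non-empty training reference.")
  if (k < 1) abort("k must be at least 1.")
  k <- min(k, nrow(tr))
  n <- nrow(q)
  out <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    sim <- tanimoto_similarity(q[idx, , drop = FALSE], tr)
    out[idx] <- apply(sim, 1, function(s) mean(sort(s, decreasing = TRUE)[seq_len(k)]))
  }
  out
}

#' Registry of confidence scoring functions
#'
#' Both default scores are the package's published definitions; an
#' experiment can swap either by passing an alternative function of the
#' same signature to [predict_pool()]. The registry names the available
#' built-ins.
#'
#' @return Nested list: `decidability` and `reliability`, each a named
#'   list of scoring functions.
#' @export
confidence_scorers <- function() {
  list(
    decidability = list(absolute_margin = decidability),
    reliability = list(knn_tanimoto = reliability)
  )
}

#' Applicability-domain membership
#'
#' A prediction is in domain when its reliability and decidability both
#' reach their thresholds. Thresholds are free experiment parameters; the
#' documented default reliability cut for study-protocol runs is 0.005.
#'
#' @param predictions Data frame with `reliability` and `decidability`
#'   columns (e.g. from [predict_pool()]), or a numeric reliability vector
#'   when `decidability` is supplied separately.
#' @param reliability_min,decidability_min Thresholds in `[0, 1]`.
#' @param decidability Decidability vector for the vector interface.
#' @return Logical vector, one entry per prediction.
#' @export
in_applicability_domain <- function(predictions, reliability_min = 0.005,
                                    decidability_min = 0,
                                    decidability = NULL) {
  if (reliability_min < 0 || reliability_min > 1 ||
      decidability_min < 0 || decidability_min > 1) {
    abort("applicability-domain thresholds must lie in [0, 1].")
  }
  if (is.data.frame(predictions)) {
    rel <- predictions$reliability
    dec <- predictions$decidability
  } else {
    rel <- predictions
    dec <- decidability
  }
  if (is.null(rel) || is.null(dec)) {
    abort("need both reliability and decidability values.")
  }
  rel >= reliability_min & dec >= decidability_min
}
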