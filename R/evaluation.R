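# Evaluation protocol: confusion-table metrics (sensitivity, specificity,
# balanced accuracy, precision, MCC), applicability-domain-restricted
# evaluation with coverage reporting, class-imbalance auditing, AD-vs-
# performance trend tables, and joint chemical-space embedding.

#' Confusion counts from paired truth/prediction vectors
#'
#' @param truth,predicted Integer 0/1 vectors of equal length (or a
#'   `ConfusionCounts`-style list passed through unchanged).
#' @return A `fluid_confusion` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted = NULL) {
  if (is.list(truth) && all(c("TP", "TN", "FP", "FN") %in% names(truth))) {
    out <- truth[c("TP", "TN", "FP", "FN")]
  } else {
    truth <- as_binary_label(truth); predicted <- as_binary_label(predicted)
    stopifnot(length(truth) == length(predicted))
    out <- list(TP = sum(truth == 1 & predicted == 1),
                TN = sum(truth == 0 & predicted == 0),
                FP = sum(truth == 0 & predicted == 1),
                FN = sum(truth == 1 & predicted == 0))
  }
  structure(lapply(out, as.numeric), class = "fluid_confusion")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' confusion-table correlation in `[-1, 1]`. When any factor of the
#' denominator is zero the coefficient is undefined; the package follows
#' the common convention of returning 0 in that case so reports stay
#' total.
#'
#' @param counts `fluid_confusion` (or anything [confusion_counts()]
#'   accepts).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  c <- confusion_counts(counts)
  denom <- (c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  if (denom == 0) return(0)
  (c$TP * c$TN - c$FP * c$FN) / sqrt(denom)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, balanced accuracy (the arithmetic mean of sensitivity and
#' specificity), and MCC. A ratio with a zero denominator is reported as
#' missing (`NA`), and balanced accuracy is missing when either of its
#' components is.
#'
#' @inheritParams mcc
#' @return One-row tibble of metrics.
#' @export
classification_metrics <- function(counts) {
  c <- confusion_counts(counts)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(c$TP, c$TP + c$FN)
  spec <- ratio(c$TN, c$TN + c$FP)
  tibble(
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    precision = ratio(c$TP, c$TP + c$FP),
    mcc = mcc(c)
  )
}

#' Evaluate a model on a labeled test set
#'
#' Predicts the test set and reports the classification metrics, optionally
#' restricted to the applicability domain: with `ad_restricted = TRUE`
#' only predictions whose reliability (against the model's training space)
#' and decidability reach their thresholds are scored, and `ad_coverage`
#' reports the in-domain fraction; otherwise every record counts and
#' coverage is 1.
#'
#' @param model A `fluid_model`.
#' @param test Model-ready dataset (list with `ids`, `labels`, `features`).
#' @param ad_restricted Restrict scoring to in-domain predictions?
#' @param reliability_min,decidability_min Applicability-domain thresholds.
#' @param k Neighbours for reliability scoring.
#' @return A `fluid_metrics` one-row tibble: metrics, `ad_coverage`,
#'   `n_evaluated`, `variant`, `ad_restricted`.
#' @export
evaluate_model <- function(model, test, ad_restricted = FALSE,
                           reliability_min = 0.005, decidability_min = 0,
                           k = 5) {
  labels <- as_binary_label(test$labels)
  p <- predict_prob(model, test$features)
  keep <- rep(TRUE, length(p))
  coverage <- 1
  if (ad_restricted) {
    rel <- reliability(test$features, model, k = k)
    keep <- in_applicability_domain(rel, reliability_min, decidability_min,
                                    decidability = decidability(p))
    coverage <- mean(keep)
  }
  if (!any(keep)) {
    warn("no test predictions fall inside the applicability domain; metrics are missing.")
    out <- tibble(sensitivity = NA_real_, specificity = NA_real_,
                  balanced_accuracy = NA_real_, precision = NA_real_,
                  mcc = NA_real_)
  } else {
    out <- classification_metrics(
      confusion_counts(labels[keep], as.integer(p[keep] >= 0.5))
    )
  }
  out <- mutate(out,
                ad_coverage = coverage,
                n_evaluated = sum(keep),
                variant = model$variant %||% model$member_id %||% model$architecture,
                ad_restricted = ad_restricted)
  class(out) <- c("fluid_metrics", class(out))
  out
}

#' Inactive/active class ratio of a labeled dataset
#'
#' The number of inactive (0) records divided by the number of active (1)
#' records — the imbalance statistic quoted in dataset audits, rounded to
#' 2 decimals in human-readable tables (full precision returned here).
#'
#' @param dataset A data frame with a `label` column, an integer 0/1
#'   vector, or a list/pair of counts `c(inactive, active)`.
#' @return Numeric scalar.
#' @export
class_ratio <- function(dataset) {
  if (is.data.frame(dataset)) {
    labels <- as_binary_label(dataset$label)
    n0 <- sum(labels == 0); n1 <- sum(labels == 1)
  } else if (length(dataset) == 2 && is.numeric(dataset) && all(dataset >= 0) &&
             !all(dataset %in% c(0, 1))) {
    n0 <- dataset[[1]]; n1 <- dataset[[2]]
  } else {
    labels <- as_binary_label(dataset)
    n0 <- sum(labels == 0); n1 <- sum(labels == 1)
  }
  if (n1 == 0) abort("class ratio undefined: no active (label 1) records.")
  n0 / n1
}

#' Applicability-domain trend table across model variants
#'
#' Lines up metric reports that share a test set, in the given order, and
#' reports each variant's AD coverage next to its performance metrics plus
#' the coverage delta from the previous variant — the table behind
#' AD-versus-performance trend plots.
#'
#' @param reports List of `fluid_metrics` rows (or a tibble of them),
#'   ordered as the comparison should read (e.g. T, HI, HF).
#' @return Tibble with variant, coverage, metrics, and `coverage_delta`.
#' @export
ad_trend <- function(reports) {
  tbl <- if (is.data.frame(reports)) as_tibble(reports) else bind_rows(reports)
  if (nrow(tbl) < 2) abort("ad_trend needs at least two reports.")
  if (length(unique(tbl$n_evaluated / tbl$ad_coverage)) > 1 &&
      stats::sd(tbl$n_evaluated / tbl$ad_coverage) > 1e-6) {
    abort("reports do not share a test set (implied test sizes differ).")
  }
  tbl |>
    select("variant", "ad_coverage", "sensitivity", "specificity",
           "balanced_accuracy", "mcc") |>
    mutate(coverage_delta = .data$ad_coverage - dplyr::lag(.data$ad_coverage))
}

#' Joint chemical-space embedding of several data sets
#'
#' Embeds the concatenation of the named feature sets into 2 or 3
#' dimensions with set-membership tags, so the chemical-space overlap
#' between, say, internal training, test, and federated sets can be
#' inspected in one coordinate system. The embedding backend is pluggable
#' (`"pca"` by default, `"mds"` for classical multidimensional scaling on
#' Euclidean distances); the analysis protocol — joint embedding, set
#' tags, and the nearest-neighbour overlap statistic — is independent of
#' the backend. Deterministic given the seed; axis signs are fixed by
#' convention.
#'
#' @param feature_matrices Named list of `fluid_features` or numeric
#'   matrices sharing one feature space.
#' @param dims 2 or 3.
#' @param method `"pca"` or `"mds"`.
#' @param seed Seed (recorded; the default backends are deterministic).
#' @param max_mds_rows Row cap above which `"mds"` falls back to `"pca"`
#'   (classical scaling is quadratic in rows).
#' @return A `fluid_embedding` tibble: `set`, `id`, `dim1`, `dim2`
#'   (`dim3`), with the method and seed as attributes.
#' @export
chemspace_embed <- function(feature_matrices, dims = 2,
                            method = c("pca", "mds"), seed = 1,
                            max_mds_rows = 4000) {
  if (!dims %in% c(2, 3)) abort("dims must be 2 or 3.")
  method <- match.arg(method)
  mats <- purrr::imap(feature_matrices, function(f, nm) {
    m <- if (inherits(f, "fluid_features")) features_matrix(f) else as.matrix(f)
    ids <- if (inherits(f, "fluid_features")) f$id else paste0(nm, "_", seq_len(nrow(m)))
    list(m = m, ids = ids, set = rep(nm, nrow(m)))
  })
  widths <- unique(vapply(mats, function(x) ncol(x$m), numeric(1)))
  if (length(widths) != 1) abort("all feature sets must share one feature space.")
  big <- do.call(rbind, lapply(mats, `[[`, "m"))
  sets <- unlist(lapply(mats, `[[`, "set"))
  ids <- unlist(lapply(mats, `[[`, "ids"))
  if (method == "mds" && nrow(big) > max_mds_rows) method <- "pca"
  coords <- withr::with_seed(seed, {
    if (method == "pca") {
      keep <- apply(big, 2, stats::var) > 0
      if (!any(keep)) {
        # degenerate input (e.g. duplicated points only): all coordinates 0
        sc <- matrix(0, nrow(big), dims)
        return_zero <- TRUE
      } else return_zero <- FALSE
      if (return_zero) sc else {
      pr <- stats::prcomp(big[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
                          rank. = dims)
      sc <- pr$x[, seq_len(dims), drop = FALSE]
      # fix axis signs: largest-magnitude loading positive
      for (j in seq_len(dims)) {
        piv <- which.max(abs(pr$rotation[, j]))
        if (pr$rotation[piv, j] < 0) sc[, j] <- -sc[, j]
      }
      if (ncol(sc) < dims) sc <- cbind(sc, matrix(0, nrow(sc), dims - ncol(sc)))
      sc
      }
    } else {
      stats::cmdscale(stats::dist(big), k = dims)
    }
  })
  out <- tibble(set = sets, id = ids)
  for (j in seq_len(dims)) out[[paste0("dim", j)]] <- coords[, j]
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  class(out) <- c("fluid_embedding", class(out))
  out
}

#' Nearest-neighbour overlap between two embedded sets
#'
#' Fraction of `query_set` points whose nearest embedded neighbour (among
#' all other points) belongs to `reference_set` — a scalar summary of how
#' strongly one set's chemical space is covered by another's in the joint
#' embedding.
#'
#' @param embedding A `fluid_embedding`.
#' @param query_set,reference_set Set names from the embedding.
#' @return Numeric scalar in `[0, 1]`.
#' @export
embedding_overlap <- function(embedding, query_set, reference_set) {
  stopifnot(inherits(embedding, "fluid_embedding"))
  dims <- grep("^dim", names(embedding), value = TRUE)
  q <- embedding$set == query_set
  if (!any(q)) abort(sprintf("no points in set '%s'", query_set))
  coords <- as.matrix(embedding[, dims])
  qi <- which(q)
  hits <- vapply(qi, function(i) {
    d <- colSums((t(coords) - coords[i, ])^2)
    d[i] <- Inf
    embedding$set[which.min(d)] == reference_set
  }, logical(1))
  mean(hits)
}
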