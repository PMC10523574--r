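# The distillation core: every member's teacher labels the shared unlabeled
# pool, member predictions are consolidated into one call per molecule, and
# the federated training set is built by reliability filtering, per-class
# decidability ranking, and cross-class fill.

#' Predict the unlabeled pool with one teacher
#'
#' One prediction record per pool molecule: predicted label, probability,
#' decidability, and reliability against the teacher's training space.
#'
#' @param teacher A `fluid_model`.
#' @param pool_features `fluid_features` for the pool, built under the same
#'   featurization configuration as the teacher's training data.
#' @param k Neighbours used for reliability (default 5).
#' @param decidability_fn,reliability_fn Scoring functions; defaults are
#'   the registry built-ins (see [confidence_scorers()]).
#' @return Tibble of prediction records: `molecule_id`, `member_id`,
#'   `predicted_label`, `probability`, `decidability`, `reliability`.
#' @export
predict_pool <- function(teacher, pool_features, k = 5,
                         decidability_fn = decidability,
                         reliability_fn = reliability) {
  stopifnot(inherits(teacher, "fluid_model"),
            inherits(pool_features, "fluid_features"))
  cfg_m <- teacher$feature_config$descriptor_hash %||% NA
  cfg_f <- pool_features$config$descriptor_hash %||% NA
  if (!identical(cfg_m, cfg_f)) {
    abort("featurization configuration mismatch between teacher and pool features.")
  }
  n <- length(pool_features$id)
  if (n == 0) {
    return(tibble(molecule_id = character(0), member_id = character(0),
                  predicted_label = integer(0), probability = numeric(0),
                  decidability = numeric(0), reliability = numeric(0)))
  }
  p <- predict_prob(teacher, pool_features)
  tibble(
    molecule_id = pool_features$id,
    member_id = teacher$member_id %||% "member01",
    predicted_label = as.integer(p >= 0.5),
    probability = p,
    decidability = decidability_fn(p),
    reliability = reliability_fn(pool_features$fingerprint,
                                 teacher$train_fingerprints, k = k)
  )
}

#' Consolidate member predictions on the shared pool
#'
#' Combines every member's call on each pool molecule into one consensus
#' record. The default rule is a decidability-weighted majority vote: the
#' label whose voters carry the larger summed decidability wins, an exact
#' weight tie resolving to inactive (0) — the conservative call for safety
#' screening. When every member is fully equivocal (all weights zero) the
#' unweighted majority decides, so a single member's predictions pass
#' through unchanged. Consensus decidability and reliability are the member
#' means; `member_agreement` is the fraction of members voting the
#' consensus label. Member order never affects the result.
#'
#' @param member_predictions Either one tibble of prediction records with a
#'   `member_id` column or a list of per-member tibbles. All members must
#'   have predicted exactly the same molecule ids.
#' @param rule `"decidability_weighted"` (default), `"majority"` (one
#'   member one vote), or `"mean_probability"` (consensus label from the
#'   mean probability).
#' @return Tibble of consolidated predictions: `molecule_id`,
#'   `consensus_label`, `consensus_decidability`, `consensus_reliability`,
#'   `n_members`, `member_agreement`.
#' @export
consolidate <- function(member_predictions,
                        rule = c("decidability_weighted", "majority",
                                 "mean_probability")) {
  rule <- match.arg(rule)
  preds <- if (is.data.frame(member_predictions)) member_predictions
           else bind_rows(member_predictions)
  stopifnot(all(c("molecule_id", "member_id", "predicted_label",
                  "probability", "decidability", "reliability") %in% names(preds)))
  members <- unique(preds$member_id)
  id_sets <- lapply(members, function(m) sort(preds$molecule_id[preds$member_id == m]))
  ref <- id_sets[[1]]
  for (i in seq_along(id_sets)[-1]) {
    if (!identical(id_sets[[i]], ref)) {
      missing <- c(setdiff(ref, id_sets[[i]]), setdiff(id_sets[[i]], ref))
      abort(sprintf("members predicted different molecule sets; %d id(s) differ (e.g. %s)",
                    length(missing), paste(head(missing, 3), collapse = ", ")))
    }
  }
  out <- preds |>
    group_by(.data$molecule_id) |>
    summarise(
      consensus_label = {
        w1 <- sum(.data$decidability[.data$predicted_label == 1L])
        w0 <- sum(.data$decidability[.data$predicted_label == 0L])
        if (rule == "mean_probability") {
          as.integer(mean(.data$probability) >= 0.5)
        } else if (rule == "majority" || (w1 == 0 && w0 == 0)) {
          v1 <- sum(.data$predicted_label == 1L)
          as.integer(v1 > n() - v1)
        } else {
          as.integer(w1 > w0)
        }
      },
      consensus_decidability = mean(.data$decidability),
      consensus_reliability = mean(.data$reliability),
      n_members = n(),
      member_agreement = mean(.data$predicted_label == consensus_label),
      .groups = "drop"
    )
  arrange(out, .data$molecule_id)
}

#' Build the federated training set by filter, rank, and fill
#'
#' The construction follows the distillation recipe: (1) consolidated
#' predictions whose reliability falls below `reliability_min` are
#' discarded; (2) the survivors are split by consensus label and each class
#' is ranked by decreasing decidability (ties broken by higher reliability,
#' then lexicographic molecule id, for full determinism); (3) up to
#' `n_per_class` records are taken from each class; (4) if one class falls
#' short, the shortfall is filled with additional records from the other
#' class, continuing down its decidability ranking; (5) if the donor class
#' is also exhausted, everything eligible is returned and a shortfall
#' warning is recorded. The total is therefore
#' `min(2 * n_per_class, eligible)`.
#'
#' @param consolidated Tibble from [consolidate()].
#' @param n_per_class Per-class target (study protocol: 10,000; desk-scale
#'   default runs use 500).
#' @param reliability_min Reliability filter threshold (study-protocol
#'   default 0.005).
#' @param decidability_min Optional additional decidability filter
#'   (`NULL` = off, the default reading of the recipe).
#' @return A `fluid_federated_set`: tibble `records` (`molecule_id`,
#'   `label`, `decidability`, `reliability`), counts `n_pos`/`n_neg`, and
#'   provenance (thresholds, targets, shortfall).
#' @export
build_federated_set <- function(consolidated, n_per_class = 10000,
                                reliability_min = 0.005,
                                decidability_min = NULL) {
  if (n_per_class < 1) abort("n_per_class must be at least 1.")
  eligible <- filter(consolidated, .data$consensus_reliability >= reliability_min)
  if (!is.null(decidability_min)) {
    eligible <- filter(eligible, .data$consensus_decidability >= decidability_min)
  }
  rank_class <- function(lab) {
    eligible |>
      filter(.data$consensus_label == lab) |>
      arrange(desc(.data$consensus_decidability),
              desc(.data$consensus_reliability), .data$molecule_id)
  }
  pos <- rank_class(1L); neg <- rank_class(0L)
  take_pos <- min(n_per_class, nrow(pos))
  take_neg <- min(n_per_class, nrow(neg))
  # cross-class fill, continuing down the donor ranking
  short_pos <- n_per_class - take_pos
  short_neg <- n_per_class - take_neg
  take_neg <- min(take_neg + short_pos, nrow(neg))
  take_pos <- min(take_pos + short_neg, nrow(pos))
  sel <- bind_rows(head(pos, take_pos), head(neg, take_neg))
  shortfall <- 2 * n_per_class - nrow(sel)
  if (nrow(sel) == 0) warn("federated set is empty: no predictions passed the reliability filter.")
  else if (shortfall > 0) warn(sprintf("federated set short by %d record(s): eligible pool exhausted.", shortfall))
  records <- tibble(
    molecule_id = sel$molecule_id,
    label = sel$consensus_label,
    decidability = sel$consensus_decidability,
    reliability = sel$consensus_reliability
  )
  structure(list(
    records = records,
    n_pos = sum(records$label == 1L),
    n_neg = sum(records$label == 0L),
    provenance = list(n_per_class = n_per_class,
                      reliability_min = reliability_min,
                      decidability_min = decidability_min,
                      n_eligible = nrow(eligible),
                      shortfall = shortfall)
  ), class = "fluid_federated_set")
}

#' @export
print.fluid_federated_set <- function(x, ...) {
  cat(sprintf("<fluid_federated_set> %d records (%d+ / %d-), target %d per class, reliability >= %g\n",
              nrow(x$records), x$n_pos, x$n_neg,
              x$provenance$n_per_class, x$provenance$reliability_min))
  invisible(x)
}

#' Write a federated set as CSV (with a JSON provenance sidecar)
#' @param fedset A `fluid_federated_set`.
#' @param path Output CSV path; provenance goes to `<path>.json`.
#' @export
write_federated_set <- function(fedset, path) {
  readr::write_csv(fedset$records, path)
  jsonlite::write_json(fedset$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
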