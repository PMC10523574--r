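# Per-partner "teacher" training: repeated stratified/random k-fold
# cross-validation, seeded hyperparameter search scored on balanced
# accuracy with sensitivity tie-breaking, minority oversampling, and the
# trained-classifier container that carries the training-space reference
# required for reliability scoring.

# Fold assignment depends only on (seed, n, labels, scheme, k, repeats) so
# every architecture compared under the same seed shares folds.
make_folds <- function(labels, k = 5, scheme = c("stratified", "random"),
                       repeats = 10, seed = 1) {
  scheme <- match.arg(scheme)
  labels <- as_binary_label(labels)
  n <- length(labels)
  if (n < k) abort("need at least k records for k-fold cross-validation.")
  if (scheme == "stratified") {
    for (cls in c(0L, 1L)) {
      if (sum(labels == cls) < k) {
        abort(sprintf("class %d has fewer than k = %d members; stratified folds impossible.", cls, k))
      }
    }
  }
  withr::with_seed(derive_seed(seed, paste0("folds-", scheme, "-", k, "-", n)), {
    lapply(seq_len(repeats), function(r) {
      fold <- integer(n)
      if (scheme == "random") {
        fold <- sample(rep_len(seq_len(k), n))
      } else {
        for (cls in c(0L, 1L)) {
          idx <- which(labels == cls)
          fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
      }
      fold
    })
  })
}

fold_metrics <- function(truth, prob) {
  pred <- as.integer(prob >= 0.5)
  cc <- confusion_counts(truth, pred)
  m <- classification_metrics(cc)
  auc <- if (length(unique(truth)) == 2) {
    as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE, direction = "<")))
  } else NA_real_
  mutate(m, auc = auc)
}

#' Repeated k-fold cross-validation of one architecture
#'
#' Runs `repeats` independent k-fold rounds (stratified folds preserve the
#' class ratio within rounding; random folds do not), fitting the
#' architecture on each training fold and scoring balanced accuracy,
#' specificity, sensitivity, precision, AUC, and MCC on the held-out fold.
#' Every record is tested exactly once per repeat.
#'
#' @param features `fluid_features` or a model-ready numeric matrix.
#' @param labels Integer 0/1 labels.
#' @param architecture Architecture name from [zoo_architectures()].
#' @param scheme `"stratified"` or `"random"` fold assignment.
#' @param k Folds per repeat (default 5).
#' @param repeats Independent repeats (default 10).
#' @param hyperparameters Optional list overriding architecture defaults.
#' @param seed Seed controlling folds and fits.
#' @return A `fluid_cv` object; `tidy()` gives per-fold metrics, `glance()`
#'   the aggregated mean and SD per metric.
#' @export
cross_validate <- function(features, labels, architecture,
                           scheme = c("stratified", "random"),
                           k = 5, repeats = 10,
                           hyperparameters = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  x <- if (inherits(features, "fluid_features")) features_matrix(features) else as.matrix(features)
  labels <- check_both_classes(labels, "cross-validation")
  folds <- make_folds(labels, k = k, scheme = scheme, repeats = repeats, seed = seed)
  rows <- list()
  for (r in seq_len(repeats)) {
    for (f in seq_len(k)) {
      test_idx <- which(folds[[r]] == f)
      train_idx <- setdiff(seq_along(labels), test_idx)
      fit <- fit_architecture(architecture, x[train_idx, , drop = FALSE],
                              labels[train_idx],
                              hyperparameters,
                              seed = derive_seed(seed, paste0("cv-", r, "-", f)))
      m <- fold_metrics(labels[test_idx], prob_architecture(fit, x[test_idx, , drop = FALSE]))
      rows[[length(rows) + 1]] <- mutate(m, replicate = r, fold = f)
    }
  }
  per_fold <- bind_rows(rows)
  metric_cols <- c("balanced_accuracy", "specificity", "sensitivity",
                   "precision", "auc", "mcc")
  summary <- tibble(
    metric = metric_cols,
    mean = unname(vapply(metric_cols, function(mc) mean(per_fold[[mc]], na.rm = TRUE), numeric(1))),
    sd = unname(vapply(metric_cols, function(mc) stats::sd(per_fold[[mc]], na.rm = TRUE), numeric(1)))
  )
  structure(list(folds = per_fold, summary = summary,
                 architecture = architecture, scheme = scheme,
                 k = k, repeats = repeats, seed = seed),
            class = "fluid_cv")
}

#' @export
print.fluid_cv <- function(x, ...) {
  cat(sprintf("<fluid_cv> %s, %s %d-fold x %d repeats\n",
              x$architecture, x$scheme, x$k, x$repeats))
  print(x$summary)
  invisible(x)
}

#' Seeded hyperparameter search scored on balanced accuracy
#'
#' Draws up to `budget` configurations from the architecture's search space
#' (seeded random search — the protocol, budget, and seed are recorded in
#' the result) and scores each by mean cross-validated balanced accuracy.
#' Among configurations within `tolerance` of the best balanced accuracy,
#' the one with the highest mean sensitivity is returned: the sensitivity
#' refit rule as a tie-break, since re-optimizing on sensitivity alone
#' would collapse to always-positive classifiers.
#'
#' @inheritParams cross_validate
#' @param n_repeats CV repeats per evaluated configuration (protocol
#'   default 10).
#' @param budget Maximum configurations evaluated (default 25).
#' @param tolerance Balanced-accuracy band treated as a tie (default 1e-6).
#' @return List with `hyperparameters`, `score` (mean balanced accuracy),
#'   `sensitivity`, `evaluations` (one row per configuration), and the
#'   search `protocol` record.
#' @export
optimize_hyperparameters <- function(features, labels, architecture,
                                     n_repeats = 10, k = 5, budget = 25,
                                     tolerance = 1e-6, seed = 1) {
  if (budget < 1) abort("search budget must be at least 1.")
  check_both_classes(labels, "hyperparameter search")
  arch <- get_architecture(architecture)
  space <- arch$space
  configs <- if (length(space) == 0) {
    list(arch$default)
  } else {
    grid_size <- prod(vapply(space, length, numeric(1)))
    if (grid_size <= budget) {
      all <- expand.grid(space, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(all)), function(i) as.list(all[i, , drop = FALSE]))
    } else {
      withr::with_seed(derive_seed(seed, "hpo-draw"), {
        seen <- character(0); out <- list()
        while (length(out) < budget) {
          cfg <- lapply(space, function(v) sample(v, 1))
          key <- paste(unlist(cfg), collapse = "|")
          if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1]] <- cfg }
        }
        out
      })
    }
  }
  evals <- purrr::imap(configs, function(cfg, i) {
    cv <- cross_validate(features, labels, architecture,
                         scheme = "stratified", k = k, repeats = n_repeats,
                         hyperparameters = cfg, seed = seed)
    tibble(config = i,
           balanced_accuracy = cv$summary$mean[cv$summary$metric == "balanced_accuracy"],
           sensitivity = cv$summary$mean[cv$summary$metric == "sensitivity"])
  })
  evals <- bind_rows(evals)
  best_ba <- max(evals$balanced_accuracy)
  near <- filter(evals, .data$balanced_accuracy >= best_ba - tolerance)
  pick <- arrange(near, desc(.data$sensitivity), .data$config)$config[1]
  list(
    hyperparameters = configs[[pick]],
    score = evals$balanced_accuracy[evals$config == pick],
    sensitivity = evals$sensitivity[evals$config == pick],
    evaluations = mutate(evals,
                         hyperparameters = purrr::map(.data$config, ~configs[[.x]])),
    protocol = list(search = "seeded random search", budget = budget,
                    k = k, repeats = n_repeats, tolerance = tolerance,
                    seed = seed)
  )
}

#' Oversample the minority class by whole-row replication
#'
#' The minority class is replicated an integer number of times (no synthetic
#' rows) so that its size divided by the majority size lands as close to
#' `target_ratio` as integer replication allows; the majority class is
#' untouched. Balanced input is returned unchanged.
#'
#' @param features `fluid_features` or matrix (rows replicated alongside
#'   labels).
#' @param labels Integer 0/1 labels.
#' @param target_ratio Desired minority/majority ratio (default 1).
#' @param seed Unused by the deterministic replication rule; kept so the
#'   operation slots into seeded pipelines.
#' @return List with `features` and `labels` after replication.
#' @export
oversample_minority <- function(features, labels, target_ratio = 1, seed = NULL) {
  labels <- check_both_classes(labels, "oversampling")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  lo <- max(1L, floor(target_ratio * n_maj / n_min))
  hi <- lo + 1L
  reps <- if (abs(lo * n_min / n_maj - target_ratio) <=
              abs(hi * n_min / n_maj - target_ratio)) lo else hi
  if (reps <= 1L) return(list(features = features, labels = labels))
  idx_min <- which(labels == minority)
  idx <- c(seq_along(labels), rep(idx_min, reps - 1L))
  feats <- if (inherits(features, "fluid_features")) features[idx] else features[idx, , drop = FALSE]
  list(features = feats, labels = labels[idx])
}

#' Train a partner ("teacher") classifier
#'
#' Fits the requested architecture on standardized, featurized, scaled data
#' and attaches the training-space reference (the training fingerprints)
#' that reliability scoring requires downstream.
#'
#' @param dataset List with `ids`, `labels`, `features` (see
#'   [model_dataset()]), or a `fluid_features` object when `labels` is
#'   given separately.
#' @param architecture Architecture name from [zoo_architectures()].
#' @param hyperparameters Optional list overriding defaults.
#' @param labels Labels when `dataset` is a bare feature container.
#' @param oversample `NULL` (off) or a target minority/majority ratio
#'   passed to [oversample_minority()] before fitting.
#' @param member_id Identifier stored with the model (used in prediction
#'   records).
#' @param seed Seed; training is deterministic given it.
#' @return A `fluid_model`.
#' @export
train_teacher <- function(dataset, architecture = "random_forest",
                          hyperparameters = NULL, labels = NULL,
                          oversample = NULL, member_id = "member01", seed = 1) {
  if (inherits(dataset, "fluid_features")) {
    dataset <- list(ids = dataset$id, labels = labels, features = dataset)
  }
  labels <- check_both_classes(dataset$labels)
  features <- dataset$features
  train_fp <- features$fingerprint
  if (nrow(train_fp) == 0) abort("training-space reference is empty.")
  fit_feats <- features; fit_labels <- labels
  if (!is.null(oversample)) {
    os <- oversample_minority(features, labels, target_ratio = oversample)
    fit_feats <- os$features; fit_labels <- os$labels
  }
  x <- features_matrix(fit_feats)
  fit <- fit_architecture(architecture, x, fit_labels, hyperparameters, seed = seed)
  structure(list(
    architecture = architecture,
    fit = fit,
    member_id = member_id,
    hyperparameters = fit$hyperparameters,
    train_fingerprints = train_fp,
    train_ids = dataset$ids,
    label_counts = c(n_neg = sum(labels == 0L), n_pos = sum(labels == 1L)),
    feature_config = features$config,
    oversample = oversample,
    seed = seed
  ), class = "fluid_model")
}

#' @export
print.fluid_model <- function(x, ...) {
  cat(sprintf("<fluid_model> %s (%s): %d train molecules (%d-/%d+), seed %d\n",
              x$architecture, x$member_id %||% x$variant %||% "model",
              nrow(x$train_fingerprints),
              x$label_counts["n_neg"], x$label_counts["n_pos"], x$seed))
  invisible(x)
}

#' Predicted probability of activity
#'
#' @param model A `fluid_model`.
#' @param features `fluid_features` or model-ready matrix, built under the
#'   same featurization configuration as the model's training data.
#' @return Numeric vector of P(active) in `[0, 1]`.
#' @export
predict_prob <- function(model, features) {
  stopifnot(inherits(model, "fluid_model"))
  if (inherits(features, "fluid_features")) {
    cfg_m <- model$feature_config$descriptor_hash %||% NA
    cfg_f <- features$config$descriptor_hash %||% NA
    if (!identical(cfg_m, cfg_f)) {
      abort("featurization configuration mismatch between model and query features.")
    }
    features <- features_matrix(features)
  }
  prob_architecture(model$fit, features)
}

#' Persist and restore a trained-model bundle
#'
#' The bundle carries the fitted model, its training-space reference,
#' hyperparameters, featurization-configuration hash, and the package
#' version that wrote it, so a restored model can refuse mismatched
#' feature spaces.
#'
#' @param model A `fluid_model`.
#' @param path Bundle file path (RDS).
#' @export
write_model_bundle <- function(model, path) {
  stopifnot(inherits(model, "fluid_model"))
  bundle <- list(format = "fluidsim-bundle-v1",
                 package_version = as.character(utils::packageVersion("fluidsim")),
                 model = model)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "fluidsim-bundle-v1")) {
    abort("not a recognized model bundle.")
  }
  bundle$model
}
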