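# Federated "student" training along two paths. The composition path
# defines a model purely by which data sources are unioned for training
# (teacher T, hybrid-internal HI, hybrid-federated HF, and the seven
# internal-comparison variants); the pretrain/fine-tune path pretrains a
# multilayer perceptron on public or federated data and optionally
# continues training on internal data (PI, RI, F, RF).

#' The frozen training-variant table
#'
#' Each named variant maps to an ordered data composition (tags among
#' `internal`, `public`, `federated`, `fluid_full`) and an optional
#' refinement source. `T`/`HI`/`HF` are the composition-path models,
#' `PI`/`RI`/`F`/`RF` the pretrain/fine-tune models, and the seven
#' remaining names the internal-comparison variants (internal data only;
#' federated labels from either label-producing engine with or without
#' internal data; the full pool pseudo-label sets).
#'
#' @return Tibble with `name`, `path`, `data_composition` (list column of
#'   source tags in deduplication priority order) and `refinement_source`.
#' @export
training_variants <- function() {
  tribble_ <- function(name, path, comp, refine) {
    tibble(name = name, path = path, data_composition = list(comp),
           refinement_source = refine)
  }
  bind_rows(
    tribble_("T",   "composition", "internal", NA_character_),
    tribble_("HI",  "composition", c("internal", "public"), NA_character_),
    tribble_("HF",  "composition", c("internal", "public", "federated"), NA_character_),
    tribble_("PI",  "finetune", "public", NA_character_),
    tribble_("RI",  "finetune", "public", "internal"),
    tribble_("F",   "finetune", "federated", NA_character_),
    tribble_("RF",  "finetune", "federated", "internal"),
    tribble_("internal_only",         "composition", "internal", NA_character_),
    tribble_("mlp_fed",               "composition", "federated", NA_character_),
    tribble_("mlp_fed_plus_internal", "composition", c("internal", "federated"), NA_character_),
    tribble_("mlp_fluid",             "composition", "fluid_full", NA_character_),
    tribble_("sohn_fed",              "composition", "federated", NA_character_),
    tribble_("sohn_fed_plus_internal","composition", c("internal", "federated"), NA_character_),
    tribble_("sohn_fluid",            "composition", "fluid_full", NA_character_)
  )
}

variant_row <- function(variant) {
  vt <- training_variants()
  if (!variant %in% vt$name) {
    abort(sprintf("unknown training variant '%s'; available: %s",
                  variant, paste(vt$name, collapse = ", ")))
  }
  vt[vt$name == variant, ]
}

#' Convert a federated set into a model-ready dataset
#' @param fedset A `fluid_federated_set`.
#' @param pool_features `fluid_features` covering the pool molecules.
#' @return List with `ids`, `labels` (the distilled consensus labels), and
#'   `features`.
#' @export
federated_dataset <- function(fedset, pool_features) {
  stopifnot(inherits(fedset, "fluid_federated_set"))
  list(ids = fedset$records$molecule_id,
       labels = as_binary_label(fedset$records$label),
       features = features_subset(pool_features, fedset$records$molecule_id))
}

# Union of datasets in priority order; molecule-id collisions keep the
# earliest (highest-priority) record, so experimental labels outrank
# distilled ones.
combine_datasets <- function(datasets) {
  datasets <- datasets[!vapply(datasets, is.null, logical(1))]
  stopifnot(length(datasets) >= 1)
  ids <- unlist(lapply(datasets, `[[`, "ids"))
  labels <- unlist(lapply(datasets, `[[`, "labels"))
  features <- do.call(features_rbind, lapply(datasets, `[[`, "features"))
  keep <- !duplicated(ids)
  list(ids = ids[keep], labels = labels[keep], features = features[keep])
}

#' Train a composition-path student model
#'
#' The model is defined by the union of data sources for its variant:
#' `T` trains on internal data only, `HI` on internal plus public, `HF` on
#' internal plus public plus the federated set. Duplicated molecules across
#' sources are deduplicated keeping the internal label (experimental beats
#' distilled). Any zoo architecture can serve as the base learner; the
#' path is defined by its data composition, not by a specific algorithm.
#'
#' @param internal,public,federated Model-ready datasets (lists with `ids`,
#'   `labels`, `features`; see [model_dataset()] and
#'   [federated_dataset()]). Sources a variant does not use may be `NULL`.
#' @param variant `"T"`, `"HI"`, `"HF"`, or one of the composition-path
#'   internal-comparison variants in [training_variants()].
#' @param base_architecture Zoo architecture (default `"random_forest"`).
#' @param hyperparameters Optional overrides for the base architecture.
#' @param fluid_full Dataset of every pool pseudo-label, for the
#'   `*_fluid` variants.
#' @param seed Seed.
#' @return A `fluid_model` whose training-space reference is the union of
#'   the composed sources' fingerprints.
#' @export
train_composition_path <- function(internal = NULL, public = NULL,
                                   federated = NULL, variant = "T",
                                   base_architecture = "random_forest",
                                   hyperparameters = NULL, fluid_full = NULL,
                                   seed = 1) {
  row <- variant_row(variant)
  if (row$path != "composition") {
    abort(sprintf("variant '%s' belongs to the fine-tune path; use train_finetune_path().", variant))
  }
  sources <- list(internal = internal, public = public,
                  federated = federated, fluid_full = fluid_full)
  comp <- row$data_composition[[1]]
  for (tag in comp) {
    if (is.null(sources[[tag]])) {
      abort(sprintf("variant '%s' requires the '%s' source, which is absent.", variant, tag))
    }
  }
  data <- combine_datasets(sources[comp])
  model <- train_teacher(data, architecture = base_architecture,
                         hyperparameters = hyperparameters,
                         member_id = variant, seed = seed)
  model$variant <- variant
  model$data_composition <- comp
  model
}

#' Train a pretrain/fine-tune-path student model
#'
#' A multilayer perceptron is pretrained on the variant's source (`PI`:
#' public data; `F`: the federated set) and, for `RI`/`RF`, refined by
#' continuing the optimization from the pretrained weights on internal
#' data with a reduced iteration budget. A refined model's training-space
#' reference is the union of the pretraining and refinement fingerprints.
#'
#' @param public,federated,internal Model-ready datasets; only the sources
#'   the variant uses are required.
#' @param variant One of `"PI"`, `"RI"`, `"F"`, `"RF"`.
#' @param size,decay,maxit Perceptron hyperparameters (hidden units, L2
#'   weight decay, pretraining iteration budget).
#' @param refine_maxit Iteration budget of the refinement continuation
#'   (default `ceiling(maxit / 2)`).
#' @param include_public For `F`/`RF`, prepend the public set to the
#'   federated pretraining data (default `FALSE`).
#' @param seed Seed; training is reproducible bit for bit given it.
#' @return A `fluid_model`.
#' @export
train_finetune_path <- function(public = NULL, federated = NULL,
                                internal = NULL, variant = "PI",
                                size = 16, decay = 1e-3, maxit = 200,
                                refine_maxit = NULL, include_public = FALSE,
                                seed = 1) {
  row <- variant_row(variant)
  if (row$path != "finetune") {
    abort(sprintf("variant '%s' belongs to the composition path; use train_composition_path().", variant))
  }
  pre_tag <- row$data_composition[[1]]
  pre <- switch(pre_tag, public = public, federated = federated)
  if (is.null(pre)) {
    abort(sprintf("variant '%s' requires the '%s' source, which is absent.", variant, pre_tag))
  }
  if (pre_tag == "federated" && include_public) {
    if (is.null(public)) abort("include_public = TRUE requires the public source.")
    pre <- combine_datasets(list(public, pre))
  }
  refine <- !is.na(row$refinement_source)
  if (refine && is.null(internal)) {
    abort(sprintf("variant '%s' requires the 'internal' refinement source, which is absent.", variant))
  }
  hp <- list(size = size, decay = decay, maxit = maxit)
  model <- train_teacher(pre, architecture = "mlp", hyperparameters = hp,
                         member_id = variant, seed = seed)
  if (refine) {
    check_both_classes(internal$labels, "refinement")
    wts <- model$fit$fit$wts
    hp_ref <- list(size = size, decay = decay,
                   maxit = refine_maxit %||% ceiling(maxit / 2), Wts = wts)
    refined <- train_teacher(internal, architecture = "mlp",
                             hyperparameters = hp_ref, member_id = variant,
                             seed = derive_seed(seed, "refine"))
    refined$train_fingerprints <- rbind(model$train_fingerprints,
                                        refined$train_fingerprints)
    refined$train_ids <- c(model$train_ids, refined$train_ids)
    refined$pretrained_on <- pre_tag
    model <- refined
  }
  model$variant <- variant
  model$data_composition <- row$data_composition[[1]]
  model$refinement_source <- row$refinement_source
  model
}
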