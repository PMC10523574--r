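# Student paths: the frozen variant table, composition unions with
# deduplication, and pretrain/fine-tune behaviour.

test_that("the variant table is frozen and exhaustive", {
  vt <- training_variants()
  expected <- list(
    T = "internal",
    HI = c("internal", "public"),
    HF = c("internal", "public", "federated"),
    PI = "public", RI = "public", F = "federated", RF = "federated",
    internal_only = "internal",
    mlp_fed = "federated",
    mlp_fed_plus_internal = c("internal", "federated"),
    mlp_fluid = "fluid_full",
    sohn_fed = "federated",
    sohn_fed_plus_internal = c("internal", "federated"),
    sohn_fluid = "fluid_full"
  )
  expect_setequal(vt$name, names(expected))
  for (nm in names(expected)) {
    expect_identical(vt$data_composition[vt$name == nm][[1]], expected[[nm]],
                     info = nm)
  }
  refine <- stats::setNames(vt$refinement_source, vt$name)
  expect_identical(unname(refine[c("RI", "RF")]), c("internal", "internal"))
  expect_true(all(is.na(refine[setdiff(vt$name, c("RI", "RF"))])))
})

test_that("composition unions deduplicate with internal label priority", {
  w <- tiny_world(seed = 51, n_pool = 200)
  internal <- model_dataset(w, w$partner_train[[1]])
  public <- model_dataset(w, w$public_set)
  # an HF over an empty federated set trains on exactly the HI data
  empty_fed <- list(ids = character(0), labels = integer(0),
                    features = internal$features[0])
  probe <- model_dataset(w, w$partner_test[[1]])$features
  hi <- train_composition_path(internal, public, variant = "HI", seed = 4)
  hf0 <- train_composition_path(internal, public, empty_fed, variant = "HF", seed = 4)
  expect_identical(predict_prob(hi, probe), predict_prob(hf0, probe))
  # duplicated molecule: the internal (experimental) label wins
  dup <- list(ids = internal$ids[1], labels = 1L - internal$labels[1],
              features = internal$features[1])
  combined <- fluidsim:::combine_datasets(list(internal, dup))
  expect_identical(length(combined$ids), length(internal$ids))
  expect_identical(combined$labels[1], internal$labels[1])
  # union bookkeeping: |HF| = |internal| + |public| + |federated| - dups
  overlap <- list(ids = c(public$ids[1:5], paste0("new", 1:3)),
                  labels = rep(1L, 8),
                  features = public$features[c(1:5, 6:8)])
  u <- fluidsim:::combine_datasets(list(internal, public, overlap))
  expect_identical(length(u$ids),
                   length(internal$ids) + length(public$ids) + 8L - 5L)
})

test_that("HF's training-space reference strictly contains HI's", {
  w <- tiny_world(seed = 52, n_pool = 400)
  internal <- model_dataset(w, w$partner_train[[1]])
  public <- model_dataset(w, w$public_set)
  teacher <- train_teacher(internal, member_id = "partner01", seed = 1)
  pf <- world_features(w, w$pool)
  fs <- suppressWarnings(build_federated_set(consolidate(predict_pool(teacher, pf)),
                                             n_per_class = 50))
  fed <- federated_dataset(fs, pf)
  hi <- train_composition_path(internal, public, variant = "HI", seed = 2)
  hf <- train_composition_path(internal, public, fed, variant = "HF", seed = 2)
  expect_true(all(hi$train_ids %in% hf$train_ids))
  expect_gt(length(hf$train_ids), length(hi$train_ids))
})

test_that("missing sources are reported by name", {
  w <- tiny_world(seed = 53, n_pool = 60)
  internal <- model_dataset(w, w$partner_train[[1]])
  expect_error(train_composition_path(internal, variant = "HI"), "'public'")
  expect_error(train_composition_path(variant = "T"), "'internal'")
  expect_error(train_finetune_path(variant = "F"), "'federated'")
  expect_error(train_finetune_path(public = internal, variant = "RI"), "refinement")
  expect_error(train_composition_path(internal, variant = "PI"), "fine-tune")
})

test_that("refinement on the pretraining data is a near no-op after convergence", {
  w <- tiny_world(seed = 54, n_train_per_partner = 250, n_public = 180, n_pool = 60)
  pub <- model_dataset(w, w$public_set)
  probe <- model_dataset(w, w$partner_test[[1]])$features
  pi <- train_finetune_path(public = pub, variant = "PI", size = 6,
                            maxit = 5000, seed = 5)
  expect_identical(pi$fit$fit$convergence, 0L)
  ri <- train_finetune_path(public = pub, internal = pub, variant = "RI",
                            size = 6, maxit = 5000, seed = 5)
  expect_lt(max(abs(predict_prob(pi, probe) - predict_prob(ri, probe))), 1e-3)
})

test_that("fine-tuned models are reproducible and carry the union reference", {
  w <- tiny_world(seed = 55, n_pool = 300)
  internal <- model_dataset(w, w$partner_train[[1]])
  teacher <- train_teacher(internal, member_id = "partner01", seed = 1)
  pf <- world_features(w, w$pool)
  fs <- suppressWarnings(build_federated_set(consolidate(predict_pool(teacher, pf)),
                                             n_per_class = 60))
  fed <- federated_dataset(fs, pf)
  probe <- model_dataset(w, w$partner_test[[1]])$features
  rf1 <- train_finetune_path(federated = fed, internal = internal,
                             variant = "RF", size = 8, maxit = 80, seed = 9)
  rf2 <- train_finetune_path(federated = fed, internal = internal,
                             variant = "RF", size = 8, maxit = 80, seed = 9)
  expect_identical(predict_prob(rf1, probe), predict_prob(rf2, probe))
  expect_identical(nrow(rf1$train_fingerprints),
                   length(fed$ids) + length(internal$ids))
  # refusal on a single-class refinement set
  single <- list(ids = internal$ids, labels = rep(1L, length(internal$ids)),
                 features = internal$features)
  expect_error(train_finetune_path(federated = fed, internal = single,
                                   variant = "RF", size = 8, maxit = 40), "single class")
})

test_that("internal refinement helps when internal and pool distributions differ", {
  # refined-federated vs federated-only on an internal-distributed test set
  # (no temporal drift: the contrast under test is internal vs pool space),
  # averaged over seeds
  deltas <- vapply(1:5, function(s) {
    w <- tiny_world(seed = 600 + s, n_train_per_partner = 400,
                    n_test_per_partner = 400, n_pool = 1500,
                    temporal_drift = 0)
    internal <- model_dataset(w, w$partner_train[[1]])
    teachers <- lapply(names(w$partner_train), function(p)
      train_teacher(model_dataset(w, w$partner_train[[p]]), member_id = p, seed = s))
    pf <- world_features(w, w$pool)
    preds <- lapply(teachers, predict_pool, pool_features = pf)
    fs <- suppressWarnings(build_federated_set(consolidate(preds), n_per_class = 150))
    fed <- federated_dataset(fs, pf)
    test <- model_dataset(w, w$partner_test[[1]])
    f <- train_finetune_path(federated = fed, variant = "F", size = 8, seed = s)
    rf <- train_finetune_path(federated = fed, internal = internal,
                              variant = "RF", size = 8, seed = s)
    evaluate_model(rf, test)$balanced_accuracy -
      evaluate_model(f, test)$balanced_accuracy
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})
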