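# Synthetic multi-partner world generator.

test_that("activity labelling thresholds at the boundary inclusively", {
  expect_identical(label_activity(50), 1L)
  expect_identical(label_activity(49.99), 0L)
  expect_identical(label_activity(-5), 0L)
  expect_identical(label_activity(c(100, 0, 50, 49.999)), c(1L, 0L, 1L, 0L))
  expect_identical(label_activity(30, threshold = 30), 1L)
})

test_that("temporal split partitions on the cutoff year", {
  rec <- tibble::tibble(id = as.character(1:4), assay_year = c(2018, 2019, 2020, 2021))
  sp <- temporal_split(rec, cutoff_year = 2020)
  expect_identical(nrow(sp$train), 2L)
  expect_identical(nrow(sp$test), 2L)
  expect_true(all(sp$test$assay_year >= 2020))
  # degenerate side yields a metadata warning, not a failure
  sp2 <- temporal_split(tibble::tibble(id = "a", assay_year = 2021))
  expect_identical(nrow(sp2$train), 0L)
  expect_match(attr(sp2, "split_warning"), "training")
  # partition property on random inputs
  withr::with_seed(9, {
    for (i in 1:10) {
      r <- tibble::tibble(id = as.character(1:50),
                          assay_year = sample(2015:2023, 50, TRUE))
      s <- temporal_split(r)
      expect_identical(nrow(s$train) + nrow(s$test), nrow(r))
      expect_length(intersect(s$train$id, s$test$id), 0)
    }
  })
})

test_that("same config and seed reproduce the world exactly", {
  w1 <- tiny_world(seed = 5)
  w2 <- tiny_world(seed = 5)
  expect_identical(w1$partner_train, w2$partner_train)
  expect_identical(w1$public_set, w2$public_set)
  expect_identical(w1$features$fingerprint, w2$features$fingerprint)
  w3 <- tiny_world(seed = 6)
  expect_false(identical(w1$partner_train, w3$partner_train))
})

test_that("realized imbalance tracks the requested ratio", {
  # ratio 1 at n = 10,000: binomial fluctuation keeps the realized ratio
  # within [0.9, 1.1]
  w <- generate_world(world_config(n_partners = 1, n_train_per_partner = 10000,
                                   n_test_per_partner = 500, n_public = 500,
                                   n_pool = 100, inactive_active_ratio = 1,
                                   seed = 21))
  r <- class_ratio(w$partner_train[[1]])
  expect_gt(r, 0.9); expect_lt(r, 1.1)
  # requested-vs-realized within 10 % for n >= 500 across other ratios
  for (req in c(2, 5)) {
    w2 <- generate_world(world_config(n_partners = 1, n_train_per_partner = 2000,
                                      n_test_per_partner = 500, n_public = 500,
                                      n_pool = 100, inactive_active_ratio = req,
                                      seed = 22))
    expect_lt(abs(class_ratio(w2$partner_train[[1]]) - req) / req, 0.1)
  }
})

test_that("unattainable ratios fail naming the dataset", {
  expect_error(
    generate_world(world_config(n_partners = 1, n_train_per_partner = 300,
                                n_test_per_partner = 100, n_public = 8,
                                n_pool = 50, inactive_active_ratio = 14,
                                seed = 1)),
    "public")
})

test_that("pool labels are hidden behind the oracle accessor", {
  w <- tiny_world(seed = 2)
  expect_true(all(is.na(w$pool$label)))
  truth <- pool_ground_truth(w)
  expect_identical(sort(truth$id), sort(w$pool$id))
  expect_true(all(truth$label %in% c(0L, 1L)))
})

test_that("partner, public, and pool sets are disjoint and temporally coherent", {
  w <- tiny_world(seed = 8)
  all_ids <- c(unlist(lapply(w$partner_train, `[[`, "id")),
               unlist(lapply(w$partner_test, `[[`, "id")),
               w$public_set$id, w$pool$id)
  expect_identical(anyDuplicated(all_ids), 0L)
  cutoff <- w$config$temporal_cutoff_year
  for (p in names(w$partner_train)) {
    expect_true(all(w$partner_train[[p]]$assay_year < cutoff))
    expect_true(all(w$partner_test[[p]]$assay_year >= cutoff))
  }
})

test_that("full overlap makes partner training sets distributionally identical", {
  # with overlap 1 both partners sample one cluster mixture: chi-squared
  # two-sample tests on cluster draws should reject only at the nominal rate
  pvals <- vapply(1:30, function(s) {
    w <- generate_world(world_config(n_partners = 2, n_train_per_partner = 300,
                                     n_test_per_partner = 50, n_public = 50,
                                     n_pool = 50, partner_cluster_overlap = 1,
                                     seed = 100 + s))
    lv <- seq_len(w$config$n_clusters)
    t1 <- table(factor(w$partner_train[[1]]$cluster, levels = lv))
    t2 <- table(factor(w$partner_train[[2]]$cluster, levels = lv))
    suppressWarnings(stats::chisq.test(rbind(t1, t2))$p.value)
  }, numeric(1))
  expect_lt(mean(pvals < 0.01), 0.15)
})

test_that("grammar-assembled SMILES are valid and flow through featurization", {
  w <- tiny_world(seed = 4, n_train_per_partner = 30, n_test_per_partner = 10,
                  n_public = 10, n_pool = 10, mode = "smiles")
  smi <- w$partner_train[[1]]$smiles
  expect_true(all(nzchar(smi)))
  std <- standardize_smiles(smi)
  expect_true(all(nzchar(std)))
  f <- featurize(tibble::tibble(id = w$partner_train[[1]]$id[1:10], smiles = std[1:10]))
  expect_identical(length(f$id), 10L)
})

test_that("a strong learner recovers the generative signal near the Bayes rate", {
  # large low-noise in-distribution world: accuracy >= 1 - noise - 0.05
  accs <- vapply(1:5, function(s) {
    w <- generate_world(world_config(n_partners = 1, n_train_per_partner = 5000,
                                     n_test_per_partner = 800, n_public = 100,
                                     n_pool = 100, label_noise = 0.05,
                                     temporal_drift = 0, seed = 300 + s))
    m <- train_teacher(model_dataset(w, w$partner_train[[1]]), seed = s)
    te <- model_dataset(w, w$partner_test[[1]])
    mean(as.integer(predict_prob(m, te$features) >= 0.5) == te$labels)
  }, numeric(1))
  expect_gte(mean(accs), 1 - 0.05 - 0.05)
})
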