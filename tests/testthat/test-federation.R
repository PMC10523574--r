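# Pool prediction, consolidation, and federated-set construction.

test_that("pool prediction is a bijection over pool molecules", {
  w <- tiny_world(seed = 41, n_pool = 150)
  teacher <- train_teacher(model_dataset(w, w$partner_train[[1]]),
                           member_id = "partner01", seed = 1)
  pf <- world_features(w, w$pool)
  pr <- predict_pool(teacher, pf)
  expect_identical(nrow(pr), 150L)
  expect_setequal(pr$molecule_id, w$pool$id)
  expect_true(all(pr$predicted_label == as.integer(pr$probability >= 0.5)))
  expect_equal(pr$decidability, abs(2 * pr$probability - 1))
  # empty pool -> empty record set
  expect_identical(nrow(predict_pool(teacher, pf[0])), 0L)
  # a pool molecule identical to a training molecule has reliability 1
  f2 <- pf
  f2$fingerprint[1, ] <- teacher$train_fingerprints[1, ]
  expect_identical(predict_pool(teacher, f2, k = 1)$reliability[1], 1)
  # featurization-config mismatch is an error
  alien <- pf; alien$config$descriptor_hash <- "other"
  expect_error(predict_pool(teacher, alien), "mismatch")
})

test_that("single-member consolidation is the identity", {
  preds <- random_predictions(50, seed = 3)
  cons <- consolidate(preds)
  cons <- cons[match(preds$molecule_id, cons$molecule_id), ]
  expect_identical(cons$consensus_label, preds$predicted_label)
  expect_equal(cons$consensus_decidability, preds$decidability)
  expect_equal(cons$consensus_reliability, preds$reliability)
  expect_true(all(cons$n_members == 1L))
  expect_true(all(cons$member_agreement == 1))
})

test_that("consolidation takes decidability-weighted majority votes", {
  mk <- function(member, label, p, rel = 0.5) {
    tibble::tibble(molecule_id = "m1", member_id = member,
                   predicted_label = label, probability = p,
                   decidability = abs(2 * p - 1), reliability = rel)
  }
  # unanimous: label kept, decidability averaged (0.2, 0.4, 0.6 -> 0.4)
  un <- consolidate(list(mk("a", 1L, 0.6), mk("b", 1L, 0.7), mk("c", 1L, 0.8)))
  expect_identical(un$consensus_label, 1L)
  expect_equal(un$consensus_decidability, 0.4)
  expect_equal(un$member_agreement, 1)
  # split vote: weight 0.9 for label 1 beats 0.3 for label 0
  sp <- consolidate(list(mk("a", 1L, 0.95), mk("b", 0L, 0.35)))
  expect_identical(sp$consensus_label, 1L)
  expect_equal(sp$member_agreement, 0.5)
  # oracle: enumerating both outcomes confirms the weighted vote
  w1 <- 0.9; w0 <- 0.3
  expect_identical(sp$consensus_label, as.integer(w1 > w0))
  # exact weight tie resolves to inactive (0.75/0.25 give decidability
  # exactly 0.5 in binary floating point)
  tie <- consolidate(list(mk("a", 1L, 0.75), mk("b", 0L, 0.25)))
  expect_identical(tie$consensus_label, 0L)
  # fully equivocal members fall back to unweighted majority (identity for
  # a single member predicting at exactly 0.5)
  eq <- consolidate(mk("a", 1L, 0.5))
  expect_identical(eq$consensus_label, 1L)
})

test_that("consolidation is invariant to member order and strict about id sets", {
  a <- random_predictions(40, seed = 5)
  b <- dplyr::mutate(random_predictions(40, seed = 6), member_id = "mB")
  c1 <- dplyr::mutate(random_predictions(40, seed = 7), member_id = "mC")
  expect_identical(consolidate(list(a, b, c1)), consolidate(list(c1, a, b)))
  b_short <- b[-(1:2), ]
  expect_error(consolidate(list(a, b_short)), "different molecule sets")
})

test_that("federated-set construction filters, ranks, and fills per class", {
  cons <- synthesize_consolidated(50, 400, seed = 2)
  fs <- build_federated_set(cons, n_per_class = 100, reliability_min = 0.005)
  expect_identical(fs$n_pos, 50L)
  expect_identical(fs$n_neg, 150L)       # shortfall of 50 filled by negatives
  expect_identical(nrow(fs$records), 200L)
  # every record passed the filter; per-class decidability optimality
  expect_true(all(fs$records$reliability >= 0.005))
  for (lab in c(0L, 1L)) {
    inc <- fs$records[fs$records$label == lab, ]
    exc <- dplyr::anti_join(cons[cons$consensus_label == lab, ],
                            inc, by = c(molecule_id = "molecule_id"))
    if (nrow(exc) > 0 && nrow(inc) > 0) {
      expect_gte(min(inc$decidability), max(exc$consensus_decidability))
    }
  }
})

test_that("degenerate federated sets warn instead of failing", {
  cons <- synthesize_consolidated(5, 5, seed = 3)
  cons$consensus_reliability <- 0.0001
  expect_warning(fs <- build_federated_set(cons, n_per_class = 10), "empty")
  expect_identical(nrow(fs$records), 0L)
  # both classes exhausted below target: everything eligible + warning
  cons2 <- synthesize_consolidated(4, 6, seed = 4)
  expect_warning(fs2 <- build_federated_set(cons2, n_per_class = 10), "short by")
  expect_identical(nrow(fs2$records), 10L)
  g <- glance(fs2)
  expect_identical(g$shortfall, 10)
})

test_that("ranking ties break by reliability then molecule id", {
  cons <- tibble::tibble(
    molecule_id = c("m3", "m1", "m2", "m4", "p1", "p2", "p3"),
    consensus_label = c(0L, 0L, 0L, 0L, 1L, 1L, 1L),
    consensus_decidability = c(0.8, 0.8, 0.8, 0.9, 0.99, 0.98, 0.97),
    consensus_reliability = c(0.5, 0.5, 0.9, 0.1, 0.5, 0.5, 0.5),
    n_members = 1L, member_agreement = 1
  )
  fs <- build_federated_set(cons, n_per_class = 3, reliability_min = 0)
  expect_identical(fs$records$molecule_id[fs$records$label == 0L],
                   c("m4", "m2", "m1"))
})

test_that("fill-rule conservation and optimality match a brute-force selector", {
  withr::with_seed(77, {
    for (i in 1:60) {
      npos <- sample(0:60, 1); nneg <- sample(0:60, 1)
      if (npos + nneg == 0) next
      n <- npos + nneg
      cons <- tibble::tibble(
        molecule_id = sprintf("x%03d", sample(n)),
        consensus_label = c(rep(1L, npos), rep(0L, nneg)),
        consensus_decidability = round(runif(n), 3),
        consensus_reliability = round(runif(n), 3),
        n_members = 2L, member_agreement = 1
      )
      target <- sample(1:40, 1); rmin <- runif(1, 0, 0.6)
      fs <- suppressWarnings(build_federated_set(cons, target, rmin))
      oracle <- oracle_federated(cons, target, rmin)
      expect_identical(fs$n_pos, as.integer(oracle$n_pos))
      expect_identical(fs$n_neg, as.integer(oracle$n_neg))
      expect_setequal(fs$records$molecule_id, oracle$ids)
      # conservation: donor class rich enough -> exactly 2N records
      eligible <- cons[cons$consensus_reliability >= rmin, ]
      if (sum(eligible$consensus_label == 1L) >= target &&
          sum(eligible$consensus_label == 0L) >= target) {
        expect_identical(nrow(fs$records), 2L * as.integer(target))
      }
    }
  })
})
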