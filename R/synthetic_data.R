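# Synthetic multi-partner world generator. Emulates the statistical
# structure of the study: partner-private labeled sets drawn from
# cluster-structured chemical space, a temporal train/test split, a public
# labeled set, and a large unlabeled pool whose ground-truth labels are
# hidden behind an explicit oracle accessor.

#' Configuration of a synthetic multi-partner world
#'
#' Defaults give the desk-scale world used throughout the package: 3
#' partners with 2,000 training molecules each, a 20,000-molecule unlabeled
#' pool, and a 500+500 federated-set target — a 1:20 scale-down of the
#' study-scale numbers (5 partners-plus at thousands of molecules, a
#' >300,000 pool, 10,000 per class). See the methods vignette for the
#' rationale behind each default.
#'
#' @param n_partners Number of consortium partners.
#' @param n_train_per_partner,n_test_per_partner Per-partner labeled set
#'   sizes (test molecules carry assay years at or after the cutoff).
#' @param n_public Size of the shared public labeled set.
#' @param n_pool Size of the unlabeled pool.
#' @param inactive_active_ratio Requested inactive/active ratio. Either a
#'   single number applied to every dataset or a named list with entries
#'   among `train`, `test`, `public`, `pool`.
#' @param n_clusters Total number of Gaussian chemical-space modes
#'   ("series"). Clusters are partitioned by role: the first
#'   `n_clusters - n_public_clusters - n_pool_clusters` are partner-owned
#'   (assigned round-robin), the next `n_public_clusters` generate the
#'   public labeled set, and the last `n_pool_clusters` occur only in the
#'   unlabeled pool; the pool itself spans every cluster, mirroring broad
#'   public chemistry that touches each partner's series as well as space
#'   no labeled set covers.
#' @param n_public_clusters,n_pool_clusters Cluster counts for the public
#'   set and the pool-only space (defaults 2 and 2).
#' @param partner_cluster_overlap In `[0, 1]`: 1 makes every partner sample
#'   the global cluster mixture; 0 gives each partner its private clusters.
#' @param label_noise Symmetric label-flip probability, emulating assay
#'   variability.
#' @param activity_threshold Percent response at or above which a molecule
#'   is active (default 50, the >=50 % at 10 uM convention).
#' @param temporal_cutoff_year Assay-year cutoff separating train from test
#'   (default 2020).
#' @param temporal_drift In `[0, 1]`: how far each partner's post-cutoff
#'   test mixture drifts from its own cluster preferences toward the global
#'   cluster mixture, emulating the expanded chemical space of more recent
#'   molecules (default 0.5; 0 = test drawn exactly like training).
#' @param partner_threshold_jitter Per-partner jitter (in latent score SD
#'   units) of the activity calibration, emulating assay-condition
#'   differences between companies; default 0 (off).
#' @param latent_dim Dimension of the latent coordinate emitted as the
#'   descriptor block in abstract mode.
#' @param n_bits Fingerprint length in abstract mode.
#' @param mode `"abstract"` emits feature-vector molecules directly (no
#'   chemistry toolkit involved); `"smiles"` assembles concrete SMILES from
#'   a small fragment grammar for end-to-end runs through [featurize()].
#' @param seed Integer seed; the whole world is reproducible from it.
#' @return A `world_config` list.
#' @export
world_config <- function(n_partners = 3,
                         n_train_per_partner = 2000,
                         n_test_per_partner = 800,
                         n_public = 1000,
                         n_pool = 20000,
                         inactive_active_ratio = 2,
                         n_clusters = 10,
                         n_public_clusters = 2,
                         n_pool_clusters = 2,
                         partner_cluster_overlap = 0,
                         label_noise = 0.05,
                         activity_threshold = 50,
                         temporal_cutoff_year = 2020,
                         temporal_drift = 0.5,
                         partner_threshold_jitter = 0,
                         latent_dim = 6,
                         n_bits = 256,
                         mode = c("abstract", "smiles"),
                         seed = 1) {
  mode <- match.arg(mode)
  counts <- c(n_partners, n_train_per_partner, n_test_per_partner, n_public, n_pool)
  if (any(counts < 0)) abort("all world counts must be non-negative.")
  if (partner_cluster_overlap < 0 || partner_cluster_overlap > 1) {
    abort("partner_cluster_overlap must be in [0, 1].")
  }
  if (label_noise < 0 || label_noise > 1) abort("label_noise must be in [0, 1].")
  if (label_noise >= 0.5) abort("label_noise must be below 0.5 for labels to carry signal.")
  if (n_public_clusters + n_pool_clusters >= n_clusters) {
    abort("n_clusters must exceed n_public_clusters + n_pool_clusters (partners need clusters).")
  }
  if (temporal_drift < 0 || temporal_drift > 1) abort("temporal_drift must be in [0, 1].")
  structure(list(
    n_partners = n_partners,
    n_train_per_partner = n_train_per_partner,
    n_test_per_partner = n_test_per_partner,
    n_public = n_public,
    n_pool = n_pool,
    inactive_active_ratio = inactive_active_ratio,
    n_clusters = n_clusters,
    n_public_clusters = n_public_clusters,
    n_pool_clusters = n_pool_clusters,
    partner_cluster_overlap = partner_cluster_overlap,
    label_noise = label_noise,
    activity_threshold = activity_threshold,
    temporal_cutoff_year = temporal_cutoff_year,
    temporal_drift = temporal_drift,
    partner_threshold_jitter = partner_threshold_jitter,
    latent_dim = latent_dim,
    n_bits = n_bits,
    mode = mode,
    seed = as.integer(seed)
  ), class = "world_config")
}

ratio_for <- function(config, kind) {
  r <- config$inactive_active_ratio
  if (is.list(r)) r <- r[[kind]] %||% 2
  as.numeric(r)
}

#' Binary activity label from a percent response
#'
#' Active (1) if and only if the percent binding/inhibition is greater than
#' or equal to the threshold; the boundary value itself is active.
#'
#' @param response_percent Numeric percent response.
#' @param threshold Activity threshold in percent (default 50).
#' @return Integer vector of 0/1 labels.
#' @export
label_activity <- function(response_percent, threshold = 50) {
  as.integer(response_percent >= threshold)
}

#' Temporal train/test split on assay year
#'
#' Molecules assayed at or after the cutoff year form the test set;
#' everything earlier is training. The two parts partition the input.
#' An empty side is not an error: a warning is recorded in the result's
#' metadata (attribute `"split_warning"`) so callers can surface it.
#'
#' @param records Data frame of molecule records with an `assay_year` column.
#' @param cutoff_year Cutoff calendar year (default 2020).
#' @return List with tibbles `train` and `test`.
#' @export
temporal_split <- function(records, cutoff_year = 2020) {
  stopifnot(is.data.frame(records), "assay_year" %in% names(records))
  if (anyNA(records$assay_year)) abort("all records must carry assay_year.")
  test <- filter(records, .data$assay_year >= cutoff_year)
  train <- filter(records, .data$assay_year < cutoff_year)
  out <- list(train = as_tibble(train), test = as_tibble(test))
  msg <- NULL
  if (nrow(train) == 0) msg <- c(msg, "temporal split produced an empty training set")
  if (nrow(test) == 0) msg <- c(msg, "temporal split produced an empty test set")
  attr(out, "split_warning") <- msg
  out
}

# SMILES fragment grammar: one ring template per cluster (recycled) with a
# substituent slot filled by 1-2 chainable units. Every emitted string is a
# valid SMILES; clusters differ in template and unit preferences.
GRAMMAR_TEMPLATES <- c(
  "c1ccc(%s)cc1", "C1CCC(%s)CC1", "c1ccnc(%s)c1",
  "C1CCOC(%s)C1", "c1csc(%s)c1", "C1CCNC(%s)C1"
)
GRAMMAR_UNITS <- c("C", "CC", "CCC", "CO", "CCO", "CN", "C(C)C",
                   "C(=O)O", "C(=O)N", "CCl", "CF", "COC", "CNC")

grammar_smiles <- function(cluster, n_clusters) {
  tmpl <- GRAMMAR_TEMPLATES[(cluster - 1L) %% length(GRAMMAR_TEMPLATES) + 1L]
  # cluster-biased unit distribution: each cluster prefers a sliding window
  w <- rep(1, length(GRAMMAR_UNITS))
  pref <- ((cluster - 1L) * 3L + seq_len(5L) - 1L) %% length(GRAMMAR_UNITS) + 1L
  w[pref] <- 6
  k <- sample(1:2, 1)
  units <- sample(GRAMMAR_UNITS, k, replace = TRUE, prob = w)
  sprintf(tmpl, paste(units, collapse = ""))
}

sample_dataset <- function(n, cluster_weights, ratio, years, world, name,
                           id_prefix, calibration_shift = 0) {
  cfg <- world$config
  # each dataset draws from its own named RNG stream so that adding or
  # removing one dataset (e.g. a partner) leaves every other dataset's
  # records bit-identical under the same world seed
  withr::local_seed(derive_seed(cfg$seed, paste0("dataset-", name)))
  e <- cfg$label_noise
  p_active <- (1 / (1 + ratio) - e) / (1 - 2 * e)
  if (p_active <= 0 || p_active >= 1) {
    abort(sprintf("dataset '%s': requested inactive/active ratio %.3g is unattainable at label noise %.3g.",
                  name, ratio, e))
  }
  if (n == 0) {
    empty <- tibble(id = character(0), smiles = character(0), label = integer(0),
                    assay_year = integer(0), partner_id = character(0),
                    target_id = character(0), cluster = integer(0))
    phys <- matrix(numeric(0), 0, cfg$latent_dim,
                   dimnames = list(NULL, paste0("L", seq_len(cfg$latent_dim))))
    return(list(records = empty,
                features = new_features(phys, matrix(0L, 0, cfg$n_bits), character(0),
                                        config = list(n_bits = cfg$n_bits,
                                                      descriptor_hash = "abstract-latent-v1",
                                                      mode = "abstract"))))
  }
  if (n * p_active < 1) {
    abort(sprintf("dataset '%s': fewer than one active molecule expected (n = %d, ratio = %.3g).",
                  name, n, ratio))
  }
  cl <- sample(cfg$n_clusters, n, replace = TRUE, prob = cluster_weights)
  z <- world$latent$centers[cl, , drop = FALSE] +
    matrix(rnorm(n * cfg$latent_dim, sd = world$latent$cluster_sd), n)
  s <- as.vector(z %*% world$latent$direction) + world$latent$offsets[cl]
  cut <- quantile(s, 1 - p_active, names = FALSE) +
    calibration_shift * stats::sd(s)
  response <- 100 * plogis((s - cut) / world$latent$response_scale)
  lab <- label_activity(response, cfg$activity_threshold)
  flip <- rbinom(n, 1, e) == 1
  lab[flip] <- 1L - lab[flip]
  ids <- sprintf("%s_%05d", id_prefix, seq_len(n))
  records <- tibble(
    id = ids,
    smiles = NA_character_,
    label = lab,
    assay_year = sample(years, n, replace = TRUE),
    partner_id = NA_character_,
    target_id = "synthetic",
    cluster = cl
  )
  if (cfg$mode == "smiles") {
    records$smiles <- vapply(cl, grammar_smiles, character(1), cfg$n_clusters)
  }
  # descriptor observation noise kept well below the cluster spread (0.6)
  # so the label-noise floor, not feature noise, bounds recoverable accuracy
  phys <- z + matrix(rnorm(n * cfg$latent_dim, sd = 0.1), n)
  colnames(phys) <- paste0("L", seq_len(cfg$latent_dim))
  proto <- world$latent$fp_prob[cl, , drop = FALSE]
  fp <- matrix(rbinom(length(proto), 1, as.vector(proto)), nrow = n)
  list(records = records,
       features = new_features(phys, fp, ids,
                               config = list(n_bits = cfg$n_bits,
                                             descriptor_hash = "abstract-latent-v1",
                                             mode = "abstract")))
}

#' Generate a synthetic multi-partner world
#'
#' Molecules are drawn from Gaussian modes in a latent coordinate; each
#' partner samples clusters according to `partner_cluster_overlap`. A
#' smooth logistic activity function of a random linear projection of the
#' latent coordinate, plus per-cluster offsets, yields a continuous percent
#' response that [label_activity()] thresholds into labels; symmetric label
#' flips emulate assay noise. Each dataset's activity calibration is set so
#' the realized inactive/active ratio matches the request in expectation.
#' The generator always emits abstract feature vectors (descriptors = noisy
#' latent coordinates, fingerprints = cluster-prototype bits); in
#' `mode = "smiles"` it additionally assembles concrete SMILES from a small
#' fragment grammar so the chemistry pipeline can be exercised end-to-end.
#'
#' @param config A [world_config()].
#' @return A `fluid_world`: per-partner `partner_train`/`partner_test`
#'   record tibbles, `public_set`, unlabeled `pool` (labels accessible only
#'   through [pool_ground_truth()]), a `fluid_features` container covering
#'   every molecule, and generator metadata.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  latent_and_jitter <- withr::with_seed(derive_seed(config$seed, "latent"), {
    latent <- list(
      centers = matrix(rnorm(config$n_clusters * config$latent_dim, sd = 1.8),
                       config$n_clusters),
      cluster_sd = 0.6,
      direction = {
        w <- rnorm(config$latent_dim); w / sqrt(sum(w^2))
      },
      offsets = rnorm(config$n_clusters, sd = 1.2),
      response_scale = 0.75,
      fp_prob = {
        p <- matrix(0.03, config$n_clusters, config$n_bits)
        for (k in seq_len(config$n_clusters)) {
          on <- runif(config$n_bits) < 0.15
          p[k, on] <- 0.85
        }
        p
      }
    )
    jit <- if (config$partner_threshold_jitter > 0) {
      rnorm(config$n_partners, sd = config$partner_threshold_jitter)
    } else rep(0, config$n_partners)
    list(latent = latent, jit = jit)
  })
  latent <- latent_and_jitter$latent
  jit <- latent_and_jitter$jit
  world <- list(config = config, latent = latent)
  alpha <- config$partner_cluster_overlap
  k <- config$n_clusters
  n_partner_cl <- k - config$n_public_clusters - config$n_pool_clusters
  partner_cl <- seq_len(n_partner_cl)
  public_cl <- n_partner_cl + seq_len(config$n_public_clusters)
  pool_cl <- n_partner_cl + config$n_public_clusters + seq_len(config$n_pool_clusters)
  uniform <- rep(1 / k, k)
  as_weights <- function(idx) {
    w <- rep(0, k); w[idx] <- 1 / length(idx); w
  }
  public_weights <- as_weights(public_cl)
  # the pool emulates broad public chemistry: it spans every cluster —
  # each partner's series (where that partner's teacher is confident),
  # the public clusters, and pool-only space no labeled set covers
  pool_weights <- uniform
  partner_pref <- lapply(seq_len(config$n_partners), function(p) {
    own <- partner_cl[(partner_cl - 1L) %% config$n_partners + 1L == p]
    if (length(own) == 0) own <- partner_cl
    as_weights(own)
  })
  {
    years_train <- seq(config$temporal_cutoff_year - 5, config$temporal_cutoff_year - 1)
    years_test <- seq(config$temporal_cutoff_year, config$temporal_cutoff_year + 3)
    years_any <- c(years_train, years_test)

    partner_train <- list(); partner_test <- list(); feats <- list()
    for (p in seq_len(config$n_partners)) {
      wts <- alpha * uniform + (1 - alpha) * partner_pref[[p]]
      pid <- sprintf("partner%02d", p)
      tr <- sample_dataset(config$n_train_per_partner, wts, ratio_for(config, "train"),
                           years_train, world, paste0(pid, "/train"),
                           paste0("P", p, "train"), jit[p])
      test_wts <- (1 - config$temporal_drift) * wts + config$temporal_drift * uniform
      te <- sample_dataset(config$n_test_per_partner, test_wts, ratio_for(config, "test"),
                           years_test, world, paste0(pid, "/test"),
                           paste0("P", p, "test"), jit[p])
      tr$records$partner_id <- pid
      te$records$partner_id <- pid
      partner_train[[pid]] <- tr$records
      partner_test[[pid]] <- te$records
      feats <- c(feats, list(tr$features, te$features))
    }
    pub <- sample_dataset(config$n_public, public_weights, ratio_for(config, "public"),
                          years_any, world, "public", "PUB")
    pub$records$partner_id <- "public"
    pool <- sample_dataset(config$n_pool, pool_weights, ratio_for(config, "pool"),
                           years_any, world, "pool", "POOL")
    pool$records$partner_id <- "pool"
    feats <- c(feats, list(pub$features, pool$features))

    pool_truth <- select(pool$records, "id", "label")
    pool_records <- mutate(pool$records, label = NA_integer_)

    structure(list(
      config = config,
      partner_train = partner_train,
      partner_test = partner_test,
      public_set = pub$records,
      pool = pool_records,
      features = do.call(features_rbind, feats),
      generator_metadata = list(config = unclass(config), seed = config$seed),
      .pool_truth = pool_truth
    ), class = "fluid_world")
  }
}

#' @export
print.fluid_world <- function(x, ...) {
  cfg <- x$config %||% x$generator_metadata$config
  cat(sprintf(
    "<fluid_world> %d partners x %d train / %d test, public %d, pool %d (seed %d)\n",
    length(x$partner_train),
    nrow(x$partner_train[[1]]), nrow(x$partner_test[[1]]),
    nrow(x$public_set), nrow(x$pool), x$generator_metadata$seed
  ))
  invisible(x)
}

#' Ground-truth pool labels (test oracle)
#'
#' The pool is unlabeled through every standard accessor; this explicit
#' oracle exposes the generator's hidden labels for evaluation and testing
#' only — production federation code never reads it.
#'
#' @param world A `fluid_world`.
#' @return Tibble with `id` and true `label`.
#' @export
pool_ground_truth <- function(world) {
  stopifnot(inherits(world, "fluid_world"))
  world$.pool_truth
}

#' Feature container for a set of world molecules
#' @param world A `fluid_world`.
#' @param records Molecule records (or a character vector of ids).
#' @return `fluid_features` rows aligned with `records`.
#' @export
world_features <- function(world, records) {
  ids <- if (is.character(records)) records else records$id
  features_subset(world$features, ids)
}

#' Assemble a model-ready dataset from world records
#'
#' Convenience bundling of ids, labels, and features used by the teacher,
#' federation, and student stages.
#'
#' @param world A `fluid_world`.
#' @param records Labeled molecule records from the world.
#' @return List with `ids`, `labels`, `features`.
#' @export
model_dataset <- function(world, records) {
  list(ids = records$id,
       labels = as_binary_label(records$label),
       features = world_features(world, records))
}
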