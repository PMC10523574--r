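# Shared fixtures and independent oracles. Oracles deliberately use the
# dumbest possible route (double loops, full sorts, exhaustive
# enumeration) so they stay independent of the implementation they check.

# Small world used by many tests; sizes chosen for speed, structure as in
# the default configuration.
tiny_world <- function(seed = 1, ...) {
  args <- modifyList(
    list(n_partners = 3, n_train_per_partner = 300, n_test_per_partner = 120,
         n_public = 200, n_pool = 1200, seed = seed),
    list(...)
  )
  generate_world(do.call(world_config, args))
}

# Exhaustive k-NN mean Tanimoto: double loop over queries and references.
oracle_knn_tanimoto <- function(q, tr, k) {
  tan <- function(a, b) {
    i <- sum(a & b); u <- sum(a) + sum(b) - i
    if (u == 0) 0 else i / u
  }
  vapply(seq_len(nrow(q)), function(i) {
    sims <- vapply(seq_len(nrow(tr)), function(j) tan(q[i, ], tr[j, ]), numeric(1))
    mean(sort(sims, decreasing = TRUE)[seq_len(min(k, length(sims)))])
  }, numeric(1))
}

# Direct-formula confusion metrics, written independently of the package.
oracle_mcc <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn); fp <- as.numeric(fp); fn <- as.numeric(fn)
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  ifelse(d == 0, 0, (tp * tn - fp * fn) / sqrt(d))
}

# Brute-force federated-set selector: filter, full sort per class, slice,
# donate the shortfall. Returns the per-class counts and selected ids.
oracle_federated <- function(consolidated, n_per_class, reliability_min) {
  elig <- consolidated[consolidated$consensus_reliability >= reliability_min, ]
  ranked <- function(lab) {
    cl <- elig[elig$consensus_label == lab, ]
    cl[order(-cl$consensus_decidability, -cl$consensus_reliability,
             cl$molecule_id), ]
  }
  pos <- ranked(1); neg <- ranked(0)
  n_pos <- min(n_per_class, nrow(pos)); n_neg <- min(n_per_class, nrow(neg))
  n_neg <- min(n_neg + (n_per_class - n_pos), nrow(neg))
  n_pos <- min(n_pos + (n_per_class - min(n_per_class, nrow(neg))), nrow(pos))
  list(n_pos = n_pos, n_neg = n_neg,
       ids = c(head(pos$molecule_id, n_pos), head(neg$molecule_id, n_neg)))
}

# Exhaustive enumeration of circular atom environments (by bond set) up to
# a radius: the expected number of distinct fingerprint features for a
# molecule small enough that hash collisions are absent.
oracle_env_count <- function(elements, bonds, radius) {
  n <- length(elements)
  adj <- lapply(seq_len(n), function(a) {
    hits <- which(bonds$from == a | bonds$to == a)
    if (length(hits) == 0) return(NULL)
    data.frame(nbr = ifelse(bonds$from[hits] == a, bonds$to[hits], bonds$from[hits]),
               bond = hits)
  })
  deg <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  val <- vapply(seq_len(n), function(a) {
    hits <- which(bonds$from == a | bonds$to == a)
    sum(bonds$order[hits])
  }, numeric(1))
  # radius-0 features: distinct (element, degree, valence) triples
  r0 <- unique(paste(elements, deg, val))
  # radius >= 1: distinct grown bond sets
  keys <- character(0)
  for (a in seq_len(n)) {
    atoms <- a; bondset <- integer(0)
    for (r in seq_len(radius)) {
      new_bonds <- unique(unlist(lapply(atoms, function(x) adj[[x]]$bond)))
      new_atoms <- unique(unlist(lapply(atoms, function(x) adj[[x]]$nbr)))
      grown <- sort(unique(c(bondset, new_bonds)))
      if (length(grown) == length(bondset)) break
      bondset <- grown
      atoms <- unique(c(atoms, new_atoms))
      keys <- c(keys, paste(bondset, collapse = ","))
    }
  }
  length(r0) + length(unique(keys))
}

# Random prediction-record table for property tests.
random_predictions <- function(n, seed = 1) {
  withr::with_seed(seed, {
    p <- runif(n)
    tibble::tibble(
      molecule_id = sprintf("m%04d", seq_len(n)),
      member_id = "mA",
      predicted_label = as.integer(p >= 0.5),
      probability = p,
      decidability = abs(2 * p - 1),
      reliability = runif(n)
    )
  })
}
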