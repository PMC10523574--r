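# SMILES standardization and featurization: canonical largest-fragment
# SMILES, a frozen physicochemical descriptor block, and hashed circular
# (Morgan) fingerprints. All models in the package consume the feature
# container built here.

#' Load the frozen physicochemical descriptor configuration
#'
#' The descriptor block is a named, versioned configuration artifact shipped
#' with the package rather than a hard-coded list: the number of 1D/2D
#' descriptors available depends on the chemistry toolkit, so `featurize()`
#' asserts its output against this configuration at run time instead of
#' assuming a fixed count.
#'
#' @param path Optional path to an alternative JSON configuration.
#' @return A list with elements `name`, `descriptors` (tibble of
#'   `name`/`source`), `n` (descriptor count) and `hash` (configuration hash
#'   used to key feature caches and model bundles).
#' @export
descriptor_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "descriptor_config.json", package = "fluidsim")
  cfg <- jsonlite::fromJSON(path)
  desc <- as_tibble(cfg$descriptors)
  if (nrow(desc) == 0) abort("descriptor configuration lists no descriptors.")
  list(
    name = cfg$name,
    descriptors = desc,
    n = nrow(desc),
    hash = object_hash(list(name = cfg$name, descriptors = desc$name))
  )
}

# Canonical SMILES of one molecule via the OpenBabel backend; "" on failure.
canonicalize_one <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))),
    error = function(e) ""
  )
  # output is "SMILES<tab>title\n"; keep the SMILES token
  sub("[ \t\r\n].*$", "", out)
}

#' Standardize SMILES: strip salts, keep the largest fragment, canonicalize
#'
#' Multi-fragment inputs (salt/solvate records, fragments separated by `.`)
#' are reduced to the fragment with the most heavy atoms; ties are broken by
#' keeping the fragment whose canonical SMILES is lexicographically smallest,
#' so the result is deterministic. The surviving fragment is returned in
#' canonical form, which makes the operation idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @param on_error `"error"` (default) aborts on the first unparseable
#'   SMILES, reporting the offending string; `"na"` returns `NA` for it so
#'   the caller can drop or inspect failures.
#' @return Character vector of canonical largest-fragment SMILES.
#' @examples
#' \donttest{
#' standardize_smiles("CCO.Cl")   # -> "CCO"
#' standardize_smiles("OCC")      # -> "CCO"
#' }
#' @export
standardize_smiles <- function(smiles, on_error = c("error", "na")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) {
      if (on_error == "error") abort("empty SMILES string.")
      return(NA_character_)
    }
    can <- canonicalize_one(s)
    if (!nzchar(can)) {
      if (on_error == "error") abort(sprintf("unparseable SMILES: '%s'", s))
      return(NA_character_)
    }
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    if (length(frags) > 1) {
      fcan <- vapply(frags, canonicalize_one, character(1))
      if (any(!nzchar(fcan))) {
        if (on_error == "error") abort(sprintf("unparseable fragment in SMILES: '%s'", s))
        return(NA_character_)
      }
      sizes <- vapply(fcan, function(f) heavy_atom_count(f), numeric(1))
      best <- which(sizes == max(sizes))
      can <- sort(fcan[best])[1]
    }
    can
  }, character(1), USE.NAMES = FALSE)
}

heavy_atom_count <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  nrow(ChemmineR::atomblock(sdf[[1]]))
}

ATOMIC_NUMBER <- c(
  H = 1, Li = 3, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
  Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Zn = 30,
  As = 33, Se = 34, Br = 35, I = 53
)

# Heavy-atom graph of one molecule from its SDF component.
mol_graph <- function(sdf_component) {
  ab <- ChemmineR::atomblock(sdf_component)
  bb <- ChemmineR::bondblock(sdf_component)
  elem <- sub("_.*$", "", rownames(ab))
  bonds <- if (length(bb) == 0 || is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    tibble(from = integer(0), to = integer(0), order = integer(0))
  } else {
    tibble(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
  }
  list(elements = elem, bonds = bonds)
}

# Deterministic integer hash of an integer vector, kept within 2^31 - 1 so
# double arithmetic stays exact.
hash_ints <- function(v) {
  M <- 2147483647
  h <- 5381
  for (x in v) h <- (h * 131 + (as.numeric(x) %% M)) %% M
  h
}

# Hashed circular (Morgan/ECFP-style) fingerprint over the heavy-atom graph.
# Initial atom invariants are (atomic number, heavy degree, bond-order sum);
# each iteration hashes the sorted (bond order, neighbour identifier) pairs
# into a new identifier, and an environment (identified by its bond set) is
# emitted once, at the smallest radius where it appears.
morgan_bits <- function(graph, radius = 3, n_bits = 2048) {
  elem <- graph$elements
  n <- length(elem)
  bonds <- graph$bonds
  z <- unname(ATOMIC_NUMBER[elem])
  z[is.na(z)] <- 99
  deg <- integer(n); val <- integer(n)
  nb <- vector("list", n)   # each: matrix cols (neighbour, order, bond index)
  for (i in seq_len(nrow(bonds))) {
    f <- bonds$from[i]; t <- bonds$to[i]; o <- bonds$order[i]
    deg[f] <- deg[f] + 1L; deg[t] <- deg[t] + 1L
    val[f] <- val[f] + o;  val[t] <- val[t] + o
    nb[[f]] <- rbind(nb[[f]], c(t, o, i))
    nb[[t]] <- rbind(nb[[t]], c(f, o, i))
  }
  inv <- vapply(seq_len(n), function(a) hash_ints(c(z[a], deg[a], val[a])), numeric(1))
  env <- replicate(n, integer(0), simplify = FALSE)
  bits <- integer(0)
  seen_keys <- ""   # the empty bond set never re-emits
  bits <- c(bits, inv %% n_bits)
  for (r in seq_len(radius)) {
    new_inv <- inv; new_env <- env
    for (a in seq_len(n)) {
      if (is.null(nb[[a]])) next
      m <- nb[[a]]
      ord <- order(m[, 2], inv[m[, 1]])
      pairs <- as.vector(t(cbind(m[ord, 2], inv[m[ord, 1]])))
      new_inv[a] <- hash_ints(c(r, inv[a], pairs))
      grown <- sort(unique(c(env[[a]], m[, 3], unlist(env[m[, 1]]))))
      new_env[[a]] <- grown
      key <- paste(grown, collapse = ",")
      if (!key %in% seen_keys) {
        seen_keys <- c(seen_keys, key)
        bits <- c(bits, new_inv[a] %% n_bits)
      }
    }
    inv <- new_inv; env <- new_env
  }
  out <- integer(n_bits)
  out[unique(bits) + 1L] <- 1L
  out
}

graph_descriptors <- function(graph, sdf_component) {
  elem <- graph$elements
  bonds <- graph$bonds
  ring <- tryCatch(
    ChemmineR::rings(sdf_component, type = "count", arom = TRUE),
    error = function(e) c(RINGS = 0, AROMATIC = 0)
  )
  n_heavy <- length(elem)
  c(
    n_heavy_atoms = n_heavy,
    n_carbon = sum(elem == "C"),
    n_nitrogen = sum(elem == "N"),
    n_oxygen = sum(elem == "O"),
    n_sulfur = sum(elem == "S"),
    n_halogen = sum(elem %in% c("F", "Cl", "Br", "I")),
    n_rings = unname(ring["RINGS"]),
    n_aromatic_rings = unname(ring["AROMATIC"]),
    n_bonds = nrow(bonds),
    n_double_bonds = sum(bonds$order == 2),
    n_triple_bonds = sum(bonds$order == 3),
    frac_heteroatoms = if (n_heavy > 0) sum(elem != "C") / n_heavy else 0
  )
}

#' Build the feature container used by all models
#'
#' Computes, for each molecule record, the frozen physicochemical descriptor
#' block (see [descriptor_config()]) and a hashed circular (Morgan)
#' fingerprint of the given radius folded to `n_bits` bits. Identical
#' standardized SMILES always yield bitwise-identical rows, and row order
#' follows the input.
#'
#' @param records Data frame with at least columns `id` and `smiles`
#'   (standardized; see [standardize_smiles()]).
#' @param radius Circular fingerprint radius in bonds (default 3).
#' @param n_bits Folded fingerprint length (default 2048).
#' @param descriptors Descriptor configuration from [descriptor_config()].
#' @return A `fluid_features` object: list with `physchem` (numeric matrix,
#'   one column per configured descriptor), `fingerprint` (0/1 integer
#'   matrix with `n_bits` columns), `id`, and `config` (radius, bits,
#'   descriptor-configuration hash).
#' @export
featurize <- function(records, radius = 3, n_bits = 2048,
                      descriptors = descriptor_config()) {
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in% names(records)))
  if (nrow(records) == 0) {
    return(new_features(
      physchem = matrix(0, 0, descriptors$n,
                        dimnames = list(NULL, descriptors$descriptors$name)),
      fingerprint = matrix(0L, 0, n_bits),
      id = character(0),
      config = list(radius = radius, n_bits = n_bits, descriptor_hash = descriptors$hash)
    ))
  }
  smiles <- records$smiles
  usmi <- unique(smiles)
  names(usmi) <- paste0("m", seq_along(usmi))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(usmi)),
    error = function(e) abort(sprintf("featurization failed while parsing SMILES: %s", conditionMessage(e)))
  )
  if (length(sdf) != length(usmi)) {
    abort("featurization failed: some SMILES could not be parsed.")
  }
  # property engine driven per molecule from SMILES (robust to degenerate
  # structures, e.g. single-atom molecules, that break SDF round-trips)
  props <- do.call(rbind, lapply(
    ChemmineOB::forEachMol("SMILES", paste(usmi, collapse = "\n"),
                           function(mol) ChemmineOB::prop_OB(mol)),
    as.data.frame))
  ob_names <- descriptors$descriptors$name[descriptors$descriptors$source == "ob"]
  gr_names <- descriptors$descriptors$name[descriptors$descriptors$source == "graph"]
  missing_ob <- setdiff(ob_names, colnames(props))
  if (length(missing_ob)) {
    abort(sprintf("descriptor(s) not provided by the property engine: %s",
                  paste(missing_ob, collapse = ", ")))
  }
  phys_u <- matrix(NA_real_, length(usmi), descriptors$n,
                   dimnames = list(NULL, descriptors$descriptors$name))
  fp_u <- matrix(0L, length(usmi), n_bits)
  for (i in seq_along(usmi)) {
    g <- mol_graph(sdf[[i]])
    gd <- graph_descriptors(g, sdf[[i]])
    phys_u[i, ob_names] <- as.numeric(props[i, ob_names])
    phys_u[i, gr_names] <- as.numeric(gd[gr_names])
    fp_u[i, ] <- morgan_bits(g, radius = radius, n_bits = n_bits)
  }
  bad <- which(!stats::complete.cases(phys_u))
  if (length(bad)) {
    ids <- records$id[match(usmi[bad[1]], smiles)]
    abort(sprintf("descriptor computation failed for molecule id '%s'", ids[1]))
  }
  idx <- match(smiles, usmi)
  new_features(
    physchem = phys_u[idx, , drop = FALSE],
    fingerprint = fp_u[idx, , drop = FALSE],
    id = as.character(records$id),
    config = list(radius = radius, n_bits = n_bits, descriptor_hash = descriptors$hash)
  )
}

#' @rdname featurize
#' @param physchem,fingerprint,id,config Components of the container; used
#'   by generators that emit feature vectors directly.
#' @export
new_features <- function(physchem, fingerprint, id, config = list()) {
  stopifnot(nrow(physchem) == nrow(fingerprint), nrow(physchem) == length(id))
  structure(
    list(physchem = physchem, fingerprint = fingerprint,
         id = as.character(id), config = config),
    class = "fluid_features"
  )
}

#' @export
print.fluid_features <- function(x, ...) {
  cat(sprintf("<fluid_features> %d molecules, %d descriptors + %d fingerprint bits\n",
              length(x$id), ncol(x$physchem), ncol(x$fingerprint)))
  invisible(x)
}

#' @export
`[.fluid_features` <- function(x, i, ...) {
  new_features(x$physchem[i, , drop = FALSE], x$fingerprint[i, , drop = FALSE],
               x$id[i], x$config)
}

#' Subset a feature container by molecule id
#' @param x A `fluid_features` object.
#' @param ids Molecule ids to keep, in the requested order.
#' @export
features_subset <- function(x, ids) {
  idx <- match(as.character(ids), x$id)
  if (anyNA(idx)) abort("some requested ids are absent from the feature container.")
  x[idx]
}

#' Combine feature containers by row
#' @param ... `fluid_features` objects sharing a configuration.
#' @export
features_rbind <- function(...) {
  xs <- list(...)
  xs <- xs[!vapply(xs, is.null, logical(1))]
  stopifnot(length(xs) >= 1)
  new_features(
    do.call(rbind, lapply(xs, `[[`, "physchem")),
    do.call(rbind, lapply(xs, `[[`, "fingerprint")),
    unlist(lapply(xs, `[[`, "id")),
    xs[[1]]$config
  )
}

#' Fit the min-max scaler on a reference feature matrix
#'
#' Records per-descriptor minima and maxima; [apply_scaler()] then maps each
#' descriptor linearly onto `[0, 1]`, clipping values outside the reference
#' range. Fingerprint bits pass through unchanged. Constant descriptors
#' (min equal to max) map to 0, avoiding a division by zero. The study
#' protocol fits the scaler on training and test jointly; `strict = TRUE`
#' callers fit on training only and clipping handles out-of-range test
#' values (see the methods vignette for the leakage trade-off).
#'
#' @param features A `fluid_features` object or a bare numeric matrix.
#' @return A `fluid_scaler` with per-descriptor `min` and `max`.
#' @export
fit_scaler <- function(features) {
  m <- if (inherits(features, "fluid_features")) features$physchem else as.matrix(features)
  if (nrow(m) == 0) abort("cannot fit a scaler on an empty reference matrix.")
  structure(
    list(min = apply(m, 2, min), max = apply(m, 2, max), fitted = TRUE),
    class = "fluid_scaler"
  )
}

#' Apply a fitted min-max scaler
#'
#' @param scaler A `fluid_scaler` from [fit_scaler()].
#' @param features A `fluid_features` object (descriptor block scaled,
#'   fingerprint untouched) or a bare numeric matrix.
#' @return Same type as `features`, with every descriptor entry in `[0, 1]`.
#' @export
apply_scaler <- function(scaler, features) {
  if (!inherits(scaler, "fluid_scaler") || !isTRUE(scaler$fitted)) {
    abort("`scaler` is not a fitted fluid_scaler; call fit_scaler() first.")
  }
  scale_mat <- function(m) {
    rng <- scaler$max - scaler$min
    out <- sweep(m, 2, scaler$min, "-")
    nonconst <- rng > 0
    out[, nonconst] <- sweep(out[, nonconst, drop = FALSE], 2, rng[nonconst], "/")
    out[, !nonconst] <- 0
    out[out < 0] <- 0
    out[out > 1] <- 1
    out
  }
  if (inherits(features, "fluid_features")) {
    features$physchem <- scale_mat(features$physchem)
    features$config$scaled <- TRUE
    features
  } else {
    scale_mat(as.matrix(features))
  }
}

#' Full model-ready matrix: scaled descriptors next to fingerprint bits
#' @param features A `fluid_features` object.
#' @return Numeric matrix with named columns.
#' @export
features_matrix <- function(features) {
  stopifnot(inherits(features, "fluid_features"))
  out <- cbind(features$physchem, features$fingerprint)
  colnames(out) <- c(colnames(features$physchem) %||% paste0("d", seq_len(ncol(features$physchem))),
                     paste0("fp", seq_len(ncol(features$fingerprint))))
  rownames(out) <- NULL
  out
}

#' Read molecule records from CSV
#'
#' Expects the dialect `smiles,label,assay_year,partner_id,target_id`
#' (a leading `id` column is kept when present, otherwise row ids are
#' assigned). `label` may be blank for unlabeled pool molecules.
#'
#' @param path CSV file path.
#' @return Tibble of molecule records.
#' @export
read_molecules <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"id" %in% names(df)) df$id <- paste0("mol", seq_len(nrow(df)))
  need <- c("smiles", "label", "assay_year", "partner_id", "target_id")
  for (col in setdiff(need, names(df))) df[[col]] <- NA
  df$label <- suppressWarnings(as.integer(df$label))
  as_tibble(df[, c("id", need)])
}

#' Read an unlabeled SMILES pool (one SMILES per line)
#' @param path Text file, one SMILES per line.
#' @return Tibble of molecule records with missing labels.
#' @export
read_pool_smiles <- function(path) {
  smi <- readLines(path)
  smi <- smi[nzchar(trimws(smi))]
  tibble(id = paste0("pool", seq_along(smi)), smiles = trimws(smi),
         label = NA_integer_, assay_year = NA_integer_,
         partner_id = NA_character_, target_id = NA_character_)
}

#' Write molecule records in the package CSV dialect
#' @param records Tibble of molecule records.
#' @param path Output CSV path.
#' @export
write_molecules <- function(records, path) {
  cols <- intersect(c("id", "smiles", "label", "assay_year", "partner_id", "target_id"),
                    names(records))
  readr::write_csv(records[, cols], path)
  invisible(path)
}
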