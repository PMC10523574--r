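# Internal helpers shared across modules.

# Derive a child seed from a parent seed and a stream label, staying within
# the 32-bit integer range. Deterministic, collision-poor for our handful of
# named streams.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

# MD5 of an in-memory string (tools::md5sum is file-based).
string_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f, sep = "")
  unname(tools::md5sum(f))
}

# Canonical JSON-ish hash of a list (config provenance).
object_hash <- function(x) {
  string_md5(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

assert_probability <- function(p, what = "probability") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort(sprintf("`%s` must be numeric in [0, 1].", what))
  }
  invisible(p)
}

# Binary labels as integer 0/1, accepting factor/logical/numeric input.
as_binary_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- as.integer(x)
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    abort("labels must be binary (0 = inactive, 1 = active).")
  }
  x
}

check_both_classes <- function(labels, context = "training") {
  labels <- as_binary_label(labels)
  if (length(unique(labels)) < 2) {
    abort(sprintf("%s labels contain a single class; both classes are required.", context))
  }
  invisible(labels)
}
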