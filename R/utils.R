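# Internal utilities: deterministic hashing, memoisation, seed handling.

# Rolling polynomial hash over non-negative integer codes. The modulus is a
# prime below 2^24 so that h * 131 + x stays exactly representable in a
# double; fingerprint bit indices are taken modulo the vector length.
hash_ints <- function(v, mod = 9999991) {
  h <- 17
  for (x in v) h <- (h * 131 + x) %% mod
  h
}

# Package-level memoisation environment (canonical SMILES -> parsed graphs,
# SDF strings, descriptor rows). Purely a cache: results are a function of
# the canonical SMILES only.
.iso_cache <- new.env(parent = emptyenv())

cache_get <- function(key) {
  if (exists(key, envir = .iso_cache, inherits = FALSE)) {
    get(key, envir = .iso_cache, inherits = FALSE)
  } else {
    NULL
  }
}

cache_set <- function(key, value) {
  assign(key, value, envir = .iso_cache)
  value
}

#' Clear the internal molecule cache
#'
#' Parsed molecular graphs and descriptor rows are memoised per canonical
#' SMILES. The cache only ever holds values that are pure functions of the
#' structure, so clearing it is never required for correctness.
#'
#' @return Invisibly, the number of entries removed.
#' @export
clear_molecule_cache <- function() {
  n <- length(ls(.iso_cache))
  rm(list = ls(.iso_cache), envir = .iso_cache)
  invisible(n)
}

# Derive a stage seed from a master seed by a fixed offset, keeping the
# result inside the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
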