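# Shared, lazily built test objects. Everything is generated in code from
# seeded generators; expensive objects are cached for the session.

.test_cache <- new.env()

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

# Small separable library and an SVM+circular model for reuse.
tt_library <- function() {
  cached("lib", generate_separable_library(120, seed = 101))
}

tt_split <- function() {
  lib <- tt_library()
  list(train = lib[1:96, ], test = lib[97:120, ])
}

tt_svm_model <- function() {
  cached("svm_model", {
    sp <- tt_split()
    train_model(sp$train, "svm", "circular", seed = 7)
  })
}

# Benzene-family canonical SMILES used across featurization tests.
tt_canon <- function(smiles) {
  std <- standardize_smiles(smiles)
  stopifnot(all(std$ok))
  std$canonical_smiles
}

# Random binary matrix helper.
tt_bits <- function(n, p, prob = 0.3, seed = 1) {
  withr::with_seed(seed, matrix(rbinom(n * p, 1, prob), n, p))
}

# Acceptance-scale objects (shared between acceptance criteria).
tt_acc_library <- function() {
  cached("acc_lib", generate_separable_library(400, seed = 211))
}

tt_acc_split <- function() {
  lib <- tt_acc_library()
  list(train = lib[1:320, ], test = lib[321:400, ])
}

tt_acc_svm <- function() {
  cached("acc_svm", {
    sp <- tt_acc_split()
    train_model(sp$train, "svm", "circular", seed = 17)
  })
}
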