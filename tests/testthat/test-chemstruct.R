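test_that("standardization strips salts and canonicalizes", {
  std <- standardize_smiles(c("CCO", "CCO.[Na+].[Cl-]", "OCC"))
  expect_true(all(std$ok))
  expect_equal(std$canonical_smiles[2], std$canonical_smiles[1])
  expect_equal(std$canonical_smiles[3], std$canonical_smiles[1])
  expect_equal(std$num_heavy_atoms[1], 3L)
  expect_setequal(std$elements[[1]], c("C", "O"))
})

test_that("standardization rejects invalid and inorganic inputs", {
  std <- standardize_smiles(c("C1CC", "[Na+].[Cl-]", ""))
  expect_false(any(std$ok))
  expect_equal(std$fail_reason[1], "invalid structure")
  expect_equal(std$fail_reason[2], "no organic fragment")
})

test_that("salt stripping keeps the largest organic fragment", {
  # glycine ethyl ester fragment vs acetate counter-fragment
  std <- standardize_smiles("CCOC(=O)CN.CC(=O)O")
  big <- standardize_smiles("CCOC(=O)CN")
  expect_equal(std$canonical_smiles, big$canonical_smiles)
})

test_that("representation lengths match their contracts", {
  smi <- tt_canon("c1ccc(S(N)(=O)=O)cc1")
  expect_equal(ncol(featurize(smi, "circular")), 2048L)
  expect_equal(ncol(featurize(smi, "path")), 2048L)
  expect_equal(ncol(featurize(smi, "keys")), 881L)
  pc <- featurize(smi, "physchem")
  expect_equal(colnames(pc), physchem_descriptor_names())
})

test_that("featurization is a pure function of the structure", {
  a <- featurize(tt_canon("OCC"), "circular")
  b <- featurize(tt_canon("CCO"), "circular")
  expect_identical(unname(a), unname(b))
  # repeated calls identical
  expect_identical(a, featurize(tt_canon("OCC"), "circular"))
})

test_that("enantiomers collide at representation level", {
  e1 <- tt_canon("N[C@@H](Cc1ccccc1)C(=O)O")
  e2 <- tt_canon("N[C@H](Cc1ccccc1)C(=O)O")
  expect_false(e1 == e2)   # stereo retained in the canonical SMILES
  for (r in c("circular", "path", "keys", "physchem")) {
    expect_identical(unname(featurize(e1, r)), unname(featurize(e2, r)))
  }
  expect_true(representation_identity(e1, e2))
})

test_that("bit vectors are binary and maps stay in atom range", {
  smi <- tt_canon("CCOC(=O)c1ccc(-c2ccc(S(N)(=O)=O)cc2)cc1")
  g_heavy <- standardize_smiles(smi)$num_heavy_atoms
  for (r in c("circular", "path", "keys")) {
    X <- featurize(smi, r)
    expect_true(all(X %in% c(0L, 1L)))
  }
  map <- map_bits_to_atoms(smi, "circular")
  atoms <- unlist(map)
  expect_true(all(atoms >= 1 & atoms <= g_heavy))
  expect_true(all(lengths(map) >= 1))
})

test_that("min-max scaler follows the stated conventions", {
  X <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  sc <- fit_scaler(X)
  scaled <- apply_scaler(sc, X)
  expect_equal(unname(scaled[, 1]), c(0, 0.5, 1))
  expect_equal(unname(scaled[, 2]), c(0, 0, 0))   # constant feature -> 0
  # out-of-sample values are not clipped
  out <- apply_scaler(sc, cbind(a = 8, b = 5))
  expect_equal(unname(out[1, 1]), 1.5)
  expect_error(apply_scaler(sc, cbind(a = 1)), "width mismatch")
  expect_error(apply_scaler(sc, cbind(z = 1, q = 2)), "descriptor list")
})

test_that("scaled training descriptors land in [0, 1]", {
  lib <- tt_library()
  X <- featurize(lib$canonical_smiles[1:30], "physchem")
  sc <- fit_scaler(X)
  S <- apply_scaler(sc, X)
  expect_true(all(S >= 0 - 1e-12 & S <= 1 + 1e-12))
})

test_that("tanimoto matches its closed form and handles edge cases", {
  a <- c(1, 1, 1, 1, 0, 0, 0)   # k = 4
  b <- c(1, 1, 0, 0, 1, 0, 0)   # m = 3, j = 2
  expect_equal(tanimoto(a, b), 0.4)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "empty")
  expect_equal(z, 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("tanimoto is symmetric and bounded on random pairs", {
  A <- tt_bits(1000, 64, seed = 3)
  B <- tt_bits(1000, 64, seed = 4)
  s1 <- diag(tanimoto_matrix(A, B))
  s2 <- diag(tanimoto_matrix(B, A))
  expect_equal(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("euclidean distance satisfies metric axioms", {
  expect_equal(euclidean_dist(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_dist(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(euclidean_dist(1:2, 1:3), "width mismatch")
  withr::with_seed(11, {
    for (i in 1:50) {
      x <- rnorm(5); y <- rnorm(5); z <- rnorm(5)
      expect_lte(euclidean_dist(x, z),
                 euclidean_dist(x, y) + euclidean_dist(y, z) + 1e-12)
    }
  })
})
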