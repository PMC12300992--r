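test_that("permutation SHAP satisfies the additivity identity", {
  sp <- tt_split()
  m <- tt_svm_model()
  smi <- sp$test$canonical_smiles[1]
  bg <- featurize(sp$train$canonical_smiles[1:5], "circular")
  sh <- shap_bits(m, smi, background = bg, n_permutations = 1, seed = 3)
  expect_equal(sum(sh$shap_value) + attr(sh, "base_value"),
               attr(sh, "p_molecule"), tolerance = 1e-10)
  # reproducible under a fixed seed
  sh2 <- shap_bits(m, smi, background = bg, n_permutations = 1, seed = 3)
  expect_identical(sh$shap_value, sh2$shap_value)
  # off-bits never differing from the background carry zero
  x <- featurize(smi, "circular")[1, ]
  never_diff <- which(vapply(seq_along(x), function(j) {
    all(bg[, j] == x[j])
  }, logical(1)))
  expect_true(all(sh$shap_value[never_diff] == 0))
})

test_that("explaining a molecule against itself gives zero contributions", {
  sp <- tt_split()
  m <- tt_svm_model()
  smi <- sp$test$canonical_smiles[2]
  self_bg <- featurize(smi, "circular")
  sh <- shap_bits(m, smi, background = self_bg, seed = 1)
  expect_true(all(sh$shap_value == 0))
  expect_equal(attr(sh, "base_value"), attr(sh, "p_molecule"))
})

test_that("descriptor models are rejected by the explainer", {
  sp <- tt_split()
  m_pc <- train_model(sp$train[1:40, ], "rf", "physchem", seed = 3)
  expect_error(shap_bits(m_pc, sp$test$canonical_smiles[1]),
               "unsupported representation")
})

test_that("atom weights follow the double-normalization formula", {
  # one bit, phi = 0.6, three atoms -> each atom gets 0.2
  contr <- tibble::tibble(bit = 10L, shap_value = 0.6)
  mapping <- list(`10` = list(c(1L, 2L, 3L)))
  w <- atom_weights(contr, mapping, n_atoms = 4)
  expect_equal(w$weight, c(0.2, 0.2, 0.2, 0))
  # atom shared by two bits: (0.4/2 + (-0.2)/1) / 2 = 0
  contr <- tibble::tibble(bit = c(1L, 2L), shap_value = c(0.4, -0.2))
  mapping <- list(`1` = list(c(1L, 2L)), `2` = list(1L))
  w <- atom_weights(contr, mapping, n_atoms = 2)
  expect_equal(w$weight[1], 0)
  expect_equal(w$weight[2], 0.2)   # (0.4/2) / r(2) with r(2) = 1
  # all-positive contributions keep covered atoms positive
  contr <- tibble::tibble(bit = c(1L, 2L), shap_value = c(0.3, 0.5))
  mapping <- list(`1` = list(c(1L, 2L)), `2` = list(c(2L, 3L)))
  w <- atom_weights(contr, mapping, n_atoms = 3)
  expect_true(all(w$weight > 0))
  # empty contributions warn and return zeros
  expect_warning(w0 <- atom_weights(tibble::tibble(bit = integer(),
                                                   shap_value = numeric()),
                                    mapping, n_atoms = 3), "all zero")
  expect_equal(w0$weight, c(0, 0, 0))
})

test_that("weights are conserved when bits partition the atoms", {
  withr::with_seed(13, {
    for (i in 1:10) {
      n_bits <- sample(2:6, 1)
      sizes <- sample(1:4, n_bits, replace = TRUE)
      atoms <- split(seq_len(sum(sizes)), rep(seq_len(n_bits), sizes))
      phi <- rnorm(n_bits)
      contr <- tibble::tibble(bit = seq_len(n_bits), shap_value = phi)
      mapping <- stats::setNames(lapply(atoms, list),
                                 as.character(seq_len(n_bits)))
      w <- atom_weights(contr, mapping, n_atoms = sum(sizes))
      expect_equal(sum(w$weight), sum(phi), tolerance = 1e-9)
    }
  })
})

test_that("both normalization orders agree on non-overlapping bits", {
  contr <- tibble::tibble(bit = c(1L, 2L), shap_value = c(0.3, -0.1))
  mapping <- list(`1` = list(c(1L, 2L)), `2` = list(c(3L)))
  w1 <- atom_weights(contr, mapping, 3, order = "atoms_first")
  w2 <- atom_weights(contr, mapping, 3, order = "occurrence_first")
  expect_equal(w1$weight, w2$weight)
})

test_that("attribution highlights the planted sulfonamide motif", {
  sp <- tt_split()
  m <- tt_svm_model()
  preds <- predict(m, sp$test$canonical_smiles)
  actives <- sp$test$canonical_smiles[
    sp$test$label == "active" & preds$predicted == "active"]
  actives <- actives[seq_len(min(6, length(actives)))]
  outrank <- vapply(actives, function(smi) {
    att <- explain_molecule(m, smi, n_background = 6, n_permutations = 1,
                            seed = 5)
    motif <- sulfonamide_atoms(smi)
    mean(att$weight[motif]) > mean(att$weight[-motif])
  }, logical(1))
  expect_gte(mean(outrank), 0.9)
})

test_that("attribution renders an image with a faithful numeric sidecar", {
  sp <- tt_split()
  m <- tt_svm_model()
  smi <- sp$test$canonical_smiles[sp$test$label == "active"][1]
  att <- explain_molecule(m, smi, n_background = 4, n_permutations = 1,
                          seed = 2)
  dir <- withr::local_tempdir()
  paths <- render_attribution(att, file.path(dir, "attr.png"))
  expect_true(file.exists(paths$image))
  side <- utils::read.csv(paths$sidecar)
  g_heavy <- standardize_smiles(smi)$num_heavy_atoms
  expect_equal(nrow(side), g_heavy)
  expect_equal(side$weight, att$weight)
  expect_equal(sign(side$weight), sign(att$weight))
})
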