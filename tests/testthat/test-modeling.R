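test_that("tanimoto kernel Gram matrices behave like a kernel", {
  A <- tt_bits(30, 128, seed = 12)
  G <- tanimoto_kernel(A)
  expect_equal(G, t(G))
  expect_true(all(diag(G)[rowSums(A) > 0] == 1))
  # disjoint rows give zero
  B <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(tanimoto_kernel(B)[1, 2], 0)
  expect_error(tanimoto_kernel(matrix(c(0, 2, 1, 1), 2)), "binary")
})

test_that("knn with k = 1 returns its own label on a training compound", {
  sp <- tt_split()
  m <- train_model(sp$train, "knn", "circular",
                   hyperparams = list(k = 1, weights = "uniform"), seed = 2)
  pred <- predict(m, sp$train$canonical_smiles[1:10])
  expect_equal(pred$p_active,
               as.numeric(sp$train$label[1:10] == "active"))
})

test_that("training is deterministic under a fixed seed", {
  sp <- tt_split()
  for (alg in c("svm", "rf")) {
    m1 <- train_model(sp$train[1:40, ], alg, "keys", seed = 9)
    m2 <- train_model(sp$train[1:40, ], alg, "keys", seed = 9)
    p1 <- predict(m1, sp$test$canonical_smiles)
    p2 <- predict(m2, sp$test$canonical_smiles)
    expect_identical(p1$p_active, p2$p_active)
  }
})

test_that("shuffling training rows leaves predictions unchanged", {
  sp <- tt_split()
  tr <- sp$train[1:40, ]
  perm <- withr::with_seed(4, sample.int(nrow(tr)))
  m1 <- train_model(tr, "svm", "keys", seed = 9)
  m2 <- train_model(tr[perm, ], "svm", "keys", seed = 9)
  p1 <- predict(m1, sp$test$canonical_smiles)$p_active
  p2 <- predict(m2, sp$test$canonical_smiles)$p_active
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("model bundles carry the novelty fingerprints and scaler", {
  sp <- tt_split()
  m_bit <- tt_svm_model()
  expect_null(m_bit$scaler)
  expect_equal(ncol(m_bit$train_keys), 881)
  expect_equal(nrow(m_bit$train_keys), nrow(sp$train))
  m_pc <- train_model(sp$train[1:40, ], "rf", "physchem", seed = 3)
  expect_s3_class(m_pc$scaler, "iso_scaler")
  expect_error(train_model(dplyr::mutate(sp$train, label = "active"),
                           "rf", "keys", seed = 1), "single-class")
})

test_that("probabilities stay in range and match the label threshold", {
  sp <- tt_split()
  m <- tt_svm_model()
  pred <- predict(m, sp$test$canonical_smiles)
  expect_true(all(pred$p_active >= 0 & pred$p_active <= 1))
  expect_identical(pred$predicted,
                   ifelse(pred$p_active >= 0.5, "active", "inactive"))
})

test_that("serialization round-trips to identical predictions", {
  sp <- tt_split()
  m <- tt_svm_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  p1 <- predict(m, sp$test$canonical_smiles)$p_active
  p2 <- predict(m2, sp$test$canonical_smiles)$p_active
  expect_identical(p1, p2)
})

test_that("grid search is exhaustive, seeded and degenerate-grid safe", {
  sp <- tt_split()
  small <- sp$train[1:40, ]
  grid1 <- data.frame(k = 3, weights = "uniform",
                      stringsAsFactors = FALSE)
  gs <- grid_search(small, "knn", "keys", grid = grid1, seed = 4)
  expect_equal(gs$best$k, 3)
  expect_equal(nrow(gs$results), 1)
  expect_length(gs$cv, 5)
  grid2 <- data.frame(k = c(1, 5), weights = "uniform",
                      stringsAsFactors = FALSE)
  gs1 <- grid_search(small, "knn", "keys", grid = grid2, seed = 4)
  gs2 <- grid_search(small, "knn", "keys", grid = grid2, seed = 4)
  expect_identical(gs1$best, gs2$best)
  expect_identical(gs1$results$mean_mcc, gs2$results$mean_mcc)
  expect_error(grid_search(small, "knn", "keys",
                           grid = data.frame(), seed = 1), "empty grid")
})

test_that("repeated Monte-Carlo CV returns the requested cycles", {
  sp <- tt_split()
  cv <- repeated_cv(sp$train[1:60, ], "rf", "keys", cycles = 4, seed = 6)
  expect_length(cv$scores, 4)
  expect_true(all(cv$scores >= -1 & cv$scores <= 1, na.rm = TRUE))
  cv2 <- repeated_cv(sp$train[1:60, ], "rf", "keys", cycles = 4, seed = 6)
  expect_identical(cv$scores, cv2$scores)
  expect_equal(glance(cv)$mean_mcc, mean(cv$scores, na.rm = TRUE))
  # a planted-rule set is learned essentially perfectly
  expect_gte(mean(cv$scores, na.rm = TRUE), 0.9)
})

test_that("tanimoto kernel is rejected for the descriptor representation", {
  sp <- tt_split()
  expect_error(
    train_model(sp$train[1:40, ], "svm", "physchem",
                hyperparams = list(kernel = "tanimoto"), seed = 1),
    "bit representation")
})
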