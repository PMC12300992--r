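test_that("pKi conversion matches its definition", {
  expect_equal(ki_to_pki(1000), 6)
  expect_equal(ki_to_pki(1), 9)
  expect_equal(round(ki_to_pki(501.19), 2), 6.3)
  expect_error(ki_to_pki(0), "positive")
  expect_error(ki_to_pki(-5), "positive")
})

test_that("replicate reconciliation follows the 25% rule", {
  expect_equal(resolve_duplicate_ki(100), 100)
  expect_equal(resolve_duplicate_ki(c(100, 120)), 110)
  expect_true(is.na(resolve_duplicate_ki(c(100, 200))))
  # n >= 3: single pass against the initial mean
  expect_equal(resolve_duplicate_ki(c(100, 105, 200)), 105)
  # boundary at exactly 25% counts as keep
  expect_equal(resolve_duplicate_ki(c(75, 125)), 100)
  # merged value lies within [min, max] of the inputs
  withr::with_seed(5, {
    for (i in 1:50) {
      ki <- exp(rnorm(sample(2:5, 1), 4, 0.3))
      m <- resolve_duplicate_ki(ki)
      if (!is.na(m)) {
        expect_gte(m, min(ki) - 1e-12)
        expect_lte(m, max(ki) + 1e-12)
      }
    }
  })
})

test_that("primary filter drops by the stated structural rules", {
  records <- tibble::tibble(
    compound_id = paste0("r", 1:6),
    smiles = c("c1cc(Cl)ccc1Cc1ccc(S(N)(=O)=O)cc1",   # fine
               "c1ccc(S(N)(=O)=O)cc1",                # 11 heavy atoms
               "C1CC",                                # invalid
               "CC(C)[Si](C)(C)Oc1ccc(CCCCCCCCCC)cc1",# silicon
               "c1cc(Br)ccc1Cc1ccc(S(N)(=O)=O)cc1",   # GT pool
               "c1cc(I)ccc1Cc1ccc(S(N)(=O)=O)cc1"),   # bad relation
    standard_value_nm = c(10, 10, 10, 10, 10000, 10),
    standard_relation = c("=", "=", "=", "=", ">", "<"),
    target = "hCA_II", source = "synthetic")
  pf <- primary_filter(records)
  expect_equal(pf$kept$compound_id, "r1")
  expect_equal(pf$gt_pool$compound_id, "r5")
  expect_setequal(pf$drops$reason,
                  c("too few heavy atoms", "invalid structure",
                    "disallowed element", "unsupported relation"))
})

test_that("structure identity separates molecules, not stereoisomers", {
  benzene <- tt_canon("c1ccccc1CCCCCCCCCC")   # need >1 heavy for graphs
  toluene <- tt_canon("Cc1ccccc1CCCCCCCCCC")
  expect_false(representation_identity(benzene, toluene))
  expect_true(representation_identity(benzene, benzene))
})

test_that("labeling with a band excludes the ambiguous zone", {
  compounds <- tibble::tibble(
    canonical_smiles = paste0("m", 1:3), pki = c(7.6, 7.4, 7.0))
  lab <- label_compounds(compounds, 7.30, 0.25)
  expect_equal(lab$labeled$label, c("active", "inactive"))
  expect_equal(lab$band_excluded$canonical_smiles, "m2")
  expect_error(label_compounds(compounds, 7.30, -0.1), "non-negative")
  # no retained compound sits inside the band
  withr::with_seed(8, {
    cmp <- tibble::tibble(canonical_smiles = paste0("x", 1:200),
                          pki = runif(200, 4, 10))
    lab <- label_compounds(cmp, 7.30, 0.25)
    expect_true(all(abs(lab$labeled$pki - 7.30) > 0.25))
    expect_equal(nrow(lab$labeled) + nrow(lab$band_excluded), 200)
  })
})

test_that("censored records integrate only below the inactive boundary", {
  gt <- tibble::tibble(
    compound_id = c("g1", "g2"),
    canonical_smiles = c(tt_canon("c1cc(F)ccc1Cc1ccc(OC)cc1"),
                         tt_canon("c1cc(Cl)ccc1Cc1ccc(OC)cc1")),
    standard_value_nm = c(10000, 100))   # bounds pKi 5.0 and 7.0
  existing <- tibble::tibble(canonical_smiles = character())
  out <- integrate_gt_inactives(gt, existing, 6.30, 0.25)
  expect_equal(out$provenance, "g1")       # pKi 7.0 bound is uninformative
  expect_equal(out$label, "inactive")
  expect_equal(out$pki_bound, 5.0)
  # duplicate of an existing compound is dropped
  out2 <- integrate_gt_inactives(
    gt, tibble::tibble(canonical_smiles = gt$canonical_smiles[1]),
    6.30, 0.25)
  expect_equal(nrow(out2), 0)
})

test_that("stratified split keeps class ratios and is reproducible", {
  labeled <- tibble::tibble(canonical_smiles = paste0("c", 1:20),
                            label = rep(c("active", "inactive"), each = 10))
  sp <- stratified_split(labeled, 0.8, seed = 3)
  expect_equal(sum(sp$train$label == "active"), 8)
  expect_equal(sum(sp$train$label == "inactive"), 8)
  expect_equal(nrow(sp$test), 4)
  expect_length(intersect(sp$train$canonical_smiles,
                          sp$test$canonical_smiles), 0)
  sp2 <- stratified_split(labeled, 0.8, seed = 3)
  expect_identical(sp, sp2)
  small <- labeled[c(1:3, 11:20), ]
  expect_error(stratified_split(small, 0.8, seed = 1),
               "insufficient class size")
  # train/test class-ratio difference bounded over random sizes
  withr::with_seed(9, {
    for (i in 1:25) {
      na <- sample(5:40, 1); ni <- sample(5:40, 1)
      lab <- tibble::tibble(canonical_smiles = paste0("z", seq_len(na + ni)),
                            label = c(rep("active", na),
                                      rep("inactive", ni)))
      sp <- stratified_split(lab, 0.8, seed = i)
      expect_equal(sum(sp$train$label == "active"), floor(0.8 * na))
      expect_equal(sum(sp$train$label == "inactive"), floor(0.8 * ni))
    }
  })
})

test_that("curation reproduces the generator's intended fates", {
  gen <- generate_activity_table(n_compounds = 120, seed = 31)
  ds <- curate_activity(gen$records, "hCA_II", seed = 5)
  man <- gen$manifest
  got <- tidy(ds)
  kept <- man[man$fate == "kept", ]
  gt <- man[man$fate == "gt_integrated", ]
  excluded <- man[man$fate %in% c("band_excluded", "discordant_discarded",
                                  "dropped_filter", "gt_uninformative"), ]
  expect_setequal(got$canonical_smiles[!is.na(got$pki)],
                  kept$canonical_smiles)
  expect_setequal(got$canonical_smiles[is.na(got$pki)], gt$canonical_smiles)
  merged <- merge(kept, got, by = "canonical_smiles")
  expect_true(all(merged$final_label == merged$label))
  expect_false(any(excluded$canonical_smiles %in% got$canonical_smiles,
                   na.rm = TRUE))
  # class ratio preserved between train and test within rounding
  ratio_tr <- mean(ds$train$label == "active")
  ratio_te <- mean(ds$test$label == "active")
  expect_lt(abs(ratio_tr - ratio_te), 0.1)
  # monotonicity of the funnel counts
  r <- ds$report
  expect_lte(r$n_unique, r$n_primary_kept)
  expect_lte(r$n_band_excluded, r$n_unique)
  expect_equal(r$n_active + r$n_inactive,
               nrow(ds$train) + nrow(ds$test))
})
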