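test_that("screen retains hits at the cutoff, ranked by probability", {
  sp <- tt_split()
  m <- tt_svm_model()
  hits <- screen(m, sp$test$canonical_smiles, prob_cutoff = 0.5)
  expect_true(all(hits$p_active >= 0.5))
  expect_true(all(diff(hits$p_active) <= 0))
  # actives should dominate the hit list on the separable library
  labels <- sp$test$label[match(hits$canonical_smiles,
                                sp$test$canonical_smiles)]
  expect_gt(mean(labels == "active"), 0.8)
  expect_warning(empty <- screen(m, character(0)), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("alert filters match known toxicophores", {
  pains <- filter_alerts("pains")
  rhodanine <- tt_canon("O=C1CSC(=S)N1Cc1ccccc1CCCCCC")
  clean <- tt_canon("c1cc(F)ccc1Cc1ccc(OC)cc1")
  expect_false(pains$fun(rhodanine))
  expect_true(pains$fun(clean))
  brenk <- filter_alerts("brenk")
  nitro <- tt_canon("O=[N+]([O-])c1ccc(Cc2ccccc2)cc1")
  expect_false(brenk$fun(nitro))
  expect_error(load_alerts(path = withr::local_tempfile(
    lines = "C1CC(\tbroken")), "malformed SMARTS")
})

test_that("property filters apply the Lipinski and Veber limits", {
  lip <- filter_lipinski()
  heavy <- tt_canon(paste0("CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",
                           "c1ccc(O)cc1"))  # MW >> 500, logP >> 5
  ok <- tt_canon("c1cc(F)ccc1Cc1ccc(OC)cc1")
  expect_false(lip$fun(heavy))
  expect_true(lip$fun(ok))
  # one violation allowed under the relaxed variant: logP is still > 5
  expect_false(filter_lipinski(max_violations = 1)$fun(heavy))
  veb <- filter_veber()
  floppy <- tt_canon("CCCCCCCCCCCCCCCCCCCCc1ccccc1")  # > 10 rotatable
  expect_false(veb$fun(floppy))
  expect_true(veb$fun(ok))
})

test_that("the cascade is monotone and records a replayable trace", {
  sp <- tt_split()
  m <- tt_svm_model()
  hits <- screen(m, sp$test$canonical_smiles)
  stages <- list(filter_alerts("pains"), filter_lipinski(), filter_veber(),
                 filter_predicate("toxicity"))
  out <- filter_cascade(hits, stages)
  funnel <- cascade_funnel(out)
  expect_equal(funnel$stage, c("pains", "lipinski", "veber", "toxicity"))
  expect_true(all(funnel$n_out <= funnel$n_in))
  expect_true(all(diff(funnel$n_in) <= 0))
  # survivors pass every stage; replay reproduces the trace
  trace_cols <- paste0("trace_", funnel$stage)
  expect_true(all(as.matrix(out[trace_cols]) == "pass"))
  out2 <- filter_cascade(hits, stages)
  expect_identical(attr(out, "trace"), attr(out2, "trace"))
  # the empty cascade is the identity
  id <- filter_cascade(hits, list())
  expect_equal(nrow(id), nrow(hits))
  # allow-list stage keeps only listed compounds
  allow <- filter_allowlist(hits$canonical_smiles[1:2])
  out3 <- filter_cascade(hits, list(allow))
  expect_equal(nrow(out3), 2)
})

test_that("novelty filter equals a brute-force similarity scan", {
  sp <- tt_split()
  m <- tt_svm_model()
  hits <- tibble::tibble(canonical_smiles = unique(c(
    sp$train$canonical_smiles[1:5],    # identical to training compounds
    sp$test$canonical_smiles)))
  filtered <- novelty_filter(hits, m, max_similarity = 0.80)
  # brute force oracle
  H <- featurize(hits$canonical_smiles, "keys")
  keep <- logical(nrow(H))
  for (i in seq_len(nrow(H))) {
    sims <- vapply(seq_len(nrow(m$train_keys)), function(j) {
      tanimoto(H[i, ], m$train_keys[j, ])
    }, numeric(1))
    keep[i] <- max(sims) <= 0.80
  }
  expect_setequal(filtered$canonical_smiles, hits$canonical_smiles[keep])
  # a training compound itself (tn = 1) is always removed
  expect_false(any(sp$train$canonical_smiles[1:5] %in%
                     filtered$canonical_smiles))
  # exact boundary is retained: plant a synthetic case
  train_keys <- matrix(0L, 1, 881); train_keys[1, 1:5] <- 1L
  hit_keys <- matrix(0L, 1, 881); hit_keys[1, 1:4] <- 1L
  expect_equal(tanimoto(hit_keys[1, ], train_keys[1, ]), 0.8)
})

test_that("cross-referencing matches brute-force set logic", {
  l1 <- tibble::tibble(canonical_smiles = c("a", "b", "c"),
                       p_active = c(0.9, 0.8, 0.7))
  l2 <- tibble::tibble(canonical_smiles = c("b", "c", "d"),
                       p_active = c(0.95, 0.6, 0.55))
  l3 <- tibble::tibble(canonical_smiles = c("c"), p_active = 0.99)
  lists <- list(iso1 = l1, iso2 = l2, iso3 = l3)
  uni <- cross_reference(lists, "union")
  expect_setequal(uni$canonical_smiles, c("a", "b", "c", "d"))
  inter <- cross_reference(lists, "intersection")
  expect_equal(inter$canonical_smiles,
               Reduce(intersect, lapply(lists, `[[`, "canonical_smiles")))
  min2 <- cross_reference(lists, "min_k", k = 2)
  expect_setequal(min2$canonical_smiles, c("b", "c"))
  expect_equal(uni$p_iso1[uni$canonical_smiles == "a"], 0.9)
  expect_true(is.na(uni$p_iso2[uni$canonical_smiles == "a"]))
})

test_that("experimental comparison classifies the tested panel correctly", {
  exp_tbl <- tested_compounds()
  preds <- tibble::tibble(
    compound_id = c("cpd_1", "cpd_3", "cpd_8", "cpd_9"),
    isoform = c("hCA_I", "hCA_II", "hCA_I", "hCA_IX"),
    predicted = c("active", "inactive", "active", "inactive"))
  cmp <- compare_to_experiment(preds, exp_tbl)
  ag <- cmp$pairs$agreement[match(paste(preds$compound_id, preds$isoform),
                                  paste(cmp$pairs$compound_id,
                                        cmp$pairs$isoform))]
  # Ki 7.3 predicted active -> TP; censored >100000 inactive -> TN;
  # Ki 1204.8 (>1 uM) predicted active -> FP; Ki 728.5 inactive -> FN
  expect_equal(ag, c("TP", "TN", "FP", "FN"))
  expect_equal(cmp$summary$n, 4)
  expect_equal(cmp$summary$hit_rate, 0.5)
  # censored bound below the cutoff is excluded as uninformative
  cmp2 <- compare_to_experiment(
    tibble::tibble(compound_id = "x", isoform = "hCA_I",
                   predicted = "active"),
    tibble::tibble(compound_id = "x", isoform = "hCA_I", ki_nm = ">500"))
  expect_equal(nrow(cmp2$pairs), 0)
  expect_equal(nrow(cmp2$excluded), 1)
})

test_that("selectivity ratios reproduce the printed fold changes", {
  exp_tbl <- tested_compounds()
  sel <- selectivity_ratios(exp_tbl, "hCA_II")
  r7 <- sel[sel$compound_id == "cpd_7" & sel$isoform == "hCA_XII", ]
  expect_equal(r7$ratio, 350.9 / 9.8, tolerance = 1e-12)
  r1 <- sel[sel$compound_id == "cpd_1" & sel$isoform == "hCA_XII", ]
  expect_equal(round(r1$ratio, 1), 511.8)
  # identical Ki across isoforms gives unit ratios
  flat <- tibble::tibble(compound_id = "f",
                         isoform = c("hCA_I", "hCA_II", "hCA_IX"),
                         ki_nm = c("10", "10", "10"))
  sflat <- selectivity_ratios(flat, "hCA_II")
  expect_true(all(sflat$ratio == 1))
  # censored numerator propagates as a lower bound
  cens <- sel[sel$compound_id == "cpd_6" & sel$isoform == "hCA_I", ]
  expect_true(cens$lower_bound)
})
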