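# Dataset curation: from raw Ki activity records to labeled, deduplicated,
# stratified train/test sets.
#
# The pipeline mirrors standard bioactivity-QSAR practice for carbonic
# anhydrase inhibition data: exact-relation Ki records are filtered on
# structural integrity (MW <= 800 Da, >= 15 heavy atoms, organic-element
# whitelist), replicate measurements are reconciled with a 25%-deviation
# rule, activity is expressed as pKi, compounds inside a +/- 0.25 band
# around the isoform threshold are excluded, ">"-censored records are
# integrated as confident inactives, and the result is split 80/20 per
# class.

#' Default pKi classification thresholds per hCA isoform
#'
#' Medians of the curated pKi distributions for the four targeted isoforms,
#' used as binary-classification cutoffs with a +/- 0.25 exclusion band.
#'
#' @return Tibble with columns `isoform`, `threshold_pki`, `band`.
#' @export
hca_thresholds <- function() {
  tibble::tibble(
    isoform = c("hCA_I", "hCA_II", "hCA_IX", "hCA_XII"),
    threshold_pki = c(6.30, 7.30, 7.30, 7.45),
    band = 0.25)
}

#' Convert Ki in nM to pKi
#'
#' `pKi = -log10(Ki in molar) = 9 - log10(Ki in nM)`.
#'
#' @param ki_nm Positive Ki values in nM.
#' @return pKi values.
#' @examples
#' ki_to_pki(1000) # 6
#' @export
ki_to_pki <- function(ki_nm) {
  assert_that(all(is.finite(ki_nm) & ki_nm > 0),
              "ki_nm must be finite and positive")
  9 - log10(ki_nm)
}

#' Read a raw activity table
#'
#' Expects a delimited text file with a header containing the columns
#' `compound_id`, `smiles`, `standard_value_nm`, `standard_relation`,
#' `target` and optionally `source`.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @return Tibble of activity records.
#' @export
read_activity_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("compound_id", "smiles", "standard_value_nm",
            "standard_relation", "target")
  assert_that(all(need %in% names(df)),
              paste("missing columns:",
                    paste(setdiff(need, names(df)), collapse = ", ")))
  if (!"source" %in% names(df)) df$source <- NA_character_
  tibble::as_tibble(df)
}

#' Primary structural and assay filter
#'
#' Standardizes every record and retains those with relation `"="`,
#' molecular weight <= `max_mw`, at least `min_heavy` heavy atoms and only
#' whitelisted elements (H, B, C, N, O, F, P, S, Cl, Br, I). Records with a
#' `">"` relation are not errors: they are set aside for later integration
#' as censored inactives and reported separately.
#'
#' @param records Tibble with at least `compound_id`, `smiles`,
#'   `standard_value_nm`, `standard_relation`.
#' @param max_mw Maximum molecular weight in Da (default 800).
#' @param min_heavy Minimum heavy-atom count (default 15).
#' @param source_allow Optional character vector; when given, only records
#'   whose `source` is in the list are retained (assay-provenance filter).
#' @return List with tibbles `kept` (relation `"="` survivors, with
#'   standardization columns), `gt_pool` (relation `">"` survivors) and
#'   `drops` (record id, rule violated).
#' @export
primary_filter <- function(records, max_mw = 800, min_heavy = 15,
                           source_allow = NULL) {
  std <- standardize_smiles(records$smiles)
  rec <- dplyr::bind_cols(records,
                          std[setdiff(names(std), "raw_smiles")])
  reason <- rep(NA_character_, nrow(rec))
  reason[!rec$ok] <- rec$fail_reason[!rec$ok]
  bad_rel <- is.na(reason) &
    !rec$standard_relation %in% c("=", ">")
  reason[bad_rel] <- "unsupported relation"
  bad_ki <- is.na(reason) &
    (!is.finite(rec$standard_value_nm) | rec$standard_value_nm <= 0)
  reason[bad_ki] <- "non-positive activity value"
  idx <- is.na(reason) & rec$mol_weight > max_mw
  reason[idx] <- "molecular weight above limit"
  idx <- is.na(reason) & rec$num_heavy_atoms < min_heavy
  reason[idx] <- "too few heavy atoms"
  bad_elem <- is.na(reason) & !vapply(rec$elements, function(e) {
    all(e %in% ELEMENT_WHITELIST)
  }, logical(1))
  reason[bad_elem] <- "disallowed element"
  if (!is.null(source_allow)) {
    idx <- is.na(reason) & !(rec$source %in% source_allow)
    reason[idx] <- "source not in allow-list"
  }
  keep <- is.na(reason)
  list(kept = rec[keep & rec$standard_relation == "=", ],
       gt_pool = rec[keep & rec$standard_relation == ">", ],
       drops = tibble::tibble(compound_id = rec$compound_id[!keep],
                              smiles = rec$smiles[!keep],
                              reason = reason[!keep]))
}

#' Reconcile replicate Ki values for one compound
#'
#' Implements the 25%-deviation rule on Ki (nM): a single value is kept as
#' is; for two values the mean is used only when both deviate from it by
#' less than 25%, otherwise the compound is discarded; for three or more
#' values a single pass removes every value deviating by more than 25% from
#' the initial mean, and the mean of the survivors is used (the compound is
#' discarded when no value survives).
#'
#' @param ki_nm Numeric vector of replicate Ki values (nM).
#' @param max_dev Relative deviation limit (default 0.25); the boundary
#'   itself counts as "within".
#' @return The merged Ki, or `NA_real_` when the replicates are discordant.
#' @examples
#' resolve_duplicate_ki(c(100, 120)) # 110
#' resolve_duplicate_ki(c(100, 200)) # NA: both deviate by > 25%
#' @export
resolve_duplicate_ki <- function(ki_nm, max_dev = 0.25) {
  assert_that(all(ki_nm > 0), "Ki values must be positive")
  n <- length(ki_nm)
  if (n == 1) return(ki_nm)
  m <- mean(ki_nm)
  dev <- abs(ki_nm - m) / m
  if (n == 2) {
    if (all(dev < max_dev | abs(dev - max_dev) < 1e-12)) return(m)
    return(NA_real_)
  }
  survivors <- ki_nm[dev <= max_dev + 1e-12]
  if (length(survivors) == 0) return(NA_real_)
  mean(survivors)
}

#' Four-representation identity test between two structures
#'
#' Two standardized structures count as the same compound when all three
#' bit fingerprints agree exactly (Tanimoto 1) and the unscaled descriptor
#' vectors coincide (Euclidean distance below `tol`). By construction the
#' representations ignore stereochemistry, so enantiomer pairs are
#' identical here even though their canonical SMILES differ.
#'
#' @param a,b Canonical SMILES of standardized structures.
#' @param tol Euclidean tolerance on descriptors (default `1e-9`).
#' @return `TRUE` or `FALSE`.
#' @export
representation_identity <- function(a, b, tol = 1e-9) {
  for (r in c("circular", "path", "keys")) {
    fa <- featurize(a, r); fb <- featurize(b, r)
    if (!isTRUE(all.equal(unname(fa), unname(fb)))) return(FALSE)
  }
  da <- featurize(a, "physchem"); db <- featurize(b, "physchem")
  euclidean_dist(da[1, ], db[1, ]) <= tol
}

# Grouping key for duplicate detection: canonical SMILES of the
# stereo-stripped structure. Cheap bucket key; representation identity is
# the authoritative test inside buckets.
dedup_key <- function(canonical_smiles) {
  vapply(canonical_smiles, function(s) ob_canonical(strip_stereo(s)),
         character(1))
}

#' Collapse duplicate records to unique compounds
#'
#' Groups records whose structures are identical at representation level
#' and reconciles their Ki values with [resolve_duplicate_ki()]. Groups
#' whose replicates are discordant are discarded.
#'
#' @param records Tibble from `primary_filter()$kept` (standardized,
#'   relation `"="`).
#' @param verify_identity When `TRUE`, membership of multi-record buckets
#'   is confirmed with [representation_identity()] rather than trusted from
#'   the grouping key.
#' @return List of tibbles: `compounds` (one row per unique compound:
#'   `canonical_smiles`, `ki_nm`, `pki`, `n_records`, `provenance`) and
#'   `discarded` (discordant groups).
#' @export
resolve_duplicates <- function(records, verify_identity = FALSE) {
  assert_that(all(records$standard_relation == "="),
              "resolve_duplicates expects '=' records only")
  key <- dedup_key(records$canonical_smiles)
  groups <- split(seq_len(nrow(records)), key)
  if (verify_identity) {
    for (g in groups) {
      if (length(g) > 1) {
        rep_smi <- records$canonical_smiles[g]
        uniq <- unique(rep_smi)
        for (u in uniq[-1]) {
          assert_that(representation_identity(uniq[1], u),
                      "grouping key merged non-identical structures")
        }
      }
    }
  }
  rows <- lapply(groups, function(g) {
    ki <- resolve_duplicate_ki(records$standard_value_nm[g])
    tibble::tibble(
      canonical_smiles = records$canonical_smiles[g[1]],
      ki_nm = ki,
      n_records = length(g),
      provenance = paste(records$compound_id[g], collapse = ";"))
  })
  merged <- dplyr::bind_rows(rows)
  discarded <- merged[is.na(merged$ki_nm), ]
  compounds <- merged[!is.na(merged$ki_nm), ]
  compounds$pki <- ki_to_pki(compounds$ki_nm)
  list(compounds = compounds, discarded = discarded)
}

#' Label compounds against a pKi threshold with an exclusion band
#'
#' Compounds with `pki > threshold + band` are labeled `"active"`, those
#' with `pki < threshold - band` `"inactive"`; compounds inside the band
#' are excluded to avoid label ambiguity near the cutoff.
#'
#' @param compounds Tibble with a `pki` column.
#' @param threshold_pki Classification cutoff (pKi).
#' @param band Half-width of the exclusion interval (default 0.25).
#' @return List of tibbles `labeled` (with a `label` column) and
#'   `band_excluded`.
#' @export
label_compounds <- function(compounds, threshold_pki, band = 0.25) {
  assert_that(band >= 0, "band must be non-negative")
  in_band <- abs(compounds$pki - threshold_pki) <= band
  labeled <- compounds[!in_band, ]
  labeled$label <- ifelse(labeled$pki > threshold_pki, "active", "inactive")
  list(labeled = labeled, band_excluded = compounds[in_band, ])
}

#' Integrate censored (">") records as confident inactives
#'
#' A `">" Ki` record states a lower bound on Ki, i.e. an upper bound on
#' pKi. The compound is added as `"inactive"` only when that bound already
#' lies below the inactive boundary (`threshold - band`), so no band-zone
#' or potentially active compound can enter. Records structurally identical
#' to an already-present compound are dropped (uniqueness control).
#'
#' @param gt_records Tibble from `primary_filter()$gt_pool`.
#' @param existing Tibble of already-labeled compounds
#'   (`canonical_smiles`).
#' @param threshold_pki,band Classification cutoff and band.
#' @return Tibble of new inactive compounds (`canonical_smiles`,
#'   `pki_bound`, `label`, `provenance`).
#' @export
integrate_gt_inactives <- function(gt_records, existing, threshold_pki,
                                   band = 0.25) {
  if (nrow(gt_records) == 0) {
    return(tibble::tibble(canonical_smiles = character(),
                          pki_bound = numeric(), label = character(),
                          provenance = character()))
  }
  bound <- ki_to_pki(gt_records$standard_value_nm)
  informative <- bound < threshold_pki - band
  cand <- gt_records[informative, ]
  cand_bound <- bound[informative]
  if (nrow(cand) == 0) {
    return(tibble::tibble(canonical_smiles = character(),
                          pki_bound = numeric(), label = character(),
                          provenance = character()))
  }
  key <- dedup_key(cand$canonical_smiles)
  exist_key <- dedup_key(existing$canonical_smiles)
  keep1 <- !duplicated(key)
  cand <- cand[keep1, ]; cand_bound <- cand_bound[keep1]
  key <- key[keep1]
  new <- !(key %in% exist_key)
  tibble::tibble(canonical_smiles = cand$canonical_smiles[new],
                 pki_bound = cand_bound[new],
                 label = "inactive",
                 provenance = cand$compound_id[new])
}

#' Stratified train/test split
#'
#' Randomly assigns `train_fraction` of each class to the training set
#' (floor on the training side, remainder to test), reproducibly for a
#' given seed.
#'
#' @param labeled Tibble with a `label` column.
#' @param train_fraction Fraction per class in the training set
#'   (default 0.8).
#' @param seed Integer seed (mandatory).
#' @param min_class Minimum compounds per class (default 5).
#' @return List of tibbles `train` and `test`.
#' @export
stratified_split <- function(labeled, train_fraction = 0.8, seed,
                             min_class = 5) {
  counts <- table(labeled$label)
  assert_that(length(counts) == 2 && all(counts >= min_class),
              "insufficient class size")
  withr::with_seed(seed, {
    train_idx <- unlist(lapply(split(seq_len(nrow(labeled)), labeled$label),
                               function(ix) {
                                 n_tr <- floor(length(ix) * train_fraction)
                                 sample(ix, n_tr)
                               }))
  })
  train_idx <- sort(train_idx)
  list(train = labeled[train_idx, ],
       test = labeled[setdiff(seq_len(nrow(labeled)), train_idx), ])
}

#' Curate a raw activity table into a modeling dataset
#'
#' End-to-end curation for one isoform: primary filter, duplicate
#' resolution, pKi labeling with band exclusion, censored-inactive
#' integration and stratified 80/20 split.
#'
#' @param records Raw activity tibble (see [read_activity_table()]).
#' @param isoform Target tag; records are subset on `target == isoform`
#'   when a `target` column is present.
#' @param threshold_pki Cutoff; defaults to the packaged value for known
#'   isoforms ([hca_thresholds()]) and otherwise to the median pKi of the
#'   deduplicated compounds.
#' @param band Exclusion half-width (default 0.25).
#' @param train_fraction Training fraction per class (default 0.8).
#' @param seed Integer seed for the split.
#' @param source_allow Optional assay-provenance allow-list.
#' @return An object of class `iso_dataset`: list with `isoform`,
#'   `threshold_pki`, `band`, tibbles `train` and `test`, and a `report`
#'   list of per-stage counts.
#' @export
curate_activity <- function(records, isoform, threshold_pki = NULL,
                            band = 0.25, train_fraction = 0.8, seed = 1,
                            source_allow = NULL) {
  if ("target" %in% names(records)) {
    records <- records[records$target == isoform, ]
  }
  assert_that(nrow(records) > 0, "no records for isoform")
  pf <- primary_filter(records, source_allow = source_allow)
  dedup <- resolve_duplicates(pf$kept)
  if (is.null(threshold_pki)) {
    known <- hca_thresholds()
    hit <- match(isoform, known$isoform)
    threshold_pki <- if (!is.na(hit)) known$threshold_pki[hit] else
      stats::median(dedup$compounds$pki)
  }
  lab <- label_compounds(dedup$compounds, threshold_pki, band)
  gt <- integrate_gt_inactives(pf$gt_pool, lab$labeled, threshold_pki, band)
  full <- dplyr::bind_rows(
    lab$labeled[, c("canonical_smiles", "pki", "label", "provenance")],
    tibble::tibble(canonical_smiles = gt$canonical_smiles,
                   pki = NA_real_, label = gt$label,
                   provenance = gt$provenance))
  full$pki_bound <- c(rep(NA_real_, nrow(lab$labeled)), gt$pki_bound)
  sp <- stratified_split(full, train_fraction, seed)
  report <- list(
    n_input = nrow(records),
    n_primary_kept = nrow(pf$kept),
    n_gt_pool = nrow(pf$gt_pool),
    drops = pf$drops,
    n_unique = nrow(dedup$compounds),
    n_discordant = nrow(dedup$discarded),
    n_band_excluded = nrow(lab$band_excluded),
    n_gt_integrated = nrow(gt),
    n_active = sum(full$label == "active"),
    n_inactive = sum(full$label == "inactive"))
  structure(list(isoform = isoform, threshold_pki = threshold_pki,
                 band = band, train = sp$train, test = sp$test,
                 report = report),
            class = "iso_dataset")
}

#' @export
print.iso_dataset <- function(x, ...) {
  cat("<iso_dataset>", x$isoform,
      sprintf("threshold pKi %.2f (+/- %.2f)\n", x$threshold_pki, x$band))
  cat(sprintf("  train: %d (%d active / %d inactive)\n", nrow(x$train),
              sum(x$train$label == "active"),
              sum(x$train$label == "inactive")))
  cat(sprintf("  test:  %d (%d active / %d inactive)\n", nrow(x$test),
              sum(x$test$label == "active"),
              sum(x$test$label == "inactive")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a curated dataset into one row per compound
#'
#' @param x An `iso_dataset`.
#' @param ... Unused.
#' @return Tibble with `canonical_smiles`, `pki`, `label`, `split`.
#' @method tidy iso_dataset
#' @export
tidy.iso_dataset <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$train, split = "train"),
    dplyr::mutate(x$test, split = "test"))
}

#' One-row summary of a curated dataset
#'
#' @param x An `iso_dataset`.
#' @param ... Unused.
#' @return One-row tibble of curation funnel counts.
#' @method glance iso_dataset
#' @export
glance.iso_dataset <- function(x, ...) {
  r <- x$report
  tibble::tibble(isoform = x$isoform, threshold_pki = x$threshold_pki,
                 n_input = r$n_input, n_primary_kept = r$n_primary_kept,
                 n_unique = r$n_unique, n_band_excluded = r$n_band_excluded,
                 n_gt_integrated = r$n_gt_integrated,
                 n_active = r$n_active, n_inactive = r$n_inactive,
                 n_train = nrow(x$train), n_test = nrow(x$test))
}

#' Plot the pKi distribution of a curated dataset
#'
#' Histogram of pKi with the classification threshold and exclusion band.
#'
#' @param object An `iso_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iso_dataset
#' @export
autoplot.iso_dataset <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$pki), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pki, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = object$threshold_pki,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$threshold_pki +
                          c(-1, 1) * object$band,
                        linetype = "dotted") +
    ggplot2::labs(x = "pKi", y = "compounds",
                  title = paste0(object$isoform, " curated dataset")) +
    ggplot2::theme_minimal()
}
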