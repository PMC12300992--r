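# Virtual-screening cascade, isoform cross-referencing and
# prediction-vs-experiment bookkeeping.
#
# Screening retains compounds predicted active with probability >= 0.5,
# then pushes them through an ordered filter cascade: substructure alerts
# (PAINS/Brenk/BMS/Inpharmatica/NIBR SMARTS collections shipped as text
# files), drug-likeness property rules (Lipinski, Veber), pluggable
# predicates (e.g. an external toxicity service) and allow-lists
# (commercial availability). A novelty filter removes hits too similar
# (Tanimoto > 0.80 on the 881-bit keys) to the model's training set.

#' Screen a compound library with a trained model
#'
#' Standardizes the library, predicts activity probabilities and retains
#' compounds at or above the probability cutoff, sorted by descending
#' probability (ties broken by canonical SMILES).
#'
#' @param model An `iso_model`.
#' @param library Character vector of raw SMILES, or a data frame with a
#'   `smiles` column.
#' @param prob_cutoff Retention threshold (default 0.5).
#' @return Tibble of hits: `canonical_smiles`, `p_active`, `isoform`.
#'   Unparsable library entries are dropped with a warning.
#' @export
screen <- function(model, library, prob_cutoff = 0.5) {
  if (is.data.frame(library)) library <- library$smiles %||%
      library$canonical_smiles
  if (length(library) == 0) {
    warning("empty screening library")
    return(tibble::tibble(canonical_smiles = character(),
                          p_active = numeric(), isoform = character()))
  }
  std <- standardize_smiles(library)
  if (any(!std$ok)) {
    warning(sum(!std$ok), " library entries failed standardization")
  }
  smi <- unique(std$canonical_smiles[std$ok])
  pred <- stats::predict(model, smi)
  hits <- pred[pred$p_active >= prob_cutoff, ]
  hits <- hits[order(-hits$p_active, hits$canonical_smiles), ]
  tibble::tibble(canonical_smiles = hits$canonical_smiles,
                 p_active = hits$p_active,
                 isoform = model$isoform)
}

# ---------------------------------------------------------------------------
# Alert sets

#' Load a structural-alert SMARTS collection
#'
#' The package ships small curated subsets of the widely used alert
#' collections (PAINS, Brenk, BMS, Inpharmatica, NIBR) as plain-text SMARTS
#' files under `extdata/alerts`; they are representative selections
#' assembled for this package, not the complete published rule sets. Each
#' pattern is validated against the SMARTS engine at load time.
#'
#' @param set Collection name (`"pains"`, `"brenk"`, `"bms"`,
#'   `"inpharmatica"`, `"nibr"`) or ignored when `path` is given.
#' @param path Optional path to a user-supplied SMARTS file (lines of
#'   `SMARTS<TAB>name`, `#` comments).
#' @return Tibble with columns `name` and `smarts`.
#' @export
load_alerts <- function(set = c("pains", "brenk", "bms", "inpharmatica",
                                "nibr"), path = NULL) {
  if (is.null(path)) {
    set <- match.arg(set)
    path <- system.file("extdata", "alerts", paste0(set, "_subset.smarts"),
                        package = "isoscreen")
    assert_that(nzchar(path), paste("alert set not installed:", set))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  out <- tibble::tibble(
    smarts = vapply(parts, `[`, character(1), 1),
    name = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                  character(1)))
  probe <- sdf_from_smiles("CCO")
  for (i in seq_len(nrow(out))) {
    ok <- tryCatch({
      ChemmineR::smartsSearchOB(probe, out$smarts[i], uniqueMatches = TRUE)
      TRUE
    }, error = function(e) FALSE)
    assert_that(ok, paste("malformed SMARTS in alert set:", out$smarts[i]))
  }
  out
}

# ---------------------------------------------------------------------------
# Filter stages

new_filter <- function(name, fun) {
  structure(list(name = name, fun = fun), class = "iso_filter")
}

#' Structural-alert filter stage
#'
#' A compound passes when none of the collection's SMARTS patterns match.
#'
#' @param set,path As in [load_alerts()].
#' @param name Stage name (defaults to the set name).
#' @return An `iso_filter` for [filter_cascade()].
#' @export
filter_alerts <- function(set = "pains", path = NULL, name = NULL) {
  alerts <- load_alerts(set, path)
  name <- name %||% if (is.null(path)) set else basename(path)
  new_filter(name, function(smiles) {
    fail <- rep(FALSE, length(smiles))
    for (i in seq_len(nrow(alerts))) {
      fail <- fail | smarts_matches(smiles, alerts$smarts[i]) > 0
    }
    !fail
  })
}

#' Lipinski rule-of-five filter stage
#'
#' Violations counted over MW <= 500 Da, logP <= 5, H-bond donors <= 5 and
#' H-bond acceptors <= 10. The default admits only compounds with zero
#' violations; set `max_violations = 1` for the common relaxed variant.
#'
#' @param max_violations Allowed violation count (default 0).
#' @return An `iso_filter`.
#' @export
filter_lipinski <- function(max_violations = 0) {
  new_filter("lipinski", function(smiles) {
    pr <- ob_properties(smiles)
    v <- (as.numeric(pr$MW) > 500) + (as.numeric(pr$logP) > 5) +
      (as.numeric(pr$HBD) > 5) + (as.numeric(pr$HBA1) > 10)
    v <= max_violations
  })
}

#' Veber filter stage
#'
#' Rotatable bonds <= 10 and TPSA <= 140 A^2.
#'
#' @param max_rotatable,max_tpsa Rule limits.
#' @return An `iso_filter`.
#' @export
filter_veber <- function(max_rotatable = 10, max_tpsa = 140) {
  new_filter("veber", function(smiles) {
    pr <- ob_properties(smiles)
    rot <- vapply(smiles, function(s) count_rotatable(mol_graph(s)),
                  integer(1))
    rot <= max_rotatable & as.numeric(pr$TPSA) <= max_tpsa
  })
}

#' Pluggable predicate filter stage
#'
#' Wraps an arbitrary compound predicate (for example an external toxicity
#' predictor) as a cascade stage. The shipped default is an always-pass
#' stub.
#'
#' @param name Stage name.
#' @param fn Function mapping a character vector of canonical SMILES to a
#'   logical pass vector; default passes everything.
#' @return An `iso_filter`.
#' @export
filter_predicate <- function(name = "predicate",
                             fn = function(smiles) rep(TRUE,
                                                       length(smiles))) {
  new_filter(name, fn)
}

#' Allow-list filter stage
#'
#' Retains only compounds whose canonical SMILES appears in a user-supplied
#' list (e.g. commercially available molecules).
#'
#' @param allowed Character vector of canonical SMILES.
#' @param name Stage name.
#' @return An `iso_filter`.
#' @export
filter_allowlist <- function(allowed, name = "allowlist") {
  allowed <- unique(allowed)
  new_filter(name, function(smiles) smiles %in% allowed)
}

#' Apply an ordered filter cascade to screening hits
#'
#' Stages run in order; a compound eliminated at stage k is marked
#' `"skipped"` for all later stages. The result keeps one trace column per
#' stage (`"pass"`, `"fail"`, `"skipped"`) and a funnel attribute with
#' per-stage survivor counts.
#'
#' @param hits Tibble with a `canonical_smiles` column (e.g. from
#'   [screen()]).
#' @param stages List of `iso_filter` objects; the empty list is the
#'   identity.
#' @return Tibble of surviving hits (trace columns included), with
#'   attributes `funnel` (tibble: stage, n_in, n_out) and `trace` (full
#'   input tibble with trace columns).
#' @export
filter_cascade <- function(hits, stages = list()) {
  assert_that(all(vapply(stages, inherits, logical(1), "iso_filter")),
              "stages must be iso_filter objects")
  trace <- hits
  alive <- rep(TRUE, nrow(hits))
  funnel <- list()
  for (st in stages) {
    res <- rep("skipped", nrow(hits))
    if (any(alive)) {
      pass <- st$fun(hits$canonical_smiles[alive])
      res[alive] <- ifelse(pass, "pass", "fail")
    }
    n_in <- sum(alive)
    alive <- alive & res == "pass"
    trace[[paste0("trace_", st$name)]] <- res
    funnel[[length(funnel) + 1L]] <- tibble::tibble(
      stage = st$name, n_in = n_in, n_out = sum(alive))
  }
  out <- trace[alive, ]
  attr(out, "funnel") <- dplyr::bind_rows(funnel)
  attr(out, "trace") <- trace
  out
}

#' Per-stage survivor counts of a cascade result
#'
#' @param cascaded Result of [filter_cascade()].
#' @return Tibble with `stage`, `n_in`, `n_out`.
#' @export
cascade_funnel <- function(cascaded) {
  attr(cascaded, "funnel")
}

#' Remove hits too similar to the training set
#'
#' Computes the maximum Tanimoto similarity of each hit to the model's
#' training compounds on the 881-bit key fingerprints and removes hits
#' whose maximum exceeds the threshold (strictly greater; a hit at exactly
#' the threshold is retained).
#'
#' @param hits Tibble with `canonical_smiles`.
#' @param train_keys Binary matrix of training-set key fingerprints (an
#'   `iso_model$train_keys`), or an `iso_model`.
#' @param max_similarity Threshold (default 0.80).
#' @return `hits` restricted to novel compounds, with a
#'   `max_train_similarity` column appended.
#' @export
novelty_filter <- function(hits, train_keys, max_similarity = 0.80) {
  if (inherits(train_keys, "iso_model")) train_keys <- train_keys$train_keys
  if (nrow(hits) == 0) {
    hits$max_train_similarity <- numeric(0)
    return(hits)
  }
  H <- featurize(hits$canonical_smiles, "keys")
  sims <- tanimoto_matrix(H, train_keys)
  m <- apply(sims, 1, max)
  out <- hits[m <= max_similarity, ]
  out$max_train_similarity <- m[m <= max_similarity]
  out
}

# ---------------------------------------------------------------------------
# Cross-isoform profiling

#' Cross-reference per-isoform hit lists into activity profiles
#'
#' Joins the hit lists of several isoform-specific screens by canonical
#' structure. Modes: `"union"` keeps compounds hit by any model,
#' `"intersection"` only those hit by all, `"min_k"` those hit by at least
#' `k` models.
#'
#' @param hit_lists Named list of hit tibbles (`canonical_smiles`,
#'   `p_active`), one per isoform.
#' @param mode Join mode (default `"union"`).
#' @param k Minimum number of isoforms for `mode = "min_k"`.
#' @return Tibble with one row per compound: per-isoform probability
#'   columns `p_<isoform>`, logical columns `active_<isoform>` and
#'   `n_active_isoforms`.
#' @export
cross_reference <- function(hit_lists, mode = c("union", "intersection",
                                                "min_k"), k = 2) {
  mode <- match.arg(mode)
  assert_that(length(hit_lists) >= 2 && !is.null(names(hit_lists)),
              "need a named list of >= 2 hit tibbles")
  all_smiles <- sort(unique(unlist(lapply(hit_lists,
                                          `[[`, "canonical_smiles"))))
  out <- tibble::tibble(canonical_smiles = all_smiles)
  for (iso in names(hit_lists)) {
    h <- hit_lists[[iso]]
    idx <- match(all_smiles, h$canonical_smiles)
    out[[paste0("p_", iso)]] <- h$p_active[idx]
    out[[paste0("active_", iso)]] <- !is.na(idx)
  }
  act_cols <- paste0("active_", names(hit_lists))
  out$n_active_isoforms <- rowSums(as.matrix(out[act_cols]))
  need <- switch(mode, union = 1, intersection = length(hit_lists),
                 min_k = k)
  out[out$n_active_isoforms >= need, ]
}

# ---------------------------------------------------------------------------
# Experimental comparison

# Parse Ki entries that may be censored (">100000" or "> 100 000").
parse_ki <- function(x) {
  x <- gsub("[, ]", "", as.character(x))
  censored <- startsWith(x, ">")
  val <- suppressWarnings(as.numeric(sub("^>", "", x)))
  tibble::tibble(ki_nm = val, censored = censored)
}

#' Compare predicted labels with experimental Ki measurements
#'
#' A (compound, isoform) pair is experimentally active when its Ki lies
#' below the activity cutoff (1 uM by default). Censored values `">X"`
#' with `X >= cutoff` are confidently inactive; censored values below the
#' cutoff are uninformative and excluded. Each usable pair is classed
#' TP/TN/FP/FN against the predicted label, and the hit rate is the
#' fraction of concordant pairs.
#'
#' @param predictions Tibble with `compound_id`, `isoform`, `predicted`
#'   (`"active"`/`"inactive"`).
#' @param experimental Tibble with `compound_id`, `isoform`, `ki_nm`
#'   (numeric or censored string).
#' @param activity_cutoff_nm Experimental activity cutoff (default 1000).
#' @return List: `pairs` (per-pair tibble with `agreement` class),
#'   `summary` (one-row tibble: tp, tn, fp, fn, n, hit_rate),
#'   `excluded` (uninformative censored pairs).
#' @export
compare_to_experiment <- function(predictions, experimental,
                                  activity_cutoff_nm = 1000) {
  ki <- parse_ki(experimental$ki_nm)
  exp_tbl <- dplyr::bind_cols(
    experimental[, c("compound_id", "isoform")], ki)
  exp_tbl$exp_label <- ifelse(
    !exp_tbl$censored,
    ifelse(exp_tbl$ki_nm < activity_cutoff_nm, "active", "inactive"),
    ifelse(exp_tbl$ki_nm >= activity_cutoff_nm, "inactive",
           NA_character_))
  excluded <- exp_tbl[is.na(exp_tbl$exp_label), ]
  usable <- exp_tbl[!is.na(exp_tbl$exp_label), ]
  pairs <- dplyr::inner_join(usable, predictions,
                             by = c("compound_id", "isoform"))
  pairs$agreement <- dplyr::case_when(
    pairs$exp_label == "active" & pairs$predicted == "active" ~ "TP",
    pairs$exp_label == "inactive" & pairs$predicted == "inactive" ~ "TN",
    pairs$exp_label == "inactive" & pairs$predicted == "active" ~ "FP",
    TRUE ~ "FN")
  counts <- table(factor(pairs$agreement, levels = c("TP", "TN", "FP",
                                                     "FN")))
  n <- nrow(pairs)
  summary <- tibble::tibble(
    tp = as.integer(counts["TP"]), tn = as.integer(counts["TN"]),
    fp = as.integer(counts["FP"]), fn = as.integer(counts["FN"]),
    n = n, hit_rate = if (n > 0) (counts[["TP"]] + counts[["TN"]]) / n else
      NA_real_)
  list(pairs = pairs, summary = summary, excluded = excluded)
}

#' Isoform selectivity ratios
#'
#' Fold-change of Ki against every other isoform relative to a reference
#' isoform: `ratio = Ki(other) / Ki(reference)`; values above 1 mean the
#' compound is more potent on (selective for) the reference. Censored Ki
#' values (`">X"`) enter as bounds and flag the resulting ratio as a lower
#' bound.
#'
#' @param experimental Tibble with `compound_id`, `isoform`, `ki_nm`.
#' @param reference_isoform Reference isoform tag.
#' @return Tibble: `compound_id`, `isoform`, `ki_reference_nm`,
#'   `ki_other_nm`, `ratio`, `lower_bound`, and the per-compound minimum
#'   ratio over the other isoforms (`min_ratio`).
#' @export
selectivity_ratios <- function(experimental, reference_isoform) {
  ki <- parse_ki(experimental$ki_nm)
  tbl <- dplyr::bind_cols(experimental[, c("compound_id", "isoform")], ki)
  ref <- tbl[tbl$isoform == reference_isoform, ]
  oth <- tbl[tbl$isoform != reference_isoform, ]
  out <- dplyr::inner_join(
    oth,
    ref[, c("compound_id", "ki_nm", "censored")],
    by = "compound_id", suffix = c("_other", "_ref"))
  assert_that(nrow(out) > 0, "reference isoform absent from the table")
  out$ratio <- out$ki_nm_other / out$ki_nm_ref
  out$lower_bound <- out$censored_other & !out$censored_ref
  res <- tibble::tibble(compound_id = out$compound_id,
                        isoform = out$isoform,
                        ki_reference_nm = out$ki_nm_ref,
                        ki_other_nm = out$ki_nm_other,
                        ratio = out$ratio,
                        lower_bound = out$lower_bound)
  res <- dplyr::group_by(res, .data$compound_id)
  res <- dplyr::mutate(res, min_ratio = min(.data$ratio))
  dplyr::ungroup(res)
}

#' Experimentally tested compound panel
#'
#' The packaged Ki table (nM) of the twelve experimentally assayed
#' virtual-screening candidates plus the acetazolamide (AAZ) reference
#' inhibitor, across hCA I, II, IX and XII. Censored entries are recorded
#' as `">100000"`.
#'
#' @return Tibble with `compound_id`, `isoform`, `ki_nm` (character).
#' @export
tested_compounds <- function() {
  path <- system.file("extdata", "tested_compounds_ki.csv",
                      package = "isoscreen")
  assert_that(nzchar(path), "packaged Ki table missing")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(ki_nm = "character")))
}
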