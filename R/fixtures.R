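# Synthetic bioactivity data with known ground truth.
#
# The generator assembles drug-like molecules from benzenoid scaffold
# templates decorated with small substituents; activity is governed by a
# planted zinc-binding motif (a primary sulfonamide, the dominant carbonic
# anhydrase inhibitor chemotype). Activity tables emulate a ChEMBL-style Ki
# extract: replicate measurements with multiplicative noise, discordant
# replicate clusters, compounds inside the classification band, censored
# ">" records, and a few records that violate the structural filters. A
# manifest records the intended curation fate of every compound so the
# whole pipeline can be checked against ground truth.

PLANTED_GROUP <- "S(N)(=O)=O"

fixture_templates <- function() {
  c("c1cc{2}cc{3}c1Cc1ccc{1}cc1",
    "c1cc{2}cc{3}c1Oc1ccc{1}cc1",
    "c1cc{2}cc{3}c1-c1ccc{1}cc1",
    "c1cc{2}cc{3}c1CCc1ccc{1}cc1",
    "O=C(Nc1ccc{1}cc1)c1cc{2}cc{3}c1",
    "c1cc{2}cc{3}c1NC(=O)c1ccc{1}cc1")
}

fixture_template_heavy <- c(13L, 13L, 12L, 14L, 15L, 15L)

fixture_substituents <- function() {
  c("" , "Cl", "F", "C", "CC", "CCC", "OC", "OCC", "O", "N(C)C",
    "C(=O)OC", "C#N", "C(F)(F)F", "NC(C)=O", "C(C)C")
}

substituent_heavy <- function(s) {
  if (!nzchar(s)) return(0L)
  n <- nchar(gsub("[^A-Z#]", "", gsub("Cl", "X", s)))
  as.integer(n - lengths(regmatches(s, gregexpr("#", s))))
}

fill_template <- function(tpl, s1, s2, s3) {
  br <- function(s) if (nzchar(s)) paste0("(", s, ")") else ""
  out <- sub("{1}", br(s1), tpl, fixed = TRUE)
  out <- sub("{2}", br(s2), out, fixed = TRUE)
  sub("{3}", br(s3), out, fixed = TRUE)
}

# Draw n unique decorated molecules; actives carry the planted group at
# slot 1. Returns tibble(smiles, active, n_heavy_est).
draw_molecules <- function(n, active, min_heavy = 15,
                           exclude = character(0)) {
  tpls <- fixture_templates()
  subs <- fixture_substituents()
  planted_heavy <- 4L
  seen <- exclude
  out <- character(0)
  guard <- 0
  while (length(out) < n && guard < n * 200) {
    guard <- guard + 1
    ti <- sample.int(length(tpls), 1)
    s1 <- if (active) PLANTED_GROUP else sample(subs[subs != ""], 1)
    s23 <- sample(subs, 2, replace = TRUE)
    heavy <- fixture_template_heavy[ti] +
      (if (active) planted_heavy else substituent_heavy(s1)) +
      sum(vapply(s23, substituent_heavy, integer(1)))
    if (heavy < min_heavy) next
    smi <- fill_template(tpls[ti], s1, s23[1], s23[2])
    # Uniqueness is decided on the canonical form: the two meta slots are
    # symmetry-equivalent, so different fills can name the same molecule.
    can <- ob_canonical(smi)
    if (!nzchar(can) || can %in% seen) next
    seen <- c(seen, can)
    out <- c(out, can)
  }
  assert_that(length(out) == n, "could not draw enough unique molecules")
  out
}

dup_cluster_factor <- function(k) if (k == 2L) 2.2 else 1.8

#' Generate a synthetic activity table with a ground-truth manifest
#'
#' Emulates a raw Ki extract for one isoform. Compounds are drawn from the
#' scaffold templates; molecules carrying the planted primary-sulfonamide
#' motif receive Ki values from the active regime and the rest from the
#' inactive regime, with pKi regimes kept clear of the classification band.
#' A configurable share of compounds is emitted as replicate clusters
#' (multiplicative log-normal noise, both concordant and planted-discordant
#' clusters of size 2 and 3), as band-zone compounds, and as censored `">"`
#' records (both informative and uninformative). A handful of
#' filter-violating records (too few heavy atoms, salt forms, invalid
#' SMILES) exercise the primary filter.
#'
#' @param n_compounds Number of base compounds (>= 20; default 200).
#' @param duplicate_fraction Fraction emitted as replicate clusters
#'   (default 0.2).
#' @param band_fraction Fraction planted inside the exclusion band
#'   (default 0.05).
#' @param gt_fraction Fraction of additional censored `">"` records
#'   relative to `n_compounds` (default 0.1).
#' @param noise_cv Log-scale standard deviation of replicate noise
#'   (default 0.1).
#' @param discordant_fraction Fraction of replicate clusters planted as
#'   discordant (one value inflated 2.2x; default 0.25).
#' @param active_fraction Fraction of base compounds in the active regime
#'   (default 0.45).
#' @param isoform Isoform tag (default `"hCA_II"`, threshold pKi 7.30).
#' @param seed Integer seed (mandatory).
#' @return List with `records` (tibble shaped like a raw activity table)
#'   and `manifest` (tibble: `smiles`, `canonical_smiles`, `fate`,
#'   `final_label`, `merged_ki_nm`). Fates are `kept`, `band_excluded`,
#'   `discordant_discarded`, `gt_integrated`, `gt_uninformative`,
#'   `dropped_filter`.
#' @export
generate_activity_table <- function(n_compounds = 200,
                                    duplicate_fraction = 0.2,
                                    band_fraction = 0.05,
                                    gt_fraction = 0.1,
                                    noise_cv = 0.1,
                                    discordant_fraction = 0.25,
                                    active_fraction = 0.45,
                                    isoform = "hCA_II",
                                    seed) {
  assert_that(n_compounds >= 20, "n_compounds must be >= 20")
  assert_that(!missing(seed), "seed is mandatory")
  thr <- hca_thresholds()
  hit <- match(isoform, thr$isoform)
  assert_that(!is.na(hit), "unknown isoform tag")
  threshold <- thr$threshold_pki[hit]
  band <- thr$band[hit]
  withr::with_seed(seed, {
    n_band <- round(n_compounds * band_fraction)
    n_act <- round((n_compounds - n_band) * active_fraction)
    n_inact <- n_compounds - n_band - n_act
    smi_act <- draw_molecules(n_act + n_band, active = TRUE)
    smi_band <- smi_act[seq_len(n_band)]
    smi_act <- smi_act[-seq_len(n_band)]
    smi_inact <- draw_molecules(n_inact, active = FALSE)
    rpki <- function(n, centre, lower, upper) {
      x <- stats::rnorm(n, centre, 0.45)
      pmin(pmax(x, lower + 0.05), upper - 0.05)
    }
    pki <- c(rpki(n_act, threshold + 1.0, threshold + band, threshold + 2.5),
             rpki(n_inact, threshold - 1.3, threshold - 2.8, threshold - band),
             stats::runif(n_band, threshold - band + 0.02,
                          threshold + band - 0.02))
    base <- tibble::tibble(
      smiles = c(smi_act, smi_inact, smi_band),
      true_ki_nm = 10^(9 - pki),
      planted_band = c(rep(FALSE, n_act + n_inact), rep(TRUE, n_band)))
    base <- base[sample.int(nrow(base)), ]

    # Replicate clusters
    n_dup <- round(n_compounds * duplicate_fraction)
    dup_idx <- sample.int(nrow(base), n_dup)
    cluster_size <- sample(c(2L, 3L), n_dup, replace = TRUE)
    discordant <- stats::runif(n_dup) < discordant_fraction &
      !base$planted_band[dup_idx]
    records <- list()
    manifest <- list()
    rec_id <- 0
    emit <- function(smiles, ki, relation = "=") {
      rec_id <<- rec_id + 1
      records[[length(records) + 1L]] <<- tibble::tibble(
        compound_id = sprintf("SYN%05d", rec_id), smiles = smiles,
        standard_value_nm = ki, standard_relation = relation,
        target = isoform, source = "synthetic")
    }
    dup_rank <- match(seq_len(nrow(base)), dup_idx)
    for (i in seq_len(nrow(base))) {
      smi <- base$smiles[i]
      ki <- base$true_ki_nm[i]
      r <- dup_rank[i]
      if (is.na(r)) {
        emit(smi, ki)
        merged <- ki
        fate_extra <- "single"
      } else {
        k <- cluster_size[r]
        reps <- ki * exp(stats::rnorm(k, 0, noise_cv))
        if (discordant[r]) reps[1] <- reps[1] * dup_cluster_factor(k)
        for (v in reps) emit(smi, v)
        merged <- resolve_duplicate_ki(reps)
        fate_extra <- if (discordant[r] && k == 2) "discordant" else "cluster"
      }
      if (is.na(merged)) {
        fate <- "discordant_discarded"; final <- NA_character_
      } else {
        mpki <- ki_to_pki(merged)
        if (abs(mpki - threshold) <= band) {
          fate <- "band_excluded"; final <- NA_character_
        } else {
          fate <- "kept"
          final <- if (mpki > threshold) "active" else "inactive"
        }
      }
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        smiles = smi, fate = fate, final_label = final,
        merged_ki_nm = merged, cluster = fate_extra)
    }

    # Censored ">" records: informative (large bound) and uninformative.
    n_gt <- round(n_compounds * gt_fraction)
    if (n_gt > 0) {
      smi_gt <- draw_molecules(n_gt, active = FALSE, exclude = base$smiles)
      informative <- stats::runif(n_gt) < 0.7
      for (i in seq_len(n_gt)) {
        # Informative bounds lie well below the inactive boundary; the
        # uninformative ones (e.g. ">10 nM") bound pKi from above inside or
        # beyond the band, so they cannot be assigned a class.
        bound <- if (informative[i]) sample(c(10000, 50000, 100000), 1) else
          sample(c(10, 50), 1)
        emit(smi_gt[i], bound, relation = ">")
        manifest[[length(manifest) + 1L]] <- tibble::tibble(
          smiles = smi_gt[i],
          fate = if (informative[i]) "gt_integrated" else "gt_uninformative",
          final_label = if (informative[i]) "inactive" else NA_character_,
          merged_ki_nm = NA_real_, cluster = "gt")
      }
    }

    # Filter-violating records.
    bad <- tibble::tibble(
      smiles = c("c1ccc(S(N)(=O)=O)cc1",          # 11 heavy atoms
                 "CCCCCCCC", "C1CC"),             # small chain; invalid
      ki = c(5, 5000, 100))
    for (i in seq_len(nrow(bad))) {
      emit(bad$smiles[i], bad$ki[i])
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        smiles = bad$smiles[i], fate = "dropped_filter",
        final_label = NA_character_, merged_ki_nm = NA_real_,
        cluster = "bad")
    }
    records <- dplyr::bind_rows(records)
    manifest <- dplyr::bind_rows(manifest)
  })
  manifest$canonical_smiles <- vapply(manifest$smiles, function(s) {
    std <- standardize_smiles(s)
    if (std$ok) std$canonical_smiles else NA_character_
  }, character(1))
  list(records = records, manifest = manifest,
       threshold_pki = threshold, band = band, isoform = isoform)
}

#' Generate a perfectly separable labeled library
#'
#' Balanced compound set whose activity label is exactly the presence of
#' the planted primary-sulfonamide motif: the acceptance surface for
#' model-recovery and attribution checks.
#'
#' @param n Total number of compounds (even; default 400).
#' @param seed Integer seed.
#' @return Tibble with `canonical_smiles` and `label`.
#' @export
generate_separable_library <- function(n = 400, seed) {
  assert_that(!missing(seed), "seed is mandatory")
  assert_that(n >= 4, "n too small")
  n_act <- floor(n / 2)
  withr::with_seed(seed, {
    smi <- c(draw_molecules(n_act, active = TRUE),
             draw_molecules(n - n_act, active = FALSE))
    ord <- sample.int(n)
  })
  std <- standardize_smiles(smi)
  assert_that(all(std$ok), "generator produced an unparsable SMILES")
  out <- tibble::tibble(
    canonical_smiles = std$canonical_smiles,
    label = c(rep("active", n_act), rep("inactive", n - n_act)))
  out[ord, ]
}

#' Atom indices of the primary-sulfonamide motif
#'
#' Locates S(=O)(=O)NH2 groups in the molecular graph: a sulfur bonded to
#' two terminal double-bonded oxygens and a terminal nitrogen. Used to
#' compare attribution weights on the planted motif against the rest of
#' the molecule.
#'
#' @param smiles Canonical SMILES.
#' @return Integer vector of atom indices (possibly empty).
#' @export
sulfonamide_atoms <- function(smiles) {
  g <- mol_graph(smiles)
  assert_that(!is.null(g), "invalid structure")
  out <- integer(0)
  for (s in which(g$elem == "S")) {
    nbrs <- g$adj[[s]]
    o2 <- nbrs[g$elem[nbrs] == "O" & g$degree[nbrs] == 1]
    nn <- nbrs[g$elem[nbrs] == "N" & g$degree[nbrs] == 1]
    if (length(o2) >= 2 && length(nn) >= 1) {
      out <- c(out, s, o2[1:2], nn[1])
    }
  }
  sort(unique(out))
}
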