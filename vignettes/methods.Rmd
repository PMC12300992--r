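---
title: "Methods: isoform-specific profiling of carbonic anhydrase inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-specific profiling of carbonic anhydrase inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Human carbonic anhydrases (hCAs) are zinc metalloenzymes whose isoforms
(here hCA I, II, IX and XII) are so structurally similar that designing an
inhibitor selective for one of them is a central medicinal-chemistry
challenge. `isoscreen` implements a complete ligand-based machine-learning
platform for this problem: it curates Ki bioactivity tables into binary
classification datasets per isoform, trains classifiers on several
molecular representations, screens compound libraries through a
multi-filter cascade, profiles hits across isoforms, and explains
individual predictions at atom level.

# Data curation

An activity record is one assay measurement: a SMILES, a Ki in nM, a
relation symbol (`=` exact, `>` censored), an isoform tag and a source tag.
Curation proceeds in fixed stages, each of which only removes (or, for
censored records, adds) compounds:

1. **Standardization.** The largest organic fragment is kept (ties broken
   by molecular weight; all-inorganic inputs are rejected), and the
   survivor is canonicalized with Open Babel. Stereochemistry is retained
   in the canonical SMILES but plays no role downstream.
2. **Primary filter.** Kept are `=`-relation records with molecular weight
   at most 800 Da, at least 15 heavy atoms, and only the elements
   H, B, C, N, O, F, P, S, Cl, Br, I. An optional source allow-list mirrors
   restricting to a single laboratory's assays. `>`-relation records are
   set aside for later reintegration.
3. **Duplicate resolution.** Records are grouped by stereo-agnostic
   canonical structure and confirmed identical under all four molecular
   representations (Tanimoto 1 on the three fingerprints, Euclidean 0 on
   descriptors) — the representation-level test is what matters, because
   enantiomers collide there and would otherwise inject contradictory
   labels. Replicate Ki values are reconciled with a 25% deviation rule on
   the nM scale: one value passes through; two values are averaged only if
   both deviate from their mean by less than 25%, otherwise the compound is
   discarded; with three or more values a *single* pass removes values
   deviating by more than 25% from the initial mean and the survivors are
   averaged. The single-pass reading (rather than iterating to a fixed
   point) is the simplest one consistent with a one-shot exclusion rule; a
   deviation of exactly 25% counts as "within" in both branches.
4. **Labeling.** Ki is converted to pKi (`pKi = 9 - log10(Ki[nM])`).
   Compounds above `threshold + 0.25` are active, below `threshold - 0.25`
   inactive, and those inside the ±0.25 band are excluded as
   label-ambiguous. Default thresholds ship per isoform (hCA I 6.30,
   hCA II 7.30, hCA IX 7.30, hCA XII 7.45); for new targets the median of
   the pKi distribution is used.
5. **Censored integration.** A `>` record bounds pKi from above; it becomes
   a confident inactive only when that bound already lies below
   `threshold - band`, so no band-zone compound can re-enter through the
   back door. A uniqueness control drops censored records whose structure
   already exists in the dataset.
6. **Split.** A stratified random 80/20 train/test split per class,
   reproducible from the seed.

# Molecular representations

Four representations are computed from the canonical connection table, so
any two SMILES of one molecule — including enantiomer pairs — map to
identical vectors:

* **circular** (2048 bits): a Morgan-style circular fingerprint, radius 2,
  binary. Atom environments of radius 0–2 are hashed; each environment
  records its atom set, so every on-bit can be mapped back to atoms for
  the attribution module. Initial atom invariants combine element, degree,
  charge, implicit-hydrogen count and ring membership.
* **path** (2048 bits): linear paths of 1–5 bonds, hashed with a canonical
  direction rule.
* **keys** (881 bits): a substructure-key fingerprint over a fixed,
  recorded dictionary defined by this package (element-count thresholds,
  ring counts and sizes, degree counts, bonded element pairs, atom triads)
  in the spirit of the classic 881-key public dictionaries. The contract is
  the recorded dictionary, not any external key set.
* **physchem** (26 descriptors): Open Babel properties (MW, logP, TPSA,
  molar refractivity, H-bond donors/acceptors) plus connectivity-derived
  counts (rings, rotatable bonds, element counts, and so on). Descriptors
  are min–max scaled to [0, 1] **on the training set only**; constant
  features map to 0 and out-of-sample values are deliberately not clipped.
  Fitting the scaler on all data would leak test information, so the
  train-only choice is fixed even though it may shift results slightly
  relative to pipelines that scale everything at once. The scaler records
  the descriptor-name list and refuses a mismatched matrix.

Similarity uses the Tanimoto coefficient `tn = j/(k + m - j)` on on-bit
counts (two empty fingerprints are defined as similarity 0), and Euclidean
distance on descriptor vectors.

# Models

Four algorithms × four representations. SVM and Gaussian-process models go
through kernlab; the Tanimoto coefficient, a valid positive semi-definite
kernel on bit vectors, is supplied as a precomputed Gram matrix (SVM) or a
kernel function (GP). The SVM kernel menu is linear, polynomial (degree 2
and 3), RBF, sigmoid and Tanimoto; the GP menu is dot-product, RBF and
Tanimoto (the package's kernel menu — other stationary families are not
offered by the backend). The random forest uses `randomForest`; KNN is a
small exact implementation so that the Jaccard distance (1 − Tanimoto) can
be used on bit vectors and Euclidean distance on descriptors. All models
output an activity probability; SVM probabilities come from Platt-style
calibration with internal cross-validation (the calibrated route was chosen
over a decision-function mapping because downstream screening consumes
probabilities at an absolute 0.5 cutoff).

Hyperparameter search is an exhaustive grid evaluated by 5-fold stratified
cross-validation with mean MCC as the score; ties go to the earliest
(simplest) grid row. The robustness protocol is 10 repeated stratified
80/20 Monte-Carlo splits of the training set — this mirrors a "10-fold CV"
described as repeated random 80/20 partitions; a classic disjoint-fold mode
is available behind `mode = "kfold"`. MCC is the primary score because it
uses all four confusion-matrix cells and is robust to class imbalance;
undefined fold scores (zero denominators) are excluded from means with a
warning rather than silently zeroed.

Every stochastic element (splits, fold assignment, forest growth,
calibration) flows from one recorded seed. Training rows are sorted
canonically before fitting so the fit is a pure function of the compound
*set*: probability calibration partitions data in row order, and without a
canonical order, shuffling rows would perturb probabilities.

# Virtual screening

Screening standardizes a library, predicts probabilities and retains
compounds at or above 0.5, ranked by probability. Survivors then pass an
ordered cascade, each stage only removing compounds and every compound
keeping a replayable pass/fail/skipped trace:

* **Structural alerts**: PAINS, Brenk, BMS, Inpharmatica and NIBR
  collections as SMARTS files shipped with the package. These are small
  curated representative subsets written for this package, not the full
  published rule sets, so survivor counts on real libraries will differ
  from any external tool's.
* **Drug-likeness**: Lipinski (MW ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10) with
  zero violations by default (configurable to the common ≤ 1 variant), and
  Veber (rotatable bonds ≤ 10, TPSA ≤ 140). The rotatable-bond count is
  the classic acyclic-single-bond definition without the amide exception.
* **Pluggable predicates** for external services (e.g. toxicity
  prediction); an always-pass stub ships for tests. **Allow-lists** cover
  commercial availability and literature-derived selections.
* **Novelty**: a hit is removed when its maximum Tanimoto similarity to
  the model's training set, on the 881-bit keys, is strictly greater than
  0.80 (a hit at exactly 0.80 is retained). The filter is applied
  per-isoform against that model's own training set.

Cross-referencing joins per-isoform hit lists by canonical structure with
union / intersection / at-least-k modes. The experimental-comparison step
labels a (compound, isoform) pair active when the measured Ki is below
1 µM, treats censored values `>X` with X at or above the cutoff as
confident inactives and excludes censored values below it as
uninformative, classes each pair TP/TN/FP/FN against the prediction, and
reports the hit rate (TP+TN)/n. Selectivity ratios are fold-changes
`Ki(other)/Ki(reference)`; censored numerators propagate as lower bounds.

# Atom-level explanation

Per-bit contributions use a permutation Shapley estimator implemented in
the package: for each background fingerprint and each sampled permutation
(walked forward and backward), features are switched one at a time from the
background value to the molecule's value and the marginal probability
changes accumulate. Features equal in molecule and background contribute
exactly zero and are skipped without breaking the telescoping sum, so the
additivity identity `sum(phi) + base = p(molecule)` holds to machine
precision for every walk and therefore for the average. The default
background is a seed-controlled sample of training compounds.

Bit contributions are retro-mapped to atoms for the circular
representation: each on-bit's footprint is the union of the atom
environments hashing to it (hash collisions merged — a bit's evidence is
its full structural footprint), and

```
w(a) = ( sum over on-bits f covering a of phi_f / |atoms(f)| ) / r(a)
```

where `r(a)` is the number of distinct on-bits covering atom `a`. The two
normalizations could be composed in either order; the footprint-first
order above is the default and the alternative is available via
`order = "occurrence_first"` for sensitivity analysis. All on-bits are
mapped (no |phi| cutoff). Atoms covered by no on-bit have weight exactly
0, and when the on-bits partition the atom set the atom weights conserve
the total bit contribution. Depictions colour atoms on a diverging scale
(orange positive, blue negative) with a numeric CSV sidecar.

# Synthetic data

The generator is first-class, tested code that emulates the curation input
and provides a separable acceptance surface. Molecules are assembled from
six benzenoid scaffold templates (diphenylmethane, diphenyl ether,
biphenyl, bibenzyl and two benzamides) with up to three small
substituents; uniqueness is decided on canonical SMILES because two of the
substituent slots are symmetry-equivalent ring positions. Activity is
governed by a planted primary sulfonamide — the dominant zinc-binding
carbonic-anhydrase-inhibitor chemotype — so the ground truth is a known
substructure rule. Active-regime pKi values centre about one log unit
above the hCA II threshold (7.30) and inactive-regime values further
below, both truncated clear of the ±0.25 band; planted band compounds sit
strictly inside it. Replicate clusters of size 2 and 3 receive
multiplicative log-normal noise (log-sd 0.1); planted discordant clusters
use inflation factors chosen so the 2-cluster exercises the discard branch
and the 3-cluster the outlier-exclusion branch of the 25% rule. Censored
records are emitted with informative bounds (10–100 µM) and uninformative
ones (10–50 nM), plus a few filter-violating records. A manifest records
every compound's intended fate, which the curation pipeline must
reproduce exactly.

What the fixtures do *not* emulate: real medicinal-chemistry diversity,
assay noise structure beyond log-normal replicates, activity cliffs, or
ChEMBL's property distributions. Passing the model-recovery criteria shows
the machinery can learn a planted substructure rule essentially perfectly;
it says nothing about attainable accuracy on real bioactivity data, where
published models of this kind reach MCC around 0.7–0.8.

# Problem sizes and numerical choices

The shipped tests run the curation oracle at 500 compounds, model recovery
on a balanced 400-compound library (320/80 split), the novelty oracle at
200 compounds, kernel validity on fifty 30×2048 matrices, and attribution
checks with 8-background single-permutation explanations — sizes chosen so
the whole suite exercises every claim in a few minutes on a single core.
Fingerprint hashing uses a fixed polynomial rolling hash with a prime
modulus below 2^24 (exactly representable in doubles), so fingerprints are
platform-independent. Tanimoto of two empty fingerprints is 0 by
definition; metric denominators of zero yield NA, never a silent 0; the
25% duplicate rule treats the exact boundary as "keep"; Gram matrices are
validated against a −1e−8 eigenvalue floor.

# Known limitations

* SMILES parsing, canonicalization, logP/TPSA and SMARTS matching follow
  Open Babel's models and will differ in detail from other toolkits;
  fingerprints follow this package's recorded algorithms, not any external
  implementation's bit assignments.
* The 881-key dictionary is package-defined; similarities computed with it
  are internally consistent but not comparable to external key sets.
* Alert sets are representative subsets; funnel counts are not comparable
  to runs with the full published collections.
* Implicit-hydrogen counts come from a standard-valence model; exotic
  valences outside the element whitelist are not guaranteed.
* The permutation SHAP estimator is exact in its additivity but sampled in
  its attribution; per-bit values stabilize with more permutations and
  backgrounds at linear cost.
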