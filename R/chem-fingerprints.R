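# The four molecular representations.
#
# - "circular": 2048-bit hashed circular fingerprint (Morgan algorithm,
#   radius 2, binary), with a retrievable bit -> atom-environment map used
#   by the attribution module.
# - "path": 2048-bit hashed linear-path fingerprint (paths of 1..5 bonds).
# - "keys": 881-bit substructure-key fingerprint over a fixed, recorded
#   dictionary of element counts, ring features, degree counts, bonded
#   element pairs and atom triads (a PubChem-style key set defined by this
#   package).
# - "physchem": continuous physicochemical descriptor vector (Open Babel
#   properties plus connectivity-derived counts), min-max scaled downstream.
#
# All representations are pure functions of the canonical (stereo-agnostic)
# connection table, so two SMILES of the same molecule -- including
# enantiomers -- map to identical vectors.

REPR_IDS <- c("circular", "path", "keys", "physchem")

repr_length <- function(repr_id) {
  switch(repr_id, circular = 2048L, path = 2048L, keys = 881L,
         physchem = length(physchem_descriptor_names()),
         stop("unknown representation: ", repr_id, call. = FALSE))
}

elem_code <- function(elem) {
  codes <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
             Cl = 17, Br = 35, I = 53)
  out <- codes[elem]
  out[is.na(out)] <- 99
  unname(out)
}

# ---------------------------------------------------------------------------
# Circular fingerprint (Morgan, radius 2)

# Returns list(bits = sorted on-bit indices (1-based), atom_map = named list
# bit -> list of atom-index vectors (the environments hashed to that bit)).
circular_fp_one <- function(g, nbits = 2048L, radius = 2L) {
  codes <- elem_code(g$elem)
  inv <- vapply(seq_len(g$n), function(a) {
    hash_ints(c(codes[a], g$degree[a], g$charge[a] + 10, g$n_h[a],
                as.integer(g$ring_atom[a])))
  }, numeric(1))
  env_atoms <- as.list(seq_len(g$n))
  features <- list()
  add_feature <- function(f, atoms) {
    bit <- as.integer(f %% nbits) + 1L
    features[[length(features) + 1L]] <<- list(bit = bit, atoms = sort(atoms))
  }
  order_lookup <- matrix(0L, g$n, g$n)
  if (nrow(g$bonds) > 0) {
    order_lookup[cbind(g$bonds$a1, g$bonds$a2)] <- g$bonds$order
    order_lookup[cbind(g$bonds$a2, g$bonds$a1)] <- g$bonds$order
  }
  bond_order_to <- function(a, b) order_lookup[a, b]
  for (a in seq_len(g$n)) add_feature(inv[a], a)
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- numeric(g$n)
    nxt_env <- vector("list", g$n)
    for (a in seq_len(g$n)) {
      nbrs <- g$adj[[a]]
      if (length(nbrs) == 0) {
        nxt[a] <- hash_ints(c(r, cur[a]))
        nxt_env[[a]] <- env_atoms[[a]]
      } else {
        pairs <- vapply(nbrs, function(b) bond_order_to(a, b) * 1e7 + cur[b],
                        numeric(1))
        ord <- order(pairs)
        nxt[a] <- hash_ints(c(r, cur[a], as.vector(rbind(
          vapply(nbrs[ord], function(b) bond_order_to(a, b), numeric(1)),
          cur[nbrs[ord]]))))
        nxt_env[[a]] <- sort(unique(c(env_atoms[[a]],
                                      unlist(env_atoms[nbrs]))))
      }
      add_feature(nxt[a], nxt_env[[a]])
    }
    cur <- nxt
    env_atoms <- nxt_env
  }
  bits <- sort(unique(vapply(features, function(f) f$bit, integer(1))))
  atom_map <- vector("list", length(bits))
  names(atom_map) <- as.character(bits)
  for (f in features) {
    k <- as.character(f$bit)
    envs <- atom_map[[k]]
    dup <- any(vapply(envs, function(e) identical(e, f$atoms), logical(1)))
    if (!dup) atom_map[[k]] <- c(envs, list(f$atoms))
  }
  list(bits = bits, atom_map = atom_map)
}

# ---------------------------------------------------------------------------
# Path fingerprint

path_fp_one <- function(g, nbits = 2048L, max_len = 5L) {
  codes <- elem_code(g$elem)
  order_lookup <- matrix(0L, g$n, g$n)
  if (nrow(g$bonds) > 0) {
    order_lookup[cbind(g$bonds$a1, g$bonds$a2)] <- g$bonds$order
    order_lookup[cbind(g$bonds$a2, g$bonds$a1)] <- g$bonds$order
  }
  seen_paths <- new.env(parent = emptyenv())
  features <- list()
  emit <- function(path) {
    fwd_key <- paste(path, collapse = ",")
    rev_key <- paste(rev(path), collapse = ",")
    if (!is.null(seen_paths[[fwd_key]]) || !is.null(seen_paths[[rev_key]]))
      return(invisible())
    seen_paths[[fwd_key]] <- TRUE
    k <- length(path) - 1L
    seq_fwd <- integer(2L * length(path) - 1L)
    seq_fwd[seq(1, length(seq_fwd), by = 2)] <- codes[path]
    if (k > 0) {
      ords <- vapply(seq_len(k), function(i) {
        order_lookup[path[i], path[i + 1]]
      }, integer(1))
      seq_fwd[seq(2, length(seq_fwd), by = 2)] <- ords
    }
    seq_rev <- rev(seq_fwd)
    canon <- if (paste(seq_fwd, collapse = ",") <=
                 paste(seq_rev, collapse = ",")) seq_fwd else seq_rev
    f <- hash_ints(c(k, canon))
    bit <- as.integer(f %% nbits) + 1L
    features[[length(features) + 1L]] <<- list(bit = bit, atoms = sort(path))
  }
  dfs <- function(path) {
    emit(path)
    if (length(path) > max_len) return(invisible())
    tip <- path[length(path)]
    for (b in g$adj[[tip]]) {
      if (!(b %in% path)) dfs(c(path, b))
    }
  }
  for (a in seq_len(g$n)) dfs(a)
  bits <- sort(unique(vapply(features, function(f) f$bit, integer(1))))
  atom_map <- vector("list", length(bits))
  names(atom_map) <- as.character(bits)
  for (f in features) {
    k <- as.character(f$bit)
    envs <- atom_map[[k]]
    dup <- any(vapply(envs, function(e) identical(e, f$atoms), logical(1)))
    if (!dup) atom_map[[k]] <- c(envs, list(f$atoms))
  }
  list(bits = bits, atom_map = atom_map)
}

# ---------------------------------------------------------------------------
# 881-bit substructure keys

# The dictionary is generated once, in a fixed order, and truncated to
# exactly 881 entries. Each entry is (kind, a, b, c, threshold).
keys_dictionary <- function() {
  hit <- cache_get("keys_dict")
  if (!is.null(hit)) return(hit)
  elems <- c("B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
  rows <- list()
  add <- function(kind, a = "", b = "", c = "", t = 1L) {
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, a = a, b = b,
                                             c = c, t = t)
  }
  counts <- list(C = c(1, 2, 4, 8, 12, 16, 20, 24, 28, 32, 36, 40),
                 N = c(1:8, 10), O = c(1:8, 10, 12, 14), S = 1:6,
                 F = c(1:4, 6, 8), Cl = 1:6, Br = 1:3, I = 1:2, P = 1:3,
                 B = 1:2)
  for (e in names(counts)) for (t in counts[[e]]) add("elem_count", e, t = t)
  for (t in 1:10) add("ring_count", t = t)
  for (t in c(3, 5, 6, 8, 10, 12, 14, 16, 18, 20)) add("ring_atoms", t = t)
  for (s in 3:12) add("ring_size", t = s)
  for (d in 1:4) for (t in c(1, 2, 4, 8, 12)) add("degree_count", a = d, t = t)
  add("degree_count", a = 5, t = 1)
  pairs <- t(utils::combn(elems, 2))
  pairs <- rbind(pairs, cbind(elems, elems))
  for (i in seq_len(nrow(pairs))) {
    for (o in 1:3) add("bond_pair", pairs[i, 1], pairs[i, 2], o, t = 1L)
  }
  for (i in seq_len(nrow(pairs))) {
    add("bond_pair", pairs[i, 1], pairs[i, 2], 1, t = 2L)
  }
  for (b in elems) {
    for (i in seq_len(nrow(pairs))) {
      add("triad", pairs[i, 1], b, pairs[i, 2], t = 1L)
    }
  }
  dict <- do.call(rbind, rows)
  assert_that(nrow(dict) >= 881L, "key dictionary shorter than 881")
  dict <- dict[seq_len(881L), ]
  rownames(dict) <- NULL
  i <- dict$kind == "bond_pair"
  attr(dict, "bp_keys") <- paste(pmin(dict$a[i], dict$b[i]),
                                 pmax(dict$a[i], dict$b[i]),
                                 dict$c[i], sep = "|")
  i <- dict$kind == "triad"
  attr(dict, "triad_keys") <- paste(pmin(dict$a[i], dict$c[i]), dict$b[i],
                                    pmax(dict$a[i], dict$c[i]), sep = "|")
  cache_set("keys_dict", dict)
}

keys_fp_one <- function(g) {
  dict <- keys_dictionary()
  elem_tab <- table(g$elem)
  deg_tab <- table(g$degree)
  pair_key <- character(0)
  pair_count <- integer(0)
  if (nrow(g$bonds) > 0) {
    e1 <- g$elem[g$bonds$a1]; e2 <- g$elem[g$bonds$a2]
    lo <- pmin(e1, e2); hi <- pmax(e1, e2)
    pk <- paste(lo, hi, g$bonds$order, sep = "|")
    tab <- table(pk)
    pair_key <- names(tab); pair_count <- as.integer(tab)
  }
  triad_parts <- lapply(seq_len(g$n), function(b) {
    nbrs <- g$adj[[b]]
    if (length(nbrs) < 2) return(NULL)
    cmb <- utils::combn(nbrs, 2)
    ea <- g$elem[cmb[1, ]]; ec <- g$elem[cmb[2, ]]
    paste(pmin(ea, ec), g$elem[b], pmax(ea, ec), sep = "|")
  })
  triads <- unique(unlist(triad_parts))
  ring_size_set <- unique(g$ring_sizes)
  n_ring_atoms <- sum(g$ring_atom)
  lookup_count <- function(tab, keys) {
    out <- as.integer(tab[keys])
    out[is.na(out)] <- 0L
    out
  }
  on <- logical(nrow(dict))
  k <- dict$kind
  i <- k == "elem_count"
  on[i] <- lookup_count(elem_tab, dict$a[i]) >= dict$t[i]
  on[k == "ring_count"] <- g$n_rings >= dict$t[k == "ring_count"]
  on[k == "ring_atoms"] <- n_ring_atoms >= dict$t[k == "ring_atoms"]
  on[k == "ring_size"] <- dict$t[k == "ring_size"] %in% ring_size_set
  i <- k == "degree_count"
  on[i] <- lookup_count(deg_tab, dict$a[i]) >= dict$t[i]
  i <- k == "bond_pair"
  bp_idx <- match(attr(dict, "bp_keys"), pair_key)
  if (length(pair_count) == 0) {
    on[i] <- FALSE
  } else {
    on[i] <- !is.na(bp_idx) &
      pair_count[ifelse(is.na(bp_idx), 1L, bp_idx)] >= dict$t[i]
  }
  on[k == "triad"] <- attr(dict, "triad_keys") %in% triads
  list(bits = which(on), atom_map = NULL)
}

# ---------------------------------------------------------------------------
# Physicochemical descriptors

#' Descriptor names of the physicochemical representation
#'
#' The ordered list of descriptors computed by
#' `featurize(..., repr = "physchem")`. Scalers record this list and refuse
#' to be applied to a mismatched one.
#'
#' @return Character vector of descriptor names.
#' @export
physchem_descriptor_names <- function() {
  c("mol_weight", "logp", "tpsa", "molar_refractivity", "hbd", "hba",
    "n_fluorine", "n_heavy", "n_carbon", "n_nitrogen", "n_oxygen",
    "n_sulfur", "n_halogen", "n_phosphorus", "n_rings", "n_ring_atoms",
    "n_rotatable", "n_bonds", "n_double_bonds", "n_triple_bonds",
    "n_branch_atoms", "frac_heteroatoms", "mean_degree", "max_ring_size",
    "n_charged_atoms", "total_h_count")
}

physchem_one <- function(g, props) {
  halogens <- c("F", "Cl", "Br", "I")
  c(mol_weight = as.numeric(props[["MW"]]),
    logp = as.numeric(props[["logP"]]),
    tpsa = as.numeric(props[["TPSA"]]),
    molar_refractivity = as.numeric(props[["MR"]]),
    hbd = as.numeric(props[["HBD"]]),
    hba = as.numeric(props[["HBA1"]]),
    n_fluorine = sum(g$elem == "F"),
    n_heavy = g$n,
    n_carbon = sum(g$elem == "C"),
    n_nitrogen = sum(g$elem == "N"),
    n_oxygen = sum(g$elem == "O"),
    n_sulfur = sum(g$elem == "S"),
    n_halogen = sum(g$elem %in% halogens),
    n_phosphorus = sum(g$elem == "P"),
    n_rings = g$n_rings,
    n_ring_atoms = sum(g$ring_atom),
    n_rotatable = count_rotatable(g),
    n_bonds = nrow(g$bonds),
    n_double_bonds = sum(g$bonds$order == 2),
    n_triple_bonds = sum(g$bonds$order == 3),
    n_branch_atoms = sum(g$degree >= 3),
    frac_heteroatoms = mean(g$elem != "C"),
    mean_degree = mean(g$degree),
    max_ring_size = if (g$n_rings > 0) max(g$ring_sizes) else 0,
    n_charged_atoms = sum(g$charge != 0),
    total_h_count = sum(g$n_h))
}

# ---------------------------------------------------------------------------
# Public featurization surface

#' Featurize standardized structures
#'
#' Computes one of the four molecular representations for a vector of
#' canonical SMILES. Bit representations are returned as a binary matrix;
#' the physicochemical representation as a numeric matrix with named
#' columns (unscaled; see [fit_scaler()]).
#'
#' @param smiles Character vector of canonical SMILES (see
#'   [standardize_smiles()]).
#' @param repr One of `"circular"`, `"path"`, `"keys"`, `"physchem"`.
#' @return Numeric matrix, one row per molecule, with attributes `repr_id`
#'   and (for `"physchem"`) `descriptor_names`.
#' @export
featurize <- function(smiles, repr = c("circular", "path", "keys",
                                       "physchem")) {
  repr <- match.arg(repr)
  graphs <- lapply(smiles, mol_graph)
  bad <- vapply(graphs, is.null, logical(1))
  assert_that(!any(bad),
              paste("invalid structure at position", which(bad)[1]))
  if (repr == "physchem") {
    props <- ob_properties(smiles)
    X <- t(vapply(seq_along(graphs), function(i) {
      physchem_one(graphs[[i]], props[i, , drop = FALSE])
    }, numeric(length(physchem_descriptor_names()))))
    colnames(X) <- physchem_descriptor_names()
    attr(X, "repr_id") <- "physchem"
    attr(X, "descriptor_names") <- physchem_descriptor_names()
    return(X)
  }
  len <- repr_length(repr)
  X <- matrix(0L, nrow = length(smiles), ncol = len)
  for (i in seq_along(graphs)) {
    X[i, fp_bits(smiles[i], graphs[[i]], repr)] <- 1L
  }
  attr(X, "repr_id") <- repr
  X
}

# On-bit indices for one molecule under a bit representation (memoised).
fp_bits <- function(smi, g, repr) {
  key <- paste0("fp:", repr, ":", smi)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit$bits)
  res <- switch(repr,
                circular = circular_fp_one(g),
                path = path_fp_one(g),
                keys = keys_fp_one(g))
  cache_set(key, res)
  res$bits
}

#' Map circular-fingerprint bits to atom environments
#'
#' For every on-bit of the 2048-bit circular fingerprint of a molecule,
#' returns the atom-index sets of the environments (centre atom plus
#' neighbourhood of radius 0-2) that hash to that bit. Several environments
#' may share a bit (hash collisions); all are reported.
#'
#' @param smiles One canonical SMILES string.
#' @param repr Bit representation; only `"circular"` and `"path"` carry an
#'   atom map, and attribution supports `"circular"` only.
#' @return Named list: bit index (as character) -> list of integer atom
#'   vectors (1-based, heavy atoms only).
#' @export
map_bits_to_atoms <- function(smiles, repr = "circular") {
  assert_that(repr %in% c("circular", "path"),
              "atom maps exist for bit representations only")
  g <- mol_graph(smiles)
  assert_that(!is.null(g), "invalid structure")
  fp_bits(smiles, g, repr)     # ensure cached
  cache_get(paste0("fp:", repr, ":", smiles))$atom_map
}

# ---------------------------------------------------------------------------
# Min-max scaler for the physicochemical representation

#' Fit a min-max scaler on training descriptor rows
#'
#' Each feature is mapped linearly so that the training data spans `[0, 1]`.
#' Constant features map to 0. The scaler records the descriptor-name list
#' and refuses application to a mismatched matrix. Out-of-sample values are
#' deliberately not clipped, so applied values may fall outside `[0, 1]`.
#'
#' @param X Numeric matrix (>= 2 rows) of unscaled descriptors.
#' @return An object of class `iso_scaler`.
#' @export
fit_scaler <- function(X) {
  assert_that(is.matrix(X) && nrow(X) >= 2, "fit_scaler needs >= 2 rows")
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max),
                 descriptor_names = colnames(X)),
            class = "iso_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler An `iso_scaler` from [fit_scaler()].
#' @param X Numeric matrix with the same columns the scaler was fitted on.
#' @return The scaled matrix (unclipped).
#' @export
apply_scaler <- function(scaler, X) {
  assert_that(inherits(scaler, "iso_scaler"), "not an iso_scaler")
  assert_that(ncol(X) == length(scaler$min), "descriptor width mismatch")
  if (!is.null(scaler$descriptor_names) && !is.null(colnames(X))) {
    assert_that(identical(colnames(X), scaler$descriptor_names),
                "descriptor list mismatch between scaler and data")
  }
  rng <- scaler$max - scaler$min
  out <- sweep(X, 2, scaler$min, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out
}
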