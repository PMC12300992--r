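# Structure standardization and the internal molecular-graph representation.
#
# SMILES parsing, canonicalization, 2D coordinates, physicochemical
# properties and SMARTS matching are delegated to Open Babel through
# ChemmineOB/ChemmineR. Everything downstream (fingerprints, descriptors
# derived from connectivity) works on the light-weight graph built here.

ELEMENT_WHITELIST <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# Default valences used to infer implicit hydrogen counts from a kekulized
# connection table. Positive formal charge raises the valence (e.g. N+ -> 4),
# negative lowers it. Hypervalent S/P (sulfone, phosphate) carry no implicit
# H because their bond-order sum already exceeds the default.
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                     Cl = 1, Br = 1, I = 1, H = 1)

ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, text),
                  error = function(e) "")
  out
}

# Canonical SMILES of a single-component SMILES string; "" when unparsable.
ob_canonical <- function(smiles) {
  key <- paste0("can:", smiles)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  out <- ob_convert("SMI", "CAN", smiles)
  out <- sub("[\t\n ].*$", "", out)
  cache_set(key, out)
}

strip_stereo <- function(smiles) {
  gsub("[@/\\\\]", "", smiles)
}

# TRUE when a SMILES string contains carbon (two-letter element symbols
# starting with C are masked first so "Cl" is not mistaken for carbon).
contains_carbon <- function(smiles) {
  grepl("[Cc]", gsub("Cl|Ca|Cd|Cu|Co|Cr|Cs|Ce", "", smiles))
}

#' Standardize raw SMILES strings
#'
#' Applies the salt-stripping and integrity rules used throughout the
#' pipeline: the input is split into disconnected components, the organic
#' component (containing carbon) with the most heavy atoms is kept (ties go
#' to the higher molecular weight), and the survivor is canonicalized.
#' Inputs that do not parse are flagged `"invalid structure"`; inputs with
#' no organic component are flagged `"no organic fragment"`.
#'
#' @param smiles Character vector of raw SMILES.
#' @return A tibble with one row per input: `raw_smiles`,
#'   `canonical_smiles`, `num_heavy_atoms`, `mol_weight`, `elements`
#'   (list-column of element symbols), `ok` and `fail_reason`.
#' @examples
#' standardize_smiles(c("CCO", "CCO.[Na+].[Cl-]"))
#' @export
standardize_smiles <- function(smiles) {
  assert_that(is.character(smiles) && length(smiles) >= 1,
              "smiles must be a non-empty character vector")
  rows <- lapply(smiles, standardize_one)
  dplyr::bind_rows(rows)
}

standardize_one <- function(raw) {
  fail <- function(reason) {
    tibble::tibble(raw_smiles = raw, canonical_smiles = NA_character_,
                   num_heavy_atoms = NA_integer_, mol_weight = NA_real_,
                   elements = list(character()), ok = FALSE,
                   fail_reason = reason)
  }
  if (is.na(raw) || !nzchar(trimws(raw))) return(fail("invalid structure"))
  frags <- strsplit(trimws(raw), ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  cans <- vapply(frags, ob_canonical, character(1))
  if (any(!nzchar(cans))) return(fail("invalid structure"))
  organic <- vapply(cans, contains_carbon, logical(1))
  if (!any(organic)) return(fail("no organic fragment"))
  cand <- unique(cans[organic])
  graphs <- lapply(cand, mol_graph)
  if (any(vapply(graphs, is.null, logical(1)))) return(fail("invalid structure"))
  heavy <- vapply(graphs, function(g) g$n, integer(1))
  mw <- vapply(graphs, function(g) g$mol_weight, numeric(1))
  ord <- order(-heavy, -mw)
  g <- graphs[[ord[1]]]
  tibble::tibble(raw_smiles = raw, canonical_smiles = g$canonical_smiles,
                 num_heavy_atoms = g$n, mol_weight = g$mol_weight,
                 elements = list(sort(unique(g$elem))), ok = TRUE,
                 fail_reason = NA_character_)
}

#' Table-first wrapper around [standardize_smiles()]
#'
#' @param data A data frame holding a SMILES column.
#' @param smiles Column (tidy-eval) containing raw SMILES; default `smiles`.
#' @return `data` with the standardization columns appended.
#' @export
standardize_structures <- function(data, smiles = smiles) {
  raw <- dplyr::pull(data, {{ smiles }})
  std <- standardize_smiles(raw)
  dplyr::bind_cols(data, std[setdiff(names(std), "raw_smiles")])
}

# ---------------------------------------------------------------------------
# Molecular graph

# Parse one canonical SMILES into a graph. Memoised. Returns NULL on failure.
mol_graph <- function(canonical_smiles) {
  key <- paste0("mol:", canonical_smiles)
  hit <- cache_get(key)
  if (!is.null(hit)) return(if (is.logical(hit)) NULL else hit)
  sdfstr <- ob_convert("SMI", "SDF", canonical_smiles)
  if (!nzchar(sdfstr)) {
    cache_set(key, NA)
    return(NULL)
  }
  g <- tryCatch(graph_from_molblock(sdfstr, canonical_smiles),
                error = function(e) NULL)
  if (is.null(g)) {
    cache_set(key, NA)
    return(NULL)
  }
  cache_set(key, g)
}

graph_from_molblock <- function(sdfstr, canonical_smiles) {
  lines <- strsplit(sdfstr, "\n", fixed = TRUE)[[1]]
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n_all <- length(elem)
  coords <- ab[, 1:2, drop = FALSE]
  if (is.null(dim(bb)) || nrow(ab) == 0) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  charge <- integer(n_all)
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
    k <- toks[1]
    for (i in seq_len(k)) {
      charge[toks[2 * i]] <- toks[2 * i + 1]
    }
  }
  # Fold explicit hydrogens into their heavy neighbour.
  extra_h <- integer(n_all)
  is_h <- elem == "H"
  if (any(is_h)) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      if (is_h[a1] && !is_h[a2]) extra_h[a2] <- extra_h[a2] + 1L
      if (is_h[a2] && !is_h[a1]) extra_h[a1] <- extra_h[a1] + 1L
    }
    keep <- which(!is_h)
    remap <- integer(n_all); remap[keep] <- seq_along(keep)
    bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    elem <- elem[keep]; charge <- charge[keep]; extra_h <- extra_h[keep]
    coords <- coords[keep, , drop = FALSE]
  }
  n <- length(elem)
  assert_that(n >= 1, "empty molecule")
  adj <- vector("list", n)
  bond_order_sum <- numeric(n)
  degree <- integer(n)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]; o <- bonds$order[b]
      adj[[a1]] <- c(adj[[a1]], a2)
      adj[[a2]] <- c(adj[[a2]], a1)
      bond_order_sum[a1] <- bond_order_sum[a1] + o
      bond_order_sum[a2] <- bond_order_sum[a2] + o
      degree[a1] <- degree[a1] + 1L
      degree[a2] <- degree[a2] + 1L
    }
  }
  defv <- DEFAULT_VALENCE[elem]
  defv[is.na(defv)] <- 4
  n_h <- pmax(0L, as.integer(defv + charge - bond_order_sum)) + extra_h
  ring <- ring_membership(n, bonds)
  list(canonical_smiles = canonical_smiles, n = n, elem = elem,
       charge = charge, n_h = n_h, bonds = bonds, adj = adj,
       degree = degree, ring_bond = ring$ring_bond,
       ring_atom = ring$ring_atom, ring_sizes = ring$ring_sizes,
       n_rings = ring$n_rings, coords = coords,
       mol_weight = graph_mw(elem, n_h))
}

# Average atomic masses for the whitelist elements (plus common extras so
# molecular weight is still reported for structures the primary filter will
# later reject on element grounds).
ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Na = 22.99, Mg = 24.305, Si = 28.086, P = 30.974,
                 S = 32.065, Cl = 35.453, K = 39.098, Ca = 40.078,
                 Br = 79.904, I = 126.904, Se = 78.971)

graph_mw <- function(elem, n_h) {
  m <- ATOMIC_MASS[elem]
  m[is.na(m)] <- 0
  sum(m) + sum(n_h) * ATOMIC_MASS[["H"]]
}

# Ring perception via bridge detection: a bond is in a ring iff it is not a
# bridge of the molecular graph. Ring sizes come from the fundamental cycle
# basis of a spanning forest (cycle rank = bonds - atoms + components).
ring_membership <- function(n, bonds) {
  if (nrow(bonds) == 0) {
    return(list(ring_bond = logical(0), ring_atom = logical(n),
                ring_sizes = integer(0), n_rings = 0L))
  }
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  ring_atom <- logical(n)
  ring_atom[unique(c(bonds$a1[ring_bond], bonds$a2[ring_bond]))] <- TRUE
  tree <- igraph::mst(g)
  tree_edges <- igraph::as_edgelist(tree)
  in_tree <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2)) %in%
    paste(pmin(tree_edges[, 1], tree_edges[, 2]),
          pmax(tree_edges[, 1], tree_edges[, 2]))
  chords <- bonds[!in_tree, , drop = FALSE]
  sizes <- integer(0)
  if (nrow(chords) > 0) {
    d <- igraph::distances(tree)
    sizes <- as.integer(d[cbind(chords$a1, chords$a2)] + 1)
  }
  list(ring_bond = ring_bond, ring_atom = ring_atom,
       ring_sizes = sizes, n_rings = length(sizes))
}

# Rotatable bond count: acyclic single bonds between two non-terminal heavy
# atoms (the classic Veber-style definition without the amide exception).
count_rotatable <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  rot <- g$bonds$order == 1 & !g$ring_bond &
    g$degree[g$bonds$a1] > 1 & g$degree[g$bonds$a2] > 1
  sum(rot)
}

# SDFset (with 2D coordinates) for a vector of canonical SMILES; used for
# Open Babel property calculation, SMARTS matching and depiction.
sdf_from_smiles <- function(smiles, gen2d = FALSE) {
  inp <- paste(paste0(smiles, "\tM", seq_along(smiles)), collapse = "\n")
  sdfstr <- ob_convert("SMI", "SDF", inp)
  assert_that(nzchar(sdfstr), "SMILES to SDF conversion failed")
  set <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(sdfstr, "\n", fixed = TRUE)[[1]]))
  assert_that(length(set) == length(smiles),
              "SDF conversion dropped molecules; standardize inputs first")
  set
}

# Open Babel property block for canonical SMILES (memoised per molecule).
ob_properties <- function(smiles) {
  need <- vapply(smiles, function(s) is.null(cache_get(paste0("prop:", s))),
                 logical(1))
  if (any(need)) {
    uniq <- unique(smiles[need])
    set <- sdf_from_smiles(uniq)
    pr <- ChemmineR::propOB(set)
    for (i in seq_along(uniq)) {
      cache_set(paste0("prop:", uniq[i]), pr[i, , drop = FALSE])
    }
  }
  do.call(rbind, lapply(smiles, function(s) cache_get(paste0("prop:", s))))
}

#' Count SMARTS matches in standardized structures
#'
#' Thin wrapper over Open Babel's SMARTS engine, vectorized over molecules.
#'
#' @param smiles Character vector of canonical SMILES.
#' @param smarts A single SMARTS pattern.
#' @return Integer vector of (unique) match counts per molecule.
#' @export
smarts_matches <- function(smiles, smarts) {
  set <- sdf_from_smiles(smiles)
  res <- ChemmineR::smartsSearchOB(set, smarts, uniqueMatches = TRUE)
  as.integer(res)
}
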