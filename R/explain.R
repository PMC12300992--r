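# Model explanation: permutation Shapley values over fingerprint bits and
# retro-mapping of bit contributions to atoms.
#
# The explainer is model-agnostic: it only needs the model's probability
# output on perturbed fingerprints. For each background fingerprint and
# each sampled permutation (walked forward and backward, an antithetic
# pair), features are switched from the background value to the molecule's
# value one at a time and the marginal probability changes are accumulated.
# Features identical in molecule and background contribute exactly zero and
# are skipped, which leaves the telescoping sum intact, so the additivity
# identity sum(phi) + base = p(molecule) holds to machine precision for
# every permutation/background pair and hence for their average.

#' Permutation SHAP values for the bits of one molecule
#'
#' @param model An `iso_model` with a bit representation (`"circular"`,
#'   `"path"` or `"keys"`); the descriptor representation has no atom
#'   mapping and is not supported.
#' @param smiles Canonical SMILES of the molecule to explain.
#' @param background Binary matrix of background fingerprints; defaults to
#'   a seed-controlled sample of up to `n_background` training compounds.
#' @param n_background Background sample size (default 25).
#' @param n_permutations Permutations per background row; each is walked in
#'   both directions (default 2).
#' @param seed Integer seed.
#' @return Tibble with one row per fingerprint bit (`bit`, `shap_value`,
#'   `on`), with attributes `base_value` (mean background probability) and
#'   `p_molecule` (model output for the molecule).
#' @export
shap_bits <- function(model, smiles, background = NULL, n_background = 25,
                      n_permutations = 2, seed = 1) {
  assert_that(inherits(model, "iso_model"), "model must be an iso_model")
  assert_that(model$repr_id != "physchem",
              "unsupported representation: atom mapping needs a bit representation")
  x <- featurize(smiles, model$repr_id)[1, ]
  p <- length(x)
  if (is.null(background)) {
    train_x <- featurize(model$train_smiles, model$repr_id)
    n_bg <- min(n_background, nrow(train_x))
    idx <- withr::with_seed(derive_seed(seed, 7), {
      sample.int(nrow(train_x), n_bg)
    })
    background <- train_x[idx, , drop = FALSE]
  }
  assert_that(is.matrix(background) && ncol(background) == p,
              "background width must match the fingerprint length")
  phi <- numeric(p)
  n_walks <- 0L
  base_value <- mean(predict_matrix(model, background))
  for (b in seq_len(nrow(background))) {
    bg <- background[b, ]
    diff <- which(x != bg)
    if (length(diff) == 0) {
      n_walks <- n_walks + 2L * n_permutations
      next
    }
    perms <- withr::with_seed(derive_seed(seed, 1000 + b), {
      lapply(seq_len(n_permutations), function(i) sample(diff))
    })
    directions <- unlist(lapply(perms, function(pm) list(pm, rev(pm))),
                         recursive = FALSE)
    # One walk = |diff| + 1 rows: row j has the first j - 1 features of the
    # permutation switched from background to molecule values. All walks
    # for this background row are stacked into one prediction call.
    rows_per_walk <- length(diff) + 1L
    W <- matrix(bg, nrow = rows_per_walk * length(directions), ncol = p,
                byrow = TRUE)
    for (w in seq_along(directions)) {
      off <- (w - 1L) * rows_per_walk
      direction <- directions[[w]]
      for (j in seq_along(direction)) {
        W[(off + j + 1L):(off + rows_per_walk), direction[j]] <-
          x[direction[j]]
      }
    }
    f <- predict_matrix(model, W)
    for (w in seq_along(directions)) {
      off <- (w - 1L) * rows_per_walk
      direction <- directions[[w]]
      phi[direction] <- phi[direction] + diff(f[(off + 1L):
                                                  (off + rows_per_walk)])
      n_walks <- n_walks + 1L
    }
  }
  phi <- phi / max(n_walks, 1L)
  out <- tibble::tibble(bit = seq_len(p), shap_value = phi, on = x == 1)
  attr(out, "base_value") <- base_value
  attr(out, "p_molecule") <- predict_matrix(model, matrix(x, nrow = 1))
  out
}

#' Aggregate bit SHAP values into per-atom weights
#'
#' Implements the retro-mapping weighting: each on-bit's SHAP value is
#' divided by the number of atoms in the bit's structural footprint (the
#' union of its environments), summed per atom, and the per-atom sum is
#' divided by the number of distinct on-bits covering that atom:
#' `w(a) = ( sum_f phi_f / |atoms(f)| ) / r(a)`. Atoms covered by no
#' on-bit get exactly 0. With `order = "occurrence_first"` the two
#' normalizations are applied in the opposite order
#' (`w(a) = sum_f phi_f / (|atoms(f)| * r(a))` summed differently), kept
#' for sensitivity analysis.
#'
#' @param contributions Tibble from [shap_bits()] (only rows with `on`
#'   are used), or any tibble with `bit` and `shap_value`.
#' @param mapping Bit -> atom-environment list from [map_bits_to_atoms()].
#' @param n_atoms Number of heavy atoms in the molecule.
#' @param order Normalization order (default `"atoms_first"`).
#' @return An `iso_attribution`: tibble with `atom` and `weight`, plus the
#'   molecule metadata carried as attributes.
#' @export
atom_weights <- function(contributions, mapping, n_atoms,
                         order = c("atoms_first", "occurrence_first")) {
  order <- match.arg(order)
  if ("on" %in% names(contributions)) {
    contributions <- contributions[contributions$on, ]
  }
  contributions <- contributions[
    as.character(contributions$bit) %in% names(mapping), ]
  w <- numeric(n_atoms)
  r <- integer(n_atoms)
  if (nrow(contributions) == 0) {
    warning("no mapped on-bit contributions; attribution is all zero")
  } else {
    footprints <- lapply(as.character(contributions$bit), function(b) {
      sort(unique(unlist(mapping[[b]])))
    })
    for (f in footprints) r[f] <- r[f] + 1L
    for (i in seq_len(nrow(contributions))) {
      atoms <- footprints[[i]]
      w[atoms] <- w[atoms] + contributions$shap_value[i] / length(atoms)
    }
    covered <- r > 0
    if (order == "atoms_first") {
      w[covered] <- w[covered] / r[covered]
    } else {
      # occurrence_first: phi_f / (r(a) * |atoms(f)|) accumulated directly
      w <- numeric(n_atoms)
      for (i in seq_len(nrow(contributions))) {
        atoms <- footprints[[i]]
        w[atoms] <- w[atoms] +
          contributions$shap_value[i] / (length(atoms) * r[atoms])
      }
    }
  }
  structure(tibble::tibble(atom = seq_len(n_atoms), weight = w),
            class = c("iso_attribution", "tbl_df", "tbl", "data.frame"),
            coverage = r)
}

#' Explain one prediction at atom level
#'
#' Convenience wrapper: permutation SHAP on the circular-fingerprint bits,
#' bit-to-atom retro-mapping, and per-atom weight aggregation.
#'
#' @inheritParams shap_bits
#' @param order Normalization order, see [atom_weights()].
#' @return An `iso_attribution` with attributes `smiles`, `bit_shap` (the
#'   per-bit table), `base_value` and `p_molecule`.
#' @export
explain_molecule <- function(model, smiles, background = NULL,
                             n_background = 25, n_permutations = 2,
                             seed = 1, order = "atoms_first") {
  assert_that(model$repr_id == "circular",
              "atom-level attribution is defined for the circular representation")
  contributions <- shap_bits(model, smiles, background, n_background,
                             n_permutations, seed)
  mapping <- map_bits_to_atoms(smiles, "circular")
  g <- mol_graph(smiles)
  att <- atom_weights(contributions, mapping, g$n, order = order)
  attr(att, "smiles") <- smiles
  attr(att, "bit_shap") <- contributions
  attr(att, "base_value") <- attr(contributions, "base_value")
  attr(att, "p_molecule") <- attr(contributions, "p_molecule")
  att
}

#' Depict an atom attribution
#'
#' 2D depiction of the molecule with atoms coloured by attribution weight
#' on a diverging scale: orange for positive (pushing toward activity),
#' blue for negative.
#'
#' @param object An `iso_attribution` from [explain_molecule()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iso_attribution
#' @export
autoplot.iso_attribution <- function(object, ...) {
  smiles <- attr(object, "smiles")
  assert_that(!is.null(smiles), "attribution carries no molecule")
  g <- mol_graph(smiles)
  xy <- data.frame(x = g$coords[, 1], y = g$coords[, 2],
                   elem = g$elem, weight = object$weight)
  seg <- data.frame(x = g$coords[g$bonds$a1, 1],
                    y = g$coords[g$bonds$a1, 2],
                    xend = g$coords[g$bonds$a2, 1],
                    yend = g$coords[g$bonds$a2, 2])
  lim <- max(abs(object$weight), 1e-9)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey40") +
    ggplot2::geom_point(data = xy,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$weight),
                        shape = 21, size = 8, colour = "grey20") +
    ggplot2::geom_text(data = xy,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$elem), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#e08214", midpoint = 0,
                                  limits = c(-lim, lim)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "atom weight")
}

#' Write an attribution depiction and its numeric sidecar
#'
#' Saves the diverging-colour depiction (PNG or SVG by extension) next to
#' a machine-readable CSV of per-atom weights.
#'
#' @param attribution An `iso_attribution`.
#' @param path Image path; the sidecar gets the same stem with
#'   `_atom_weights.csv` appended.
#' @return Invisibly, a list with the two paths written.
#' @export
render_attribution <- function(attribution, path) {
  plt <- autoplot(attribution)
  ggplot2::ggsave(path, plt, width = 6, height = 5, dpi = 150)
  sidecar <- paste0(sub("\\.[A-Za-z]+$", "", path), "_atom_weights.csv")
  utils::write.csv(as.data.frame(attribution), sidecar, row.names = FALSE)
  invisible(list(image = path, sidecar = sidecar))
}
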