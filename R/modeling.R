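# Classifier training and evaluation: SVM, random forest, k-nearest
# neighbours and Gaussian process over the four molecular representations,
# with grid search (5-fold stratified CV on MCC), repeated Monte-Carlo CV,
# final training and probability prediction.
#
# SVM and GP fits go through kernlab; the Tanimoto kernel is supplied as a
# precomputed Gram matrix (SVM) or a custom kernel function (GP). The
# random forest is randomForest; KNN is a small exact implementation so the
# Jaccard (1 - Tanimoto) distance can be used on bit representations.

ALGORITHMS <- c("svm", "rf", "knn", "gp")

default_hyperparams <- function(algorithm, repr_id) {
  bit <- repr_id != "physchem"
  switch(algorithm,
         svm = list(C = 10, kernel = if (bit) "tanimoto" else "rbf",
                    degree = 3),
         rf = list(ntree = 300, max_features = "sqrt"),
         knn = list(k = 5, weights = "uniform"),
         gp = list(kernel = if (bit) "tanimoto" else "rbf"),
         stop("unknown algorithm: ", algorithm, call. = FALSE))
}

#' Default hyperparameter grid for an algorithm
#'
#' Grids are ordered from simpler to more complex configurations; grid
#' search breaks mean-MCC ties by taking the earliest entry.
#'
#' @param algorithm One of `"svm"`, `"rf"`, `"knn"`, `"gp"`.
#' @param repr_id Representation the grid will be used with (the Tanimoto
#'   kernel is only offered for bit representations).
#' @return A data frame, one row per hyperparameter combination.
#' @export
default_grid <- function(algorithm, repr_id = "circular") {
  bit <- repr_id != "physchem"
  switch(algorithm,
         svm = expand.grid(
           kernel = c("linear", "poly2", "poly3", "rbf", "sigmoid",
                      if (bit) "tanimoto"),
           C = c(0.1, 1, 10, 100),
           stringsAsFactors = FALSE),
         rf = expand.grid(ntree = c(100, 300, 500),
                          max_features = c("sqrt", "log2", "0.3"),
                          stringsAsFactors = FALSE),
         knn = expand.grid(k = c(1, 3, 5, 7, 9),
                           weights = c("uniform", "distance"),
                           stringsAsFactors = FALSE),
         gp = expand.grid(kernel = c("dot", "rbf", if (bit) "tanimoto"),
                          stringsAsFactors = FALSE),
         stop("unknown algorithm: ", algorithm, call. = FALSE))
}

# ---------------------------------------------------------------------------
# Kernels

svm_gram <- function(kernel, A, B, p) {
  gamma <- 1 / p
  lin <- function() A %*% t(B)
  switch(kernel,
         linear = lin(),
         poly2 = (gamma * lin() + 1)^2,
         poly3 = (gamma * lin() + 1)^3,
         rbf = {
           d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * lin()
           exp(-gamma * pmax(d2, 0))
         },
         sigmoid = tanh(gamma * lin() + 1),
         tanimoto = tanimoto_matrix(A, B),
         stop("unknown SVM kernel: ", kernel, call. = FALSE))
}

tanimoto_kernfun <- function() {
  k <- function(x, y) {
    j <- sum(x * y)
    d <- sum(x) + sum(y) - j
    if (d == 0) 0 else j / d
  }
  class(k) <- "kernel"
  k
}

gp_kernel <- function(kernel) {
  switch(kernel,
         dot = kernlab::vanilladot(),
         rbf = kernlab::rbfdot(sigma = 1),
         tanimoto = tanimoto_kernfun(),
         stop("unknown GP kernel: ", kernel, call. = FALSE))
}

# ---------------------------------------------------------------------------
# Fit / predict on feature matrices

label_factor <- function(label) {
  factor(label, levels = c("inactive", "active"))
}

fit_algorithm <- function(X, y, algorithm, hyperparams, repr_id, seed) {
  hp <- utils::modifyList(default_hyperparams(algorithm, repr_id),
                          hyperparams)
  assert_that(nlevels(droplevels(y)) == 2,
              "degenerate single-class training set")
  bit <- repr_id != "physchem"
  if (!bit && identical(hp$kernel, "tanimoto")) {
    stop("the Tanimoto kernel requires a bit representation",
         call. = FALSE)
  }
  fit <- switch(
    algorithm,
    svm = {
      K <- svm_gram(hp$kernel, X, X, ncol(X))
      m <- withr::with_seed(seed, kernlab::ksvm(
        kernlab::as.kernelMatrix(K), y, C = hp$C, prob.model = TRUE))
      list(model = m, kernel = hp$kernel)
    },
    rf = {
      mtry <- switch(as.character(hp$max_features),
                     sqrt = max(1L, floor(sqrt(ncol(X)))),
                     log2 = max(1L, floor(log2(ncol(X)))),
                     max(1L, floor(as.numeric(hp$max_features) * ncol(X))))
      m <- withr::with_seed(seed, randomForest::randomForest(
        x = X, y = y, ntree = hp$ntree, mtry = mtry))
      list(model = m)
    },
    knn = list(k = hp$k, weights = hp$weights),
    gp = {
      m <- withr::with_seed(seed, kernlab::gausspr(
        X, y, kernel = gp_kernel(hp$kernel), scaled = FALSE))
      list(model = m, kernel = hp$kernel)
    })
  list(algorithm = algorithm, hyperparams = hp, fit = fit,
       train_x = X, train_y = y, repr_id = repr_id, seed = seed)
}

predict_fit <- function(fitobj, X) {
  assert_that(ncol(X) == ncol(fitobj$train_x),
              "feature width does not match the model's representation")
  switch(
    fitobj$algorithm,
    svm = {
      Kt <- svm_gram(fitobj$fit$kernel, X, fitobj$train_x,
                     ncol(fitobj$train_x))
      sv <- kernlab::SVindex(fitobj$fit$model)
      pr <- kernlab::predict(fitobj$fit$model,
                             kernlab::as.kernelMatrix(Kt[, sv, drop = FALSE]),
                             type = "probabilities")
      pr[, "active"]
    },
    rf = {
      pr <- stats::predict(fitobj$fit$model, X, type = "prob")
      pr[, "active"]
    },
    knn = {
      D <- if (fitobj$repr_id == "physchem") {
        sqrt(pmax(outer(rowSums(X^2), rowSums(fitobj$train_x^2), "+") -
                    2 * X %*% t(fitobj$train_x), 0))
      } else {
        1 - tanimoto_matrix(X, fitobj$train_x)
      }
      y01 <- as.integer(fitobj$train_y == "active")
      k <- fitobj$fit$k
      apply(D, 1, function(d) {
        ord <- order(d)[seq_len(min(k, length(d)))]
        if (fitobj$fit$weights == "distance") {
          w <- 1 / (d[ord] + 1e-12)
          sum(w * y01[ord]) / sum(w)
        } else {
          mean(y01[ord])
        }
      })
    },
    gp = {
      pr <- kernlab::predict(fitobj$fit$model, X, type = "probabilities")
      pr[, "active"]
    })
}

# ---------------------------------------------------------------------------
# User-facing training surface

#' Train a profiling classifier
#'
#' Featurizes the training compounds under the requested representation,
#' fits the requested algorithm and returns a self-contained model bundle:
#' the fitted classifier, the min-max scaler (physchem only), and the
#' 881-bit key fingerprints of the training compounds for downstream
#' novelty filtering.
#'
#' @param train Tibble with columns `canonical_smiles` and `label`
#'   (`"active"`/`"inactive"`).
#' @param algorithm One of `"svm"`, `"rf"`, `"knn"`, `"gp"`.
#' @param repr One of `"circular"`, `"path"`, `"keys"`, `"physchem"`.
#' @param hyperparams Named list overriding the algorithm defaults (see
#'   [default_grid()] for the searched space).
#' @param seed Integer seed controlling every stochastic element of the
#'   fit.
#' @param isoform,threshold_pki Optional metadata recorded in the bundle.
#' @return An object of class `iso_model`.
#' @export
train_model <- function(train, algorithm, repr, hyperparams = list(),
                        seed = 1, isoform = NA_character_,
                        threshold_pki = NA_real_) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  repr <- match.arg(repr, REPR_IDS)
  assert_that(all(c("canonical_smiles", "label") %in% names(train)),
              "train needs canonical_smiles and label columns")
  # Canonical row order: the fit (including probability calibration, whose
  # internal CV folds follow row order) becomes a pure function of the
  # compound set, so shuffling the input rows cannot change predictions.
  train <- train[order(train$canonical_smiles, train$label), ]
  X <- featurize(train$canonical_smiles, repr)
  scaler <- NULL
  if (repr == "physchem") {
    scaler <- fit_scaler(X)
    X <- apply_scaler(scaler, X)
  }
  colnames(X) <- feature_names(repr, ncol(X))
  y <- label_factor(train$label)
  fitobj <- fit_algorithm(X, y, algorithm, hyperparams, repr, seed)
  structure(list(algorithm = algorithm, repr_id = repr,
                 hyperparams = fitobj$hyperparams, seed = seed,
                 fitobj = fitobj, scaler = scaler,
                 train_smiles = train$canonical_smiles,
                 train_keys = featurize(train$canonical_smiles, "keys"),
                 isoform = isoform, threshold_pki = threshold_pki,
                 descriptor_names = if (repr == "physchem")
                   physchem_descriptor_names() else NULL,
                 package_version = as.character(utils::packageVersion("isoscreen"))),
            class = "iso_model")
}

feature_names <- function(repr, p) {
  if (repr == "physchem") physchem_descriptor_names() else
    paste0("b", seq_len(p))
}

#' @export
print.iso_model <- function(x, ...) {
  cat(sprintf("<iso_model> %s + %s (%s)\n", toupper(x$algorithm), x$repr_id,
              if (is.na(x$isoform)) "no isoform tag" else x$isoform))
  hp <- paste(names(x$hyperparams),
              vapply(x$hyperparams, as.character, character(1)),
              sep = "=", collapse = ", ")
  cat("  hyperparameters:", hp, "\n")
  cat("  training compounds:", length(x$train_smiles), "\n")
  invisible(x)
}

#' Predict activity probabilities for new structures
#'
#' @param object An `iso_model`.
#' @param smiles Character vector of canonical SMILES, or a data frame with
#'   a `canonical_smiles` column.
#' @param ... Unused.
#' @return Tibble with `canonical_smiles`, `p_active` and `predicted`
#'   (label at the 0.5 probability cutoff).
#' @export
predict.iso_model <- function(object, smiles, ...) {
  if (is.data.frame(smiles)) smiles <- smiles$canonical_smiles
  X <- featurize(smiles, object$repr_id)
  if (!is.null(object$scaler)) X <- apply_scaler(object$scaler, X)
  colnames(X) <- feature_names(object$repr_id, ncol(X))
  p <- predict_fit(object$fitobj, X)
  tibble::tibble(canonical_smiles = smiles, p_active = unname(p),
                 predicted = ifelse(p >= 0.5, "active", "inactive"))
}

# Probability prediction straight from a feature matrix (used by the
# attribution module, where perturbed fingerprints have no SMILES).
predict_matrix <- function(object, X) {
  if (!is.null(object$scaler)) X <- apply_scaler(object$scaler, X)
  colnames(X) <- feature_names(object$repr_id, ncol(X))
  unname(predict_fit(object$fitobj, X))
}

#' Evaluate a model on labeled compounds
#'
#' @param model An `iso_model`.
#' @param test Tibble with `canonical_smiles` and `label`.
#' @return One-row metrics tibble (see [metric_set()]).
#' @export
evaluate_model <- function(model, test) {
  pred <- predict(model, test$canonical_smiles)
  classification_metrics(test$label, pred$predicted)
}

#' @method tidy iso_model
#' @export
tidy.iso_model <- function(x, ...) {
  tibble::tibble(term = names(x$hyperparams),
                 value = vapply(x$hyperparams, as.character, character(1)))
}

#' @method glance iso_model
#' @export
glance.iso_model <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, repr_id = x$repr_id,
                 n_train = length(x$train_smiles), seed = x$seed,
                 isoform = x$isoform, threshold_pki = x$threshold_pki)
}

# ---------------------------------------------------------------------------
# Cross-validation

stratified_folds <- function(y, folds, seed) {
  idx <- seq_along(y)
  fold_id <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      members <- sample(idx[y == cl])
      fold_id[members] <- rep(seq_len(folds), length.out = length(members))
    }
  })
  fold_id
}

cv_mcc <- function(X, y, algorithm, hyperparams, repr_id, folds, seed) {
  fold_id <- stratified_folds(y, folds, seed)
  vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- fit_algorithm(X[tr, , drop = FALSE], y[tr], algorithm,
                         hyperparams, repr_id, derive_seed(seed, f))
    p <- predict_fit(fit, X[!tr, , drop = FALSE])
    classification_metrics(as.integer(y[!tr] == "active"),
                           as.integer(p >= 0.5))$mcc
  }, numeric(1))
}

#' Exhaustive hyperparameter grid search
#'
#' Scores every grid row by mean MCC over a stratified k-fold
#' cross-validation of the training set and returns the winning
#' configuration. Ties are broken deterministically in favour of the
#' earliest (simplest) grid entry. Fold MCCs that are undefined (a fold
#' where a metric denominator vanishes) are dropped from the mean with a
#' warning.
#'
#' @param train Training tibble (`canonical_smiles`, `label`).
#' @param algorithm,repr Algorithm and representation.
#' @param grid Data frame of hyperparameter combinations; defaults to
#'   [default_grid()].
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @return List with `best` (named hyperparameter list), `results`
#'   (tibble: one row per grid entry with `mean_mcc`), and `cv` (fold MCCs
#'   of the winner).
#' @export
grid_search <- function(train, algorithm, repr, grid = NULL, folds = 5,
                        seed = 1) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  repr <- match.arg(repr, REPR_IDS)
  if (is.null(grid)) grid <- default_grid(algorithm, repr)
  assert_that(is.data.frame(grid) && nrow(grid) >= 1, "empty grid")
  X <- featurize(train$canonical_smiles, repr)
  if (repr == "physchem") X <- apply_scaler(fit_scaler(X), X)
  colnames(X) <- feature_names(repr, ncol(X))
  y <- label_factor(train$label)
  all_cv <- vector("list", nrow(grid))
  means <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- as.list(grid[i, , drop = FALSE])
    hp <- lapply(hp, function(v) if (is.factor(v)) as.character(v) else v)
    scores <- cv_mcc(X, y, algorithm, hp, repr, folds, seed)
    if (anyNA(scores)) {
      warning("undefined fold MCCs excluded from the grid-search mean")
    }
    all_cv[[i]] <- scores
    means[i] <- mean(scores, na.rm = TRUE)
  }
  best_i <- which.max(means)   # first maximum: deterministic tie-break
  best <- as.list(grid[best_i, , drop = FALSE])
  best <- lapply(best, function(v) if (is.factor(v)) as.character(v) else v)
  results <- tibble::as_tibble(grid)
  results$mean_mcc <- means
  list(best = best, results = results, cv = all_cv[[best_i]])
}

#' Repeated Monte-Carlo cross-validation
#'
#' Robustness protocol: in each of `cycles` rounds the training set is
#' split into a stratified random 80/20 train/validation partition, a
#' control model is fitted on the 80% and scored (MCC) on the 20%. A
#' classic disjoint k-fold mode is available via `mode = "kfold"`.
#'
#' @param train Training tibble.
#' @param algorithm,repr,hyperparams,seed As in [train_model()].
#' @param cycles Number of rounds (default 10).
#' @param mode `"montecarlo"` (default) or `"kfold"`.
#' @return An `iso_cv` object: fold scores plus metadata.
#' @export
repeated_cv <- function(train, algorithm, repr, hyperparams = list(),
                        cycles = 10, seed = 1, mode = "montecarlo") {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  repr <- match.arg(repr, REPR_IDS)
  mode <- match.arg(mode, c("montecarlo", "kfold"))
  X <- featurize(train$canonical_smiles, repr)
  if (repr == "physchem") X <- apply_scaler(fit_scaler(X), X)
  colnames(X) <- feature_names(repr, ncol(X))
  y <- label_factor(train$label)
  scores <- if (mode == "kfold") {
    cv_mcc(X, y, algorithm, hyperparams, repr, cycles, seed)
  } else {
    vapply(seq_len(cycles), function(cyc) {
      cyc_seed <- derive_seed(seed, 100 + cyc)
      tr <- logical(length(y))
      withr::with_seed(cyc_seed, {
        for (cl in levels(y)) {
          members <- which(y == cl)
          tr[sample(members, floor(0.8 * length(members)))] <- TRUE
        }
      })
      fit <- fit_algorithm(X[tr, , drop = FALSE], y[tr], algorithm,
                           hyperparams, repr, cyc_seed)
      p <- predict_fit(fit, X[!tr, , drop = FALSE])
      classification_metrics(as.integer(y[!tr] == "active"),
                             as.integer(p >= 0.5))$mcc
    }, numeric(1))
  }
  structure(list(algorithm = algorithm, repr_id = repr, scores = scores,
                 cycles = cycles, mode = mode, seed = seed),
            class = "iso_cv")
}

#' @export
print.iso_cv <- function(x, ...) {
  cat(sprintf("<iso_cv> %s + %s: mean MCC %.3f (sd %.3f) over %d cycles\n",
              toupper(x$algorithm), x$repr_id,
              mean(x$scores, na.rm = TRUE),
              stats::sd(x$scores, na.rm = TRUE), x$cycles))
  invisible(x)
}

#' @method tidy iso_cv
#' @export
tidy.iso_cv <- function(x, ...) {
  tibble::tibble(cycle = seq_along(x$scores), mcc = x$scores)
}

#' @method glance iso_cv
#' @export
glance.iso_cv <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, repr_id = x$repr_id,
                 cycles = x$cycles, mode = x$mode,
                 mean_mcc = mean(x$scores, na.rm = TRUE),
                 sd_mcc = stats::sd(x$scores, na.rm = TRUE))
}

#' Plot repeated-CV scores
#'
#' @param object An `iso_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iso_cv
#' @export
autoplot.iso_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cycle), y = .data$mcc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "CV cycle", y = "MCC",
                  title = sprintf("%s + %s repeated CV",
                                  toupper(object$algorithm),
                                  object$repr_id)) +
    ggplot2::theme_minimal()
}

# ---------------------------------------------------------------------------
# Serialization

#' Save a trained model bundle
#'
#' Writes the model with a manifest (algorithm, representation, seed,
#' descriptor list, package version). [load_model()] refuses bundles whose
#' manifest does not match the installed package's representation
#' contracts.
#'
#' @param model An `iso_model`.
#' @param path Destination file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  assert_that(inherits(model, "iso_model"), "not an iso_model")
  saveRDS(model, path)
  invisible(path)
}

#' Load a trained model bundle
#'
#' @param path Path written by [save_model()].
#' @return The `iso_model`.
#' @export
load_model <- function(path) {
  assert_that(file.exists(path), paste("no such model bundle:", path))
  model <- readRDS(path)
  assert_that(inherits(model, "iso_model"),
              "file is not an isoscreen model bundle")
  if (model$repr_id == "physchem") {
    assert_that(identical(model$descriptor_names,
                          physchem_descriptor_names()),
                "model bundle descriptor list does not match this package")
  }
  model
}
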