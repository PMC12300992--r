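# Workflow surface: configuration, run manifests and the command pipeline
# tying curation, training, evaluation, screening, profiling and
# explanation together. The shipped CLI script (inst/cli/isoscreen.R) is a
# thin option-parsing wrapper over run_pipeline().

#' Default pipeline configuration
#'
#' @return Nested list with sections `curation`, `representations`,
#'   `grids`, `cv` and `screening`; every field can be overridden from a
#'   YAML file (see [read_config()]).
#' @export
default_config <- function() {
  list(
    seed = 1,
    curation = list(isoform = "hCA_II", threshold_pki = NULL, band = 0.25,
                    train_fraction = 0.8, source_allow = NULL),
    representations = list(model_repr = "circular"),
    grids = list(algorithm = "svm", grid_search = FALSE),
    cv = list(cycles = 10, mode = "montecarlo"),
    screening = list(prob_cutoff = 0.5, novelty_max_similarity = 0.80,
                     alert_sets = c("pains", "brenk", "bms",
                                    "inpharmatica", "nibr"),
                     lipinski_max_violations = 0),
    fixtures = list(n_compounds = 200, duplicate_fraction = 0.2,
                    band_fraction = 0.05, gt_fraction = 0.1,
                    noise_cv = 0.1, library_n = 400))
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected with a message naming the key; omitted keys
#' fall back to [default_config()].
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  assert_that(file.exists(path), paste("missing config file:", path))
  user <- yaml::read_yaml(path)
  merge_checked <- function(base, override, prefix = "") {
    for (k in names(override)) {
      if (!k %in% names(base)) {
        stop("unknown config key: ", prefix, k, call. = FALSE)
      }
      if (is.list(base[[k]]) && is.list(override[[k]])) {
        base[[k]] <- merge_checked(base[[k]], override[[k]],
                                   paste0(prefix, k, "."))
      } else {
        base[[k]] <- override[[k]]
      }
    }
    base
  }
  merge_checked(cfg, user)
}

write_manifest <- function(out_dir, command, cfg, inputs = character()) {
  digests <- vapply(inputs, function(f) {
    if (file.exists(f)) as.character(file.size(f)) else "missing"
  }, character(1))
  manifest <- list(
    command = command,
    master_seed = cfg$seed,
    config = cfg,
    package_version = as.character(utils::packageVersion("isoscreen")),
    r_version = as.character(getRversion()),
    input_sizes = as.list(digests),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Run one pipeline command
#'
#' Commands: `"fixtures"` (emit a synthetic activity table + manifest),
#' `"curate"` (activity table -> curated train/test tables + report),
#' `"train"` (curated tables -> model bundle + hold-out metrics),
#' `"screen"` (model bundle + library -> ranked, cascade-filtered hits),
#' `"profile"` (several model bundles + library -> cross-isoform activity
#' profiles), `"explain"` (model bundle + SMILES -> attribution image and
#' CSVs). Every command writes its artifacts plus a `run_manifest.json`
#' into `out_dir` and returns the main result invisibly.
#'
#' @param command One of the commands above.
#' @param config Configuration list ([read_config()]) or YAML path.
#' @param out_dir Output directory (created if needed).
#' @param activity_table,model_paths,library_path,smiles Command-specific
#'   inputs: path to an activity CSV, model bundle path(s), screening
#'   library (SMILES file: one SMILES per line, optional tab-separated
#'   id), molecule to explain.
#' @return Invisibly, the command's primary result object.
#' @export
run_pipeline <- function(command = c("fixtures", "curate", "train",
                                     "screen", "profile", "explain"),
                         config = NULL, out_dir,
                         activity_table = NULL, model_paths = NULL,
                         library_path = NULL, smiles = NULL) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) read_config(config) else
    config %||% default_config()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  result <- switch(
    command,
    fixtures = {
      fx <- cfg$fixtures
      gen <- generate_activity_table(
        n_compounds = fx$n_compounds,
        duplicate_fraction = fx$duplicate_fraction,
        band_fraction = fx$band_fraction, gt_fraction = fx$gt_fraction,
        noise_cv = fx$noise_cv, isoform = cfg$curation$isoform,
        seed = derive_seed(seed, 1))
      utils::write.csv(gen$records, file.path(out_dir, "activity.csv"),
                       row.names = FALSE)
      utils::write.csv(gen$manifest,
                       file.path(out_dir, "ground_truth_manifest.csv"),
                       row.names = FALSE)
      lib <- generate_separable_library(fx$library_n,
                                        seed = derive_seed(seed, 2))
      writeLines(paste(lib$canonical_smiles, lib$label, sep = "\t"),
                 file.path(out_dir, "library.smi"))
      gen
    },
    curate = {
      assert_that(!is.null(activity_table) && file.exists(activity_table),
                  "curate needs an existing activity_table path")
      records <- read_activity_table(activity_table)
      ds <- curate_activity(records, cfg$curation$isoform,
                            threshold_pki = cfg$curation$threshold_pki,
                            band = cfg$curation$band,
                            train_fraction = cfg$curation$train_fraction,
                            seed = derive_seed(seed, 3),
                            source_allow = cfg$curation$source_allow)
      utils::write.csv(ds$train, file.path(out_dir, "train.csv"),
                       row.names = FALSE)
      utils::write.csv(ds$test, file.path(out_dir, "test.csv"),
                       row.names = FALSE)
      rep <- ds$report
      rep$drops <- NULL
      jsonlite::write_json(
        c(list(isoform = ds$isoform, threshold_pki = ds$threshold_pki),
          rep),
        file.path(out_dir, "curation_report.json"), auto_unbox = TRUE)
      utils::write.csv(ds$report$drops,
                       file.path(out_dir, "dropped_records.csv"),
                       row.names = FALSE)
      ds
    },
    train = {
      assert_that(!is.null(activity_table),
                  "train needs activity_table = directory of curate output")
      train_tbl <- tibble::as_tibble(utils::read.csv(
        file.path(activity_table, "train.csv"),
        stringsAsFactors = FALSE))
      test_tbl <- tibble::as_tibble(utils::read.csv(
        file.path(activity_table, "test.csv"), stringsAsFactors = FALSE))
      algorithm <- cfg$grids$algorithm
      repr <- cfg$representations$model_repr
      hp <- list()
      if (isTRUE(cfg$grids$grid_search)) {
        gs <- grid_search(train_tbl, algorithm, repr,
                          seed = derive_seed(seed, 4))
        hp <- gs$best
      }
      model <- train_model(train_tbl, algorithm, repr, hp,
                           seed = derive_seed(seed, 5),
                           isoform = cfg$curation$isoform)
      metrics <- evaluate_model(model, test_tbl)
      save_model(model, file.path(out_dir, "model.rds"))
      jsonlite::write_json(as.list(metrics),
                           file.path(out_dir, "test_metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      list(model = model, metrics = metrics)
    },
    screen = {
      assert_that(!is.null(model_paths) && !is.null(library_path),
                  "screen needs model_paths and library_path")
      assert_that(file.exists(library_path),
                  paste("missing library file:", library_path))
      model <- load_model(model_paths[1])
      lib <- read_smiles_file(library_path)
      hits <- screen(model, lib$smiles,
                     prob_cutoff = cfg$screening$prob_cutoff)
      stages <- lapply(cfg$screening$alert_sets, function(s) {
        filter_alerts(s)
      })
      stages <- c(stages,
                  list(filter_lipinski(cfg$screening$lipinski_max_violations),
                       filter_veber()))
      filtered <- filter_cascade(hits, stages)
      novel <- novelty_filter(filtered, model,
                              cfg$screening$novelty_max_similarity)
      utils::write.csv(novel, file.path(out_dir, "hits.csv"),
                       row.names = FALSE)
      jsonlite::write_json(cascade_funnel(filtered),
                           file.path(out_dir, "funnel.json"),
                           auto_unbox = TRUE)
      novel
    },
    profile = {
      assert_that(length(model_paths) >= 2 && !is.null(library_path),
                  "profile needs >= 2 model bundles and a library")
      lib <- read_smiles_file(library_path)
      hit_lists <- list()
      for (mp in model_paths) {
        model <- load_model(mp)
        iso <- if (is.na(model$isoform)) basename(mp) else model$isoform
        if (iso %in% names(hit_lists)) {
          iso <- paste0(iso, "_", length(hit_lists) + 1L)
        }
        hit_lists[[iso]] <- screen(model, lib$smiles,
                                   prob_cutoff = cfg$screening$prob_cutoff)
      }
      profiles <- cross_reference(hit_lists, mode = "union")
      utils::write.csv(profiles, file.path(out_dir, "activity_profiles.csv"),
                       row.names = FALSE)
      profiles
    },
    explain = {
      assert_that(!is.null(model_paths) && !is.null(smiles),
                  "explain needs a model bundle and a SMILES")
      model <- load_model(model_paths[1])
      std <- standardize_smiles(smiles)
      assert_that(all(std$ok), "cannot explain an invalid structure")
      att <- explain_molecule(model, std$canonical_smiles[1],
                              seed = derive_seed(seed, 6))
      render_attribution(att, file.path(out_dir, "attribution.png"))
      utils::write.csv(attr(att, "bit_shap"),
                       file.path(out_dir, "bit_shap.csv"),
                       row.names = FALSE)
      att
    })
  write_manifest(out_dir, command, cfg,
                 inputs = c(activity_table %||% character(),
                            model_paths %||% character(),
                            library_path %||% character()))
  invisible(result)
}

#' Read a SMILES file
#'
#' One molecule per line: `SMILES` or `SMILES<TAB>id`.
#'
#' @param path File path.
#' @return Tibble with `smiles` and `id`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  tibble::tibble(
    smiles = vapply(parts, `[`, character(1), 1),
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("mol", i)
    }, character(1)))
}
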