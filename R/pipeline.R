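# Workflow orchestration: configured, logged, manifest-writing commands.
# Each pipeline_* function wraps the corresponding package stage; the thin
# command-line script in inst/cli/oilauth dispatches to them.

#' Pipeline run configuration
#'
#' A single configuration object for the end-to-end workflow. Defaults are
#' the study conditions: the full four-system adulteration design at the
#' eleven gradient levels with three replicates, default instrument noise,
#' the packaged default bin configuration, PCA features and an 8:2 split.
#'
#' @param out_dir Output directory (created if missing).
#' @param systems Adulteration systems to simulate (1-4 adulterants).
#' @param levels Gradient percentages.
#' @param replicates Replicates per gradient point.
#' @param pure_replicates Pure samples per oil class.
#' @param noise A [noise_model()].
#' @param bin_config_path Bin-configuration CSV (`NULL` = packaged default).
#' @param embed_method `"non"`, `"pca"` or `"umap"`.
#' @param model Classifier kind(s) for qualitative tasks.
#' @param task `"binary"`, `"multiclass"` or `"quantify"`.
#' @param n_runs Repeated runs for quantitative evaluation.
#' @param quantifier_args Named list of [quantifier_spec()] overrides used
#'   by the quantify task (e.g. `list(epochs = 60)`).
#' @param seed Global seed; stage seeds are derived from it.
#' @param test_frac Held-out test fraction.
#' @param top_k,window Bin-refinement parameters.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("oilauth_run_"),
                       systems = 1:4,
                       levels = c(3, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90),
                       replicates = 3, pure_replicates = 3,
                       noise = noise_model(), bin_config_path = NULL,
                       embed_method = "pca", model = "rf",
                       task = c("binary", "multiclass", "quantify"),
                       n_runs = 10, seed = 42, test_frac = 0.2,
                       top_k = 5, window = 0.03, quantifier_args = list()) {
  task <- match.arg(task)
  structure(list(out_dir = out_dir, systems = systems, levels = levels,
                 replicates = replicates, pure_replicates = pure_replicates,
                 noise = noise, bin_config_path = bin_config_path,
                 embed_method = embed_method, model = model, task = task,
                 n_runs = n_runs, seed = seed, test_frac = test_frac,
                 top_k = top_k, window = window,
                 quantifier_args = quantifier_args),
            class = "run_config")
}

config_bins <- function(config) {
  if (is.null(config$bin_config_path)) {
    default_bin_config()
  } else {
    read_bin_config(config$bin_config_path)
  }
}

write_manifest <- function(config, stage, extra = list()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(list(
    stage = stage,
    timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("oilauth")),
    seed = config$seed,
    config = config[setdiff(names(config), "noise")],
    noise = unclass(config$noise)
  ), extra)
  path <- file.path(config$out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

log_info <- function(stage, msg, ...) {
  message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"),
                  stage, sprintf(msg, ...)))
}

#' Simulate the adulteration sample set to disk
#'
#' Generates the profile library and the configured design, simulates every
#' sample's scan series, writes one mzXML file per sample plus the master
#' design table and a manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, the design tibble (with an `mzxml` path column).
#' @export
pipeline_simulate <- function(config = run_config()) {
  t0 <- Sys.time()
  dir.create(file.path(config$out_dir, "mzxml"), showWarnings = FALSE,
             recursive = TRUE)
  lib <- make_profile_library(seed = derive_seed(config$seed, 1L))
  designs <- enumerate_design(systems = config$systems, levels = config$levels,
                              replicates = config$replicates)
  ds <- simulate_dataset(lib, designs, noise = config$noise,
                         pure_replicates = config$pure_replicates,
                         seed = derive_seed(config$seed, 2L))
  design_tab <- dataset_design(ds)
  paths <- vapply(ds, function(s) {
    p <- file.path(config$out_dir, "mzxml",
                   paste0(sample_id(s$series), ".mzXML"))
    write_mzxml(s$series, p)
    p
  }, character(1))
  design_tab$mzxml <- paths
  readr::write_csv(design_tab, file.path(config$out_dir, "design.csv"))
  write_manifest(config, "simulate",
                 list(n_samples = nrow(design_tab),
                      library_seed = derive_seed(config$seed, 1L)))
  log_info("simulate", "%d samples in %.1fs", nrow(design_tab),
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(design_tab)
}

#' Featurize simulated mzXML files to a feature table
#'
#' Reads every mzXML listed in the run's design table, featurizes it with
#' the configured bin grid, and writes `features.csv`. Unreadable files are
#' reported by name; the remaining files are still processed, and an error
#' naming the failures is raised at the end.
#'
#' @param config A [run_config()] whose `out_dir` holds a `design.csv`.
#' @return Invisibly, the feature tibble.
#' @export
pipeline_featurize <- function(config) {
  t0 <- Sys.time()
  design_path <- file.path(config$out_dir, "design.csv")
  if (!file.exists(design_path)) stop_io("no design.csv in %s", config$out_dir)
  design <- readr::read_csv(design_path, show_col_types = FALSE, progress = FALSE)
  grid <- expand_bins(config_bins(config))
  failures <- character(0)
  rows <- purrr::map(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    feats <- tryCatch(
      featurize_sample(read_mzxml(row$mzxml, sample_id = row$sample_id), grid),
      error = function(e) {
        failures <<- c(failures, sprintf("%s (%s)", row$mzxml, conditionMessage(e)))
        NULL
      })
    if (is.null(feats)) return(NULL)
    dplyr::bind_cols(tibble(sample_id = row$sample_id, label = row$label),
                     row[fraction_cols()], feats[-1])
  })
  features <- dplyr::bind_rows(rows)
  if (nrow(features)) {
    write_feature_table(features, file.path(config$out_dir, "features.csv"))
  }
  readr::write_csv(grid_summary(grid),
                   file.path(config$out_dir, "grid_summary.csv"))
  write_manifest(config, "featurize",
                 list(n_features = sum(grepl("^f[0-9]+$", names(features))),
                      n_samples = nrow(features), n_failed = length(failures),
                      failed = as.list(failures)))
  log_info("featurize", "%d samples x %d features in %.1fs (%d failures)",
           nrow(features), sum(grepl("^f[0-9]+$", names(features))),
           as.numeric(difftime(Sys.time(), t0, units = "secs")),
           length(failures))
  if (length(failures)) {
    stop_io("featurization failed for %d file(s): %s",
            length(failures), paste(failures, collapse = "; "))
  }
  invisible(features)
}

# Map binned feature columns to m/z anchors (sub-bin centres), one score
# table per temporal statistic, so anchors within a table are unique.
binned_anchor_sets <- function(features, grid) {
  centers <- (grid$lo + grid$hi) / 2
  nb <- nrow(grid)
  stats <- agg_stat_names()
  fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
  stopifnot(length(fcols) >= 5L * nb)
  purrr::map(seq_along(stats), function(s) {
    cols <- fcols[(seq_len(nb) - 1L) * 5L + s]
    list(stat = stats[s], cols = cols, mz = centers)
  })
}

#' Importance-driven bin refinement over a feature table
#'
#' Scores the binned block of a feature table with the four importance
#' methods (one score table per temporal statistic, so every table has
#' unique m/z anchors), writes all score tables, and merges the top-k
#' anchors into a refined bin configuration.
#'
#' @param config A [run_config()] whose `out_dir` holds `features.csv`.
#' @param methods Importance methods to run.
#' @return Invisibly, the refined [bin_config].
#' @export
pipeline_select_bins <- function(config,
                                 methods = c("anova_f", "mutual_info",
                                             "rf_importance", "pearson")) {
  t0 <- Sys.time()
  features <- read_feature_table(file.path(config$out_dir, "features.csv"))
  grid <- expand_bins(config_bins(config))
  sets <- binned_anchor_sets(features, grid)
  target <- 1 - features$frac_cao
  tables <- list()
  for (m in methods) {
    for (set in sets) {
      x <- as.matrix(features[set$cols])
      tb <- switch(m,
        anova_f = anova_f(x, features$label, mz = set$mz),
        mutual_info = mutual_info(x, features$label, mz = set$mz),
        rf_importance = rf_importance(x, features$label, mz = set$mz,
                                      seed = derive_seed(config$seed, 7L)),
        pearson = pearson_scores(x, target, mz = set$mz)
      )
      tb$method <- paste(tb$method, set$stat, sep = "_")
      tables[[length(tables) + 1L]] <- tb
    }
  }
  dir.create(file.path(config$out_dir, "scores"), showWarnings = FALSE)
  for (tb in tables) {
    write_score_table(tb, file.path(config$out_dir, "scores",
                                    paste0(tb$method[1], ".csv")))
  }
  refined <- refine_bins(tables, top_k = config$top_k, window = config$window)
  write_bin_config(refined, file.path(config$out_dir, "bins_refined.csv"))
  write_manifest(config, "select_bins",
                 list(n_tables = length(tables),
                      n_refined_intervals = nrow(refined)))
  log_info("select-bins", "%d tables -> %d intervals in %.1fs",
           length(tables), nrow(refined),
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(refined)
}

prepare_task <- function(features, task) {
  if (task == "binary") {
    lab <- ifelse(features$label == "CAO", "pure", "adulterated")
    keep <- features$label == "CAO" | startsWith(features$label, "CAO-")
    features <- features[keep, , drop = FALSE]
    features$label <- lab[keep]
  }
  features
}

layout_hash <- function(feature_names) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(feature_names, tf)
  unname(tools::md5sum(tf))
}

#' Train task models on a featurized run
#'
#' Splits the feature table (stratified 8:2), fits the configured embedding
#' on the training set, trains the requested model(s), and saves each model
#' with a JSON sidecar recording the spec, seeds and feature-layout hash.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the split, the fitted embedding and the
#'   fitted models.
#' @export
pipeline_train <- function(config) {
  t0 <- Sys.time()
  features <- read_feature_table(file.path(config$out_dir, "features.csv"))
  features <- prepare_task(features, config$task)
  split <- split_data(features, test_frac = config$test_frac,
                      seed = derive_seed(config$seed, 3L))
  emb <- embed_fit(split$train,
                   embed_config(config$embed_method,
                                seed = derive_seed(config$seed, 4L)))
  xtr <- emb$x
  hash <- layout_hash(colnames(feature_matrix(features)))
  dir.create(file.path(config$out_dir, "models"), showWarnings = FALSE)
  models <- list()
  if (config$task == "quantify") {
    spec <- do.call(quantifier_spec,
                    c(list(seed = derive_seed(config$seed, 5L)),
                      config$quantifier_args))
    fit <- train_quantifier(spec, list(
      x = xtr, y = as.matrix(split$train[fraction_cols()])))
    models$quantifier <- fit
    saveRDS(fit, file.path(config$out_dir, "models", "quantifier.rds"))
    sidecar <- list(kind = "quantifier", layout_hash = hash,
                    seed = spec$seed, embed = config$embed_method)
    jsonlite::write_json(sidecar,
                         file.path(config$out_dir, "models", "quantifier.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    for (kind in config$model) {
      spec <- classifier_spec(kind, seed = derive_seed(config$seed, 6L))
      fit <- train_classifier(spec, list(x = xtr, y = split$train$label))
      models[[kind]] <- fit
      saveRDS(fit, file.path(config$out_dir, "models", paste0(kind, ".rds")))
      jsonlite::write_json(
        list(kind = kind, layout_hash = hash, seed = spec$seed,
             embed = config$embed_method, task = config$task),
        file.path(config$out_dir, "models", paste0(kind, ".json")),
        auto_unbox = TRUE, pretty = TRUE)
    }
  }
  saveRDS(emb, file.path(config$out_dir, "models", "embedding.rds"))
  saveRDS(split, file.path(config$out_dir, "models", "split.rds"))
  write_manifest(config, "train", list(layout_hash = hash,
                                       n_train = nrow(split$train),
                                       n_test = nrow(split$test)))
  log_info("train", "task=%s models=%s in %.1fs", config$task,
           paste(config$model, collapse = ","),
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(split = split, embedding = emb, models = models,
                 layout_hash = hash))
}

#' Evaluate trained models on the held-out test set
#'
#' For qualitative tasks, writes a classification report per model; for the
#' quantitative task, repeats the train/predict cycle `n_runs` times with
#' per-run seeds and writes per-oil regression statistics as mean over SD.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of reports.
#' @export
pipeline_evaluate <- function(config) {
  features <- read_feature_table(file.path(config$out_dir, "features.csv"))
  features <- prepare_task(features, config$task)
  hash <- layout_hash(colnames(feature_matrix(features)))
  split <- readRDS(file.path(config$out_dir, "models", "split.rds"))
  emb <- readRDS(file.path(config$out_dir, "models", "embedding.rds"))
  xte <- predict(emb, split$test)
  out <- list()
  if (config$task == "quantify") {
    sidecar <- jsonlite::read_json(file.path(config$out_dir, "models",
                                             "quantifier.json"))
    if (!identical(sidecar$layout_hash, hash)) {
      stop_contract("feature layout hash mismatch: expected %s, got %s",
                    sidecar$layout_hash, hash)
    }
    runs <- repeated_runs(function(seed) {
      fit <- train_quantifier(
        do.call(quantifier_spec, c(list(seed = seed), config$quantifier_args)),
        list(
        x = emb$x, y = as.matrix(split$train[fraction_cols()])))
      pred <- predict(fit, xte)
      truth <- split$test[[fraction_cols()[1]]]
      rep <- regression_report(truth, pred[[fraction_cols()[1]]], "prediction")
      c(r2p = rep$r2, rmsep = rep$rmse, rpd = rep$rpd)
    }, n_runs = config$n_runs, base_seed = derive_seed(config$seed, 8L))
    readr::write_csv(runs$summary,
                     file.path(config$out_dir, "report_quantify.csv"))
    out$quantify <- runs
  } else {
    for (kind in config$model) {
      sidecar <- jsonlite::read_json(file.path(config$out_dir, "models",
                                               paste0(kind, ".json")))
      if (!identical(sidecar$layout_hash, hash)) {
        stop_contract("feature layout hash mismatch for model '%s'", kind)
      }
      model <- readRDS(file.path(config$out_dir, "models", paste0(kind, ".rds")))
      pred <- predict(model, xte)
      scores <- as.matrix(pred[model$levels])
      rep <- classification_report(split$test$label, pred$.pred_class, scores)
      readr::write_csv(rep$metrics,
                       file.path(config$out_dir,
                                 sprintf("report_%s_%s.csv", config$task, kind)))
      out[[kind]] <- rep
    }
  }
  write_manifest(config, "evaluate", list(layout_hash = hash))
  invisible(out)
}

#' Predict with a trained model on a new feature table
#'
#' @param config A [run_config()] with trained models in `out_dir`.
#' @param features_path Path of the feature table to predict on.
#' @param model Model kind (or `"quantifier"`).
#' @return The prediction tibble (also written to `predictions.csv`).
#' @export
pipeline_predict <- function(config, features_path,
                             model = config$model[1]) {
  features <- read_feature_table(features_path)
  emb <- readRDS(file.path(config$out_dir, "models", "embedding.rds"))
  x <- predict(emb, features)
  name <- if (config$task == "quantify") "quantifier" else model
  fit <- readRDS(file.path(config$out_dir, "models", paste0(name, ".rds")))
  pred <- predict(fit, x)
  pred <- dplyr::bind_cols(tibble(sample_id = features$sample_id), pred)
  readr::write_csv(pred, file.path(config$out_dir, "predictions.csv"))
  pred
}
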