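# End-to-end orchestration: simulate -> extract -> reduce -> train ->
# cross-validate -> explain -> report, with stage seeds derived from the
# master seed, artifact writing, and YAML/JSON config round-tripping.

#' Pipeline configuration
#'
#' @param n_per_class Subjects per class (default 116).
#' @param duration Recording length in seconds (default 60).
#' @param sampling_rate Sampling rate (default 256 Hz).
#' @param seed Master seed; every stage seed is a stable hash of it and the
#'   stage name.
#' @param n_components PCA components (default 21).
#' @param perplexity,tsne_iterations t-SNE parameters (defaults 50, 300).
#' @param train A [train_config()].
#' @param background_size SHAP background subset size (default 50).
#' @param n_coalitions Kernel SHAP coalition budget (default 2048).
#' @param n_explain Test samples explained per run (default 4, two per
#'   class, mirroring a small representative-case readout).
#' @param outdir Optional artifact directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_class = 116, duration = 60,
                            sampling_rate = 256, seed = 1,
                            n_components = 21, perplexity = 50,
                            tsne_iterations = 300,
                            train = train_config(),
                            background_size = 50, n_coalitions = 2048,
                            n_explain = 4, outdir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Save / load a pipeline configuration (YAML round trip)
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `save_config()` returns the path invisibly; `load_config()` the
#'   restored `pipeline_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$train <- unclass(lst$train)
  lst$schema_version <- config_schema_version
  yaml::write_yaml(lst, path)
  invisible(path)
}

config_schema_version <- 1L

#' @rdname save_config
#' @export
load_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ver <- lst$schema_version %||% 0L
  if (ver != config_schema_version)
    abort(sprintf(
      "config schema version %s is incompatible with this package (expects %d)",
      ver, config_schema_version))
  lst$schema_version <- NULL
  tr <- do.call(train_config, lst$train)
  lst$train <- NULL
  cfg <- do.call(pipeline_config, c(lst, list(train = tr)))
  cfg
}

#' Write a feature table to CSV
#'
#' Canonical layout: `subject_id`, the 31 feature slugs, `label`. Full
#' double precision (lossless round trip).
#'
#' @param table Feature table.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  split_feature_table(table)  # validates schema
  readr::write_csv(table, path)
  invisible(path)
}

#' Read a feature table from CSV, optionally through a schema mapping
#'
#' Without a mapping the file must already use the canonical layout. A
#' mapping (YAML file or list) adapts external schemas:
#' \describe{
#'   \item{aggregated}{`columns:` maps canonical slug -> source column name
#'     (plus `label:`).}
#'   \item{per_region}{wide `<region>_<feature>` layouts: `pattern:` (with
#'     `{region}` and `{feature}` placeholders), `regions:` canonical ->
#'     source region token, `features:` canonical slug -> source feature
#'     token, `label:` source label column. Per-region values are collapsed
#'     with the registry aggregation rules.}
#' }
#' Unknown columns are dropped with a warning; a missing canonical feature
#' is an error naming it.
#'
#' @param path CSV path.
#' @param mapping Optional mapping list or YAML path.
#' @return Canonical feature table tibble.
#' @export
read_feature_csv <- function(path, mapping = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(mapping)) {
    split_feature_table(raw)
    return(raw)
  }
  if (is.character(mapping)) mapping <- yaml::read_yaml(mapping)
  fmt <- mapping$format %||% "aggregated"
  feats <- feature_registry()$feature
  if (fmt == "aggregated") {
    cols <- mapping$columns
    missing <- setdiff(feats, names(cols))
    if (length(missing))
      abort(paste("mapping does not resolve canonical feature(s):",
                  paste(missing, collapse = ", ")))
    src <- unlist(cols)
    absent <- setdiff(src, names(raw))
    if (length(absent))
      abort(paste("mapped source column(s) absent from file:",
                  paste(absent, collapse = ", ")))
    out <- as_tibble(stats::setNames(raw[src], names(cols)))
    label_col <- mapping$label %||% "label"
    if (!label_col %in% names(raw))
      abort(paste("label column not found:", label_col))
    out$label <- as.integer(raw[[label_col]])
    extra <- setdiff(names(raw), c(src, label_col, "subject_id"))
    if (length(extra))
      warn(paste("dropping unmapped column(s):", paste(extra, collapse = ", ")))
    if ("subject_id" %in% names(raw)) out <- dplyr::bind_cols(
      tibble(subject_id = raw$subject_id), out)
    split_feature_table(out)
    return(out)
  }
  if (fmt == "per_region") {
    pattern <- mapping$pattern %||% "{region}_{feature}"
    fmap <- mapping$features
    rmap <- mapping$regions %||%
      stats::setNames(as.list(eeg_regions()), eeg_regions())
    missing <- setdiff(feats, names(fmap))
    if (length(missing))
      abort(paste("mapping does not resolve canonical feature(s):",
                  paste(missing, collapse = ", ")))
    label_col <- mapping$label %||% "label"
    if (!label_col %in% names(raw))
      abort(paste("label column not found:", label_col))
    used <- label_col
    rows <- lapply(seq_len(nrow(raw)), function(i) {
      per_region <- purrr::map_dfr(names(rmap), function(rg) {
        vals <- purrr::map_dbl(feats, function(fe) {
          col <- sub("\\{region\\}", rmap[[rg]],
                     sub("\\{feature\\}", fmap[[fe]], pattern))
          if (!col %in% names(raw))
            abort(paste("expected column missing:", col))
          as.numeric(raw[[col]][i])
        })
        dplyr::bind_cols(tibble(region = rg),
                         as_tibble(as.list(stats::setNames(vals, feats))))
      })
      aggregate_regions(per_region)
    })
    out <- dplyr::bind_rows(rows)
    out$label <- as.integer(raw[[label_col]])
    if ("subject_id" %in% names(raw))
      out <- dplyr::bind_cols(tibble(subject_id = raw$subject_id), out)
    split_feature_table(out)
    return(out)
  }
  abort(paste("unknown mapping format:", fmt))
}

#' Run the full pipeline end to end
#'
#' Simulates (or accepts) a feature table, splits 70/30 stratified, fits
#' standardizer + PCA on the training split only, embeds with t-SNE for
#' visualization, trains the CNN, evaluates on the held-out split, runs
#' stratified cross-validation, explains representative test samples with
#' Kernel SHAP, and back-projects importances onto the 31 features.
#' Deterministic given the config master seed.
#'
#' @param config A [pipeline_config()].
#' @param features Optional pre-extracted feature table (31 features +
#'   `label`); skips simulation and extraction.
#' @return A `run_report` list with elements `eval`, `cv`, `importance`,
#'   `tiers`, `explanation`, `pca`, `standardizer`, `embedding`, `model`,
#'   `split`, `stages`, `timings`, `artifacts`, `versions`.
#' @export
run_end_to_end <- function(config = pipeline_config(), features = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- character(0)
  timings <- numeric(0)
  tic <- function() proc.time()[["elapsed"]]
  mark <- function(stage, t0) {
    stages <<- c(stages, stage)
    timings <<- c(timings, tic() - t0)
  }
  if (is.null(features)) {
    t0 <- tic()
    spec <- cohort_spec(n_per_class = config$n_per_class,
                        sampling_rate = config$sampling_rate,
                        duration = config$duration,
                        seed = derive_seed(config$seed, "simulate"))
    features <- extract_feature_table(spec)
    mark("simulate+extract", t0)
  } else {
    split_feature_table(features)
  }
  parts <- split_feature_table(features)
  if (is.null(parts$label)) abort("feature table must carry a `label` column")
  y <- parts$label

  t0 <- tic()
  test_idx <- stratified_holdout(y, config$train$test_fraction,
                                 derive_seed(config$seed, "split"))
  train_tbl <- features[-test_idx, , drop = FALSE]
  test_tbl <- features[test_idx, , drop = FALSE]
  st <- fit_standardizer(train_tbl)
  pca <- fit_pca(standardize(st, train_tbl), n_components = config$n_components)
  sc_train <- pca_project(pca, standardize(st, train_tbl))
  sc_test <- pca_project(pca, standardize(st, test_tbl))
  sc_all <- pca_project(pca, standardize(st, features))
  mark("reduce", t0)

  t0 <- tic()
  emb <- tsne_embed(sc_all, perplexity = config$perplexity,
                    iterations = config$tsne_iterations,
                    seed = derive_seed(config$seed, "tsne"), label = y)
  mark("embed", t0)

  t0 <- tic()
  tr_cfg <- config$train
  tr_cfg$seed <- derive_seed(config$seed, "train")
  model <- train_cnn(sc_train, y[-test_idx], tr_cfg)
  eval <- evaluate_model(model, sc_test, y[test_idx])
  mark("train+evaluate", t0)

  t0 <- tic()
  cv_cfg <- config$train
  cv_cfg$seed <- derive_seed(config$seed, "cv")
  cv <- cross_validate(features, cv_cfg, n_components = config$n_components)
  mark("cross-validate", t0)

  t0 <- tic()
  bg_idx <- with_local_seed(derive_seed(config$seed, "background"),
                            sample(nrow(sc_train),
                                   min(config$background_size, nrow(sc_train))))
  background <- sc_train[bg_idx, , drop = FALSE]
  yte <- y[test_idx]
  per_class <- max(1L, config$n_explain %/% 2L)
  pick <- c(which(yte == 0)[seq_len(min(per_class, sum(yte == 0)))],
            which(yte == 1)[seq_len(min(per_class, sum(yte == 1)))])
  expl <- explain_samples(model, sc_test[pick, , drop = FALSE], background,
                          n_coalitions = config$n_coalitions,
                          seed = derive_seed(config$seed, "shap"))
  importance <- backproject_importance(expl, pca)
  tiers <- rank_and_bucket(importance)
  mark("explain", t0)

  report <- structure(list(
    eval = eval, cv = cv, importance = importance, tiers = tiers,
    explanation = expl, pca = pca, standardizer = st, embedding = emb,
    model = model, features = features,
    split = list(test_idx = test_idx, explained_idx = test_idx[pick],
                 background_idx = bg_idx),
    stages = stages, timings = stats::setNames(timings, stages),
    config = config,
    versions = list(package = as.character(utils::packageVersion("neurodep")),
                    r = R.version.string)
  ), class = "run_report")
  if (!is.null(config$outdir)) report$artifacts <- write_artifacts(report, config$outdir)
  report
}

write_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    features = file.path(outdir, "features.csv"),
    embedding = file.path(outdir, "embedding.csv"),
    metrics = file.path(outdir, "metrics.csv"),
    history = file.path(outdir, "history.csv"),
    importance = file.path(outdir, "importance.csv"),
    shap_values = file.path(outdir, "shap_values.csv"),
    cv = file.path(outdir, "cv_summary.csv"),
    config = file.path(outdir, "config.yaml"),
    report = file.path(outdir, "report.json")
  )
  readr::write_csv(report$features, paths$features)
  readr::write_csv(as_tibble(report$embedding), paths$embedding)
  readr::write_csv(report$eval$metrics, paths$metrics)
  readr::write_csv(report$model$history, paths$history)
  readr::write_csv(as_tibble(report$tiers), paths$importance)
  shap_tbl <- as_tibble(as.data.frame(report$explanation$phi))
  names(shap_tbl) <- paste0("PC", seq_len(ncol(shap_tbl)))
  shap_tbl$fx <- report$explanation$fx
  shap_tbl$base <- report$explanation$base
  readr::write_csv(shap_tbl, paths$shap_values)
  readr::write_csv(report$cv$summary, paths$cv)
  save_config(report$config, paths$config)
  jsonlite::write_json(make_report(report), paths$report, auto_unbox = TRUE,
                       digits = NA)
  paths
}

#' Summarize a pipeline run as a plain list (JSON-ready)
#'
#' Emits the metrics table, CV mean ± SD, explained-variance summary and
#' the tiered importance list.
#'
#' @param report A `run_report`.
#' @return A named list.
#' @export
make_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  list(
    accuracy = report$eval$accuracy,
    metrics = as.data.frame(report$eval$metrics),
    cv = list(
      mean = report$cv$accuracy_mean, sd = report$cv$accuracy_sd,
      display = sprintf("%.1f%% ± %.1f%%", 100 * report$cv$accuracy_mean,
                        100 * report$cv$accuracy_sd),
      folds = as.data.frame(report$cv$summary)
    ),
    pca_variance_retained = sum(report$pca$variance_ratio),
    importance = as.data.frame(report$tiers),
    tier_counts = as.list(table(report$tiers$tier)),
    stages = report$stages,
    timings = as.list(report$timings),
    versions = report$versions
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("neurodep pipeline run\n")
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = " -> ")))
  cat(sprintf("  held-out accuracy: %.1f%%\n", 100 * x$eval$accuracy))
  cat(sprintf("  CV accuracy: %.1f%% ± %.1f%%\n",
              100 * x$cv$accuracy_mean, 100 * x$cv$accuracy_sd))
  cat(sprintf("  variance retained by %d PCs: %.1f%%\n",
              x$pca$n_components, 100 * sum(x$pca$variance_ratio)))
  top <- utils::head(x$importance, 3)
  cat("  top features:", paste(top$feature, collapse = ", "), "\n")
  invisible(x)
}
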