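#' Fit the fusion model on the full study
#'
#' Convenience wrapper: fits the complete pipeline (scaling, base models,
#' grids, fused matrix, OPLS-DA with LOO-selected orthogonal components
#' and VIP filter) on all samples — the final interpretable model whose
#' weight maps are plotted — and refolds the predictive weights into
#' per-aliquot leukocyte maps.
#'
#' @param dataset A [study_dataset()].
#' @param config A [pipeline_config()].
#' @return The [fit_fold()] bundle with an extra `weight_maps` element
#'   (`F x F x M` [refold_weights()] array).
#' @export
fit_fusion_model <- function(dataset, config = pipeline_config()) {
  bundle <- fit_fold(dataset, dataset$samples, config)
  if (config$features == "histogram" && config$classifier == "oplsda") {
    bundle$weight_maps <- refold_weights(bundle$model$w_top, bundle$F,
                                         length(bundle$aliquots),
                                         aliquot_ids = bundle$aliquots)
  }
  bundle
}

#' Per-class mean histograms of a fitted bundle
#'
#' Averages the unit-sum sample histograms per class and aliquot; used
#' for the density contours of the leukocyte maps ("where, on average, a
#' given fraction of a class's cells lie").
#'
#' @param bundle A [fit_fold()]/[fit_fusion_model()] bundle with
#'   histogram features.
#' @param dataset The [study_dataset()].
#' @return Nested list: aliquot -> class -> F x F matrix.
#' @export
class_mean_histograms <- function(bundle, dataset) {
  stopifnot(bundle$config$features == "histogram")
  rows <- featurize_samples(bundle, dataset, dataset$samples)
  rows <- sweep(rows, 2L, bundle$column_means, "+")  # undo centring
  out <- list()
  for (a in bundle$aliquots) {
    cols <- bundle$block_index[[a]]
    out[[a]] <- lapply(stats::setNames(nm = sort(unique(dataset$labels))),
      function(cl) {
        smp <- dataset$samples[dataset$labels[dataset$samples] == cl]
        refold_histogram(colMeans(rows[smp, cols, drop = FALSE]), bundle$F)
      })
  }
  out
}

#' Serialize a fitted fusion model
#'
#' Writes a versioned, portable JSON archive of everything needed to
#' score new samples: scalers, base-model loadings and means, grid
#' edges, fused-matrix column means, OPLS-DA weights, orthogonal
#' components, regression scalar and threshold.
#'
#' @param bundle A [fit_fold()]/[fit_fusion_model()] bundle.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(bundle, path) {
  m <- bundle$model
  obj <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("cytofuse")),
    aliquots = bundle$aliquots, F = bundle$F,
    scheme = bundle$config$scheme, cofactor = bundle$config$cofactor,
    scalers = bundle$scalers,
    base_models = lapply(bundle$base_models, function(b) {
      list(loadings = b$loadings, column_means = b$column_means,
           marker_names = b$marker_names)
    }),
    grid_edges = lapply(bundle$grids, `[[`, "edges"),
    smoothing_sd = bundle$config$smoothing_sd,
    column_means = bundle$column_means,
    w_top = m$w_top, K_ortho = m$K_ortho,
    ortho_weights = m$ortho_weights, ortho_loadings = m$ortho_loadings,
    b = m$b, intercept = m$intercept, threshold = m$threshold,
    y_coding = as.list(m$y_coding))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML file whose keys mirror the [pipeline_config()] arguments, plus
#' `manifest` (study manifest CSV), `out_dir`, optional `gates` (map
#' aliquot -> predicate string) and `run_permutation` (number of
#' permutations, 0 to skip).
#'
#' @param path YAML file.
#' @return List with `config` ([pipeline_config()]), `manifest`,
#'   `out_dir`, `gates`, `run_permutation`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw),
                     c(known, "manifest", "out_dir", "gates",
                       "run_permutation"))
  if (length(unknown)) {
    cf_stop("cytofuse_config_error", "unknown config key(s): %s",
            paste(unknown, collapse = ", "))
  }
  config <- do.call(pipeline_config, raw[intersect(names(raw), known)])
  list(config = config, manifest = raw$manifest, out_dir = raw$out_dir,
       gates = raw$gates, run_permutation = raw$run_permutation %||% 0L)
}

#' Apply configured gates to a dataset
#'
#' @param dataset A [study_dataset()].
#' @param gates Named list: aliquot id -> predicate string (see
#'   [gate_expression()]).
#' @return The gated dataset.
#' @export
apply_gates <- function(dataset, gates) {
  if (is.null(gates) || length(gates) == 0L) return(dataset)
  for (a in names(gates)) {
    expr <- gate_expression(gates[[a]])
    for (key in names(dataset$frames)) {
      if (dataset$frames[[key]]$aliquot_id == a) {
        dataset$frames[[key]] <- gate(dataset$frames[[key]], expr)
      }
    }
  }
  dataset
}

#' Run the end-to-end fusion pipeline
#'
#' Reads the study, applies gates, draws (or reuses) stored splits, runs
#' the repeated double cross-validation, fits the final full-data model,
#' optionally runs the permutation test with the hyperparameters fixed
#' to the modal cross-validated choice, and writes all artifacts
#' (metrics CSV, splits JSON, model archive, figures, provenance log)
#' into the output directory. Reruns with an identical configuration and
#' seed produce identical metrics.
#'
#' @param run Either a path to a YAML run configuration (see
#'   [read_run_config()]) or the list that function returns.
#' @param dataset Optional pre-loaded [study_dataset()] (overrides the
#'   manifest path).
#' @return Invisibly, a list with `cv`, `bundle`, `splits`,
#'   `permutation` and the output directory.
#' @export
run_pipeline <- function(run, dataset = NULL) {
  if (is.character(run)) run <- read_run_config(run)
  config <- run$config
  out_dir <- run$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(dataset)) {
    if (is.null(run$manifest)) {
      cf_stop("cytofuse_config_error", "no manifest and no dataset supplied")
    }
    dataset <- read_study(run$manifest)
  }
  dataset <- apply_gates(dataset, run$gates)

  splits <- make_splits(dataset$labels, groups = dataset$individuals,
                        n_folds = config$n_folds,
                        n_repetitions = config$n_repetitions,
                        seed = config$seed)
  write_splits(splits, file.path(out_dir, "splits.json"))

  cv <- run_double_cv(dataset, config, splits)
  metrics <- data.frame(
    metric = c("accuracy", "sensitivity", "specificity", "threshold"),
    value = c(cv$accuracy, cv$sensitivity, cv$specificity, cv$threshold))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(sample = names(cv$mean_scores),
               label = unname(cv$labels[names(cv$mean_scores)]),
               mean_score = unname(cv$mean_scores),
               predicted = unname(cv$predicted)),
    file.path(out_dir, "scores.csv"), row.names = FALSE)

  bundle <- fit_fusion_model(dataset, config)
  write_model_json(bundle, file.path(out_dir, "model.json"))

  plot_scores(cv$mean_scores, dataset$labels, cv$threshold,
              positive_class = cv$positive_class,
              file = file.path(out_dir, "scores.png"))
  if (!is.null(bundle$weight_maps)) {
    cmh <- class_mean_histograms(bundle, dataset)
    for (a in bundle$aliquots) {
      plot_leukocyte_map(bundle$weight_maps, a, bundle$base_models[[a]],
                         bundle$grids[[a]], class_histograms = cmh[[a]],
                         file = file.path(out_dir, sprintf("map_%s.png", a)))
    }
  }

  perm <- NULL
  n_perm <- run$run_permutation %||% 0L
  if (n_perm > 0L) {
    k_tab <- table(cv$K_ortho)
    k_mode <- as.integer(names(k_tab)[which.max(k_tab)])
    perm <- permutation_test(dataset, config, splits, cv$accuracy,
                             fixed_hyperparameters = list(K_ortho = k_mode),
                             n_permutations = n_perm, seed = config$seed + 1L)
    utils::write.csv(
      data.frame(permutation = seq_along(perm$null_accuracies),
                 accuracy = perm$null_accuracies),
      file.path(out_dir, "permutation_null.csv"), row.names = FALSE)
  }

  cfg_json <- jsonlite::toJSON(config, digits = NA, auto_unbox = TRUE,
                               force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  prov <- list(
    package = "cytofuse",
    version = as.character(utils::packageVersion("cytofuse")),
    config = config, config_hash = unname(tools::md5sum(tmp)),
    seed = config$seed, n_samples = length(dataset$samples),
    aliquots = dataset$aliquots,
    p_bound = if (!is.null(perm)) perm$p_bound else NULL)
  unlink(tmp)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)

  invisible(list(cv = cv, bundle = bundle, splits = splits,
                 permutation = perm, out_dir = out_dir))
}

#' Compare classification methods on identical stored splits
#'
#' Runs the requested method arms — histogram fusion with OPLS-DA
#' (`damacy_fusion`), linear SVM on the fused histograms (`damacy_svm`),
#' and SOM node counts with SVM / lasso / OPLS-DA (`som_svm`,
#' `som_lasso`, `som_oplsda`) — through the same double cross-validation
#' with the same stored splits, and tabulates the metrics.
#'
#' @param dataset A [study_dataset()].
#' @param config Base [pipeline_config()]; `features`/`classifier` are
#'   overridden per method.
#' @param splits Stored [make_splits()].
#' @param methods Character vector of method names.
#' @param repetitions Subset of repetitions (default all).
#' @return Data frame: method, accuracy, sensitivity, specificity.
#' @export
compare_methods <- function(dataset, config = pipeline_config(), splits,
                            methods = c("damacy_fusion", "som_svm",
                                        "damacy_svm", "som_lasso",
                                        "som_oplsda"),
                            repetitions = NULL) {
  arms <- list(
    damacy_fusion = c("histogram", "oplsda"),
    damacy_svm = c("histogram", "svm"),
    som_svm = c("som", "svm"),
    som_lasso = c("som", "lasso"),
    som_oplsda = c("som", "oplsda"))
  rows <- lapply(methods, function(mth) {
    if (!mth %in% names(arms)) {
      cf_stop("cytofuse_config_error", "unknown method '%s'", mth)
    }
    cfg <- config
    cfg$features <- arms[[mth]][1L]
    cfg$classifier <- arms[[mth]][2L]
    cv <- run_double_cv(dataset, cfg, splits, repetitions)
    data.frame(method = mth, accuracy = cv$accuracy,
               sensitivity = cv$sensitivity, specificity = cv$specificity)
  })
  do.call(rbind, rows)
}
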