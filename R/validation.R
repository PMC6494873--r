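#' Pipeline configuration
#'
#' Collects every tunable of the fusion pipeline. Defaults follow the
#' method's published settings: arcsinh cofactor 150, `K_base = 2`
#' principal components, `F = 100` histogram bins per dimension (500 is
#' the method default for densely sampled data; 100 suits samples with
#' fewer than 10,000 cells), 5 folds x 50 repetitions, 1000 permutations
#' and VIP threshold 1.
#'
#' @param scheme Centring/scaling scheme, `"cohort_reference"` or
#'   `"paired_individual"`.
#' @param reference_class Reference class for the cohort scheme (default
#'   `"control"` when present, else the alphabetically first class).
#' @param cofactor Arcsinh cofactor applied to raw frames.
#' @param K_base Principal components of the per-aliquot base model.
#' @param F Histogram bins per dimension.
#' @param margin_fraction Grid margin as a fraction of the training score
#'   range.
#' @param smoothing_sd Histogram smoothing kernel width in bins.
#' @param K_ortho Fixed number of orthogonal components; `NULL` (default)
#'   selects it per training fold by internal leave-one-out CV.
#' @param K_ortho_max Upper bound for the leave-one-out selection.
#' @param vip_threshold VIP threshold; `NULL` disables the filter.
#' @param refit_after_vip Refit the OPLS components on the retained
#'   variables after filtering (default `FALSE`: weights are zeroed only).
#' @param features `"histogram"` (fused smoothed histograms) or `"som"`
#'   (self-organising-map node counts).
#' @param classifier `"oplsda"`, `"svm"` (linear, box constraint 1) or
#'   `"lasso"` (logistic, 10-fold inner CV for lambda).
#' @param som Options for the SOM featurizer: `grid_dim`, `n_epochs`,
#'   `normalize` (`"fraction"` or `"count"`).
#' @param positive_class Class coded +1 (default `"case"` when present).
#' @param n_folds,n_repetitions Outer cross-validation design.
#' @param n_permutations Label permutations for the permutation test.
#' @param seed Master seed for splits/permutations.
#'
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scheme = "cohort_reference",
                            reference_class = NULL, cofactor = 150,
                            K_base = 2L, F = 100L, margin_fraction = 0.05,
                            smoothing_sd = 2, K_ortho = NULL,
                            K_ortho_max = 5L, vip_threshold = 1,
                            refit_after_vip = FALSE,
                            features = c("histogram", "som"),
                            classifier = c("oplsda", "svm", "lasso"),
                            som = list(grid_dim = c(10L, 10L),
                                       n_epochs = 10L,
                                       normalize = "fraction"),
                            positive_class = NULL, n_folds = 5L,
                            n_repetitions = 50L, n_permutations = 1000L,
                            seed = 1L) {
  structure(
    list(scheme = match.arg(scheme, c("cohort_reference", "paired_individual")),
         reference_class = reference_class, cofactor = cofactor,
         K_base = as.integer(K_base), F = as.integer(F),
         margin_fraction = margin_fraction, smoothing_sd = smoothing_sd,
         K_ortho = K_ortho, K_ortho_max = as.integer(K_ortho_max),
         vip_threshold = vip_threshold,
         refit_after_vip = isTRUE(refit_after_vip),
         features = match.arg(features), classifier = match.arg(classifier),
         som = som, positive_class = positive_class,
         n_folds = as.integer(n_folds),
         n_repetitions = as.integer(n_repetitions),
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

default_reference_class <- function(dataset, config) {
  config$reference_class %||%
    (if ("control" %in% dataset$classes) "control" else dataset$classes[1L])
}

default_positive_class <- function(dataset, config) {
  config$positive_class %||%
    (if ("case" %in% dataset$classes) "case" else dataset$classes[2L])
}

#' Create stored stratified cross-validation splits
#'
#' Assigns individuals (groups of samples) to `n_folds` folds,
#' `n_repetitions` times, stratified by class so per-fold class counts
#' differ by at most one from proportional, with overall fold sizes as
#' equal as possible. All samples of one individual are constrained to
#' the same fold (prevents identity leakage in paired designs).
#' Assignments are drawn once under the seed and stored, so every method
#' under comparison reuses the identical splits.
#'
#' @param labels Named character vector: sample id -> class label.
#' @param groups Named character vector: sample id -> individual id
#'   (default: each sample is its own group).
#' @param n_folds Number of folds (default 5).
#' @param n_repetitions Number of repeated splittings (default 50).
#' @param seed RNG seed; identical seeds give identical splits.
#'
#' @return Object of class `cv_splits` with `assignments` (group x
#'   repetition fold-id matrix), `group_samples`, `n_folds`,
#'   `n_repetitions`, `seed`.
#' @export
make_splits <- function(labels, groups = NULL, n_folds = 5L,
                        n_repetitions = 50L, seed = 1L) {
  samples <- names(labels)
  stopifnot(!is.null(samples))
  groups <- groups %||% stats::setNames(samples, samples)
  group_ids <- unique(unname(groups[samples]))
  group_samples <- split(samples, unname(groups[samples]))[group_ids]
  # stratum = class composition of the group (single-class for
  # case-control designs, mixed for paired pre/post designs)
  strata <- vapply(group_samples, function(s) {
    paste(sort(unique(unname(labels[s]))), collapse = "+")
  }, "")
  n_groups <- length(group_ids)
  if (n_groups < n_folds) {
    cf_stop("cytofuse_config_error", "fewer groups (%d) than folds (%d)",
            n_groups, n_folds)
  }
  set.seed(seed)
  assignments <- matrix(NA_integer_, n_groups, n_repetitions,
                        dimnames = list(group_ids, NULL))
  for (r in seq_len(n_repetitions)) {
    for (try in 1:100) {
      fold_of <- stats::setNames(integer(n_groups), group_ids)
      totals <- numeric(n_folds)
      for (st in names(sort(table(strata), decreasing = TRUE))) {
        g <- sample(group_ids[strata == st])
        base <- length(g) %/% n_folds
        r_extra <- length(g) %% n_folds
        quota <- rep(base, n_folds)
        if (r_extra > 0L) {
          pick <- order(totals, sample.int(n_folds))[seq_len(r_extra)]
          quota[pick] <- quota[pick] + 1L
        }
        slots <- sample(rep(seq_len(n_folds), times = quota))
        fold_of[g] <- slots
        for (k in seq_along(g)) {
          totals[slots[k]] <- totals[slots[k]] + length(group_samples[[g[k]]])
        }
      }
      ok <- all(vapply(seq_len(n_folds), function(f) {
        tr <- unlist(group_samples[names(fold_of)[fold_of != f]])
        length(unique(unname(labels[tr]))) >= 2L && any(fold_of == f)
      }, TRUE))
      if (ok) break
      if (try == 100L) {
        cf_stop("cytofuse_config_error",
                "could not draw folds with two-class training sets")
      }
    }
    assignments[, r] <- fold_of[group_ids]
  }
  structure(
    list(assignments = assignments, group_samples = group_samples,
         n_folds = as.integer(n_folds),
         n_repetitions = as.integer(n_repetitions), seed = as.integer(seed)),
    class = "cv_splits"
  )
}

#' Samples held out in one (repetition, fold) cell
#' @param splits A [make_splits()] result.
#' @param repetition,fold Indices.
#' @return Character vector of test sample ids.
#' @export
test_samples <- function(splits, repetition, fold) {
  g <- rownames(splits$assignments)[splits$assignments[, repetition] == fold]
  unlist(splits$group_samples[g], use.names = FALSE)
}

#' Write / read stored splits
#'
#' Splits are serialized as JSON so that every method under comparison
#' can reuse the identical file.
#'
#' @param splits A [make_splits()] result.
#' @param path File path.
#' @return `read_splits()` returns the `cv_splits` object.
#' @export
write_splits <- function(splits, path) {
  obj <- list(assignments = splits$assignments,
              group_ids = rownames(splits$assignments),
              group_samples = splits$group_samples,
              n_folds = splits$n_folds,
              n_repetitions = splits$n_repetitions, seed = splits$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_splits
#' @export
read_splits <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignments <- as.matrix(obj$assignments)
  rownames(assignments) <- obj$group_ids
  structure(
    list(assignments = assignments,
         group_samples = lapply(obj$group_samples, as.character),
         n_folds = as.integer(obj$n_folds),
         n_repetitions = as.integer(obj$n_repetitions),
         seed = as.integer(obj$seed)),
    class = "cv_splits"
  )
}

# ---- fold pipeline ---------------------------------------------------------

arcsinh_if_raw <- function(frame, cofactor) {
  if (frame$transform_state == "raw") arcsinh_transform(frame, cofactor) else frame
}

#' Fit the full fold pipeline on training samples only
#'
#' Runs every training-dependent stage — scaling, per-aliquot PCA base
#' models, histogram grids, fused-matrix column means, featurization and
#' the classifier (including the internal leave-one-out selection of the
#' number of orthogonal components and the VIP filter) — using the
#' training samples exclusively. The returned bundle contains everything
#' needed to score held-out samples with [predict_fold()]; no statistic
#' in it depends on any non-training frame.
#'
#' @param dataset A [study_dataset()].
#' @param train_samples Sample ids of the training fold.
#' @param config A [pipeline_config()].
#'
#' @return Object of class `fold_bundle`.
#' @export
fit_fold <- function(dataset, train_samples, config = pipeline_config()) {
  ds <- subset_study(dataset, samples = train_samples)
  for (key in names(ds$frames)) {
    ds$frames[[key]] <- arcsinh_if_raw(ds$frames[[key]], config$cofactor)
  }
  ref_class <- default_reference_class(ds, config)
  pos_class <- default_positive_class(dataset, config)
  sc <- scale_study(ds, scheme = config$scheme, reference_class = ref_class,
                    training_samples = train_samples)
  ds <- sc$dataset

  base_models <- list()
  grids <- list()
  som_models <- list()
  feat_rows <- NULL
  if (config$features == "histogram") {
    hists <- list()
    for (a in ds$aliquots) {
      frames <- lapply(train_samples, function(s) get_frame(ds, s, a))
      bm <- fit_base_model(frames, K_base = config$K_base)
      pooled_scores <- do.call(rbind, lapply(frames, project_cells, model = bm))
      gr <- make_grid(pooled_scores, F = config$F,
                      margin_fraction = config$margin_fraction,
                      smoothing_sd = config$smoothing_sd)
      base_models[[a]] <- bm
      grids[[a]] <- gr
      for (s in train_samples) {
        hists[[length(hists) + 1L]] <-
          histogram_sample(project_cells(get_frame(ds, s, a), bm), gr,
                           sample_id = s, aliquot_id = a)
      }
    }
    fused <- fuse_histograms(hists, sample_ids = train_samples,
                             aliquot_ids = ds$aliquots)
    feat_rows <- fused$H
    block_index <- fused$block_index
    F_used <- fused$F
  } else {
    counts <- list()
    for (a in ds$aliquots) {
      frames <- lapply(train_samples, function(s) get_frame(ds, s, a))
      pooled <- do.call(rbind, lapply(frames, `[[`, "events"))
      som <- fit_som(pooled, grid_dim = config$som$grid_dim,
                     n_epochs = config$som$n_epochs %||% 10L)
      som$aliquot_id <- a
      som_models[[a]] <- som
      counts[[a]] <- t(vapply(frames, function(fr) {
        cnt <- count_node_assignments(fr$events, som)
        if (identical(config$som$normalize %||% "fraction", "fraction")) {
          cnt / sum(cnt)
        } else cnt
      }, numeric(nrow(som$codebook))))
    }
    feat_rows <- do.call(cbind, counts)
    rownames(feat_rows) <- train_samples
    nn <- nrow(som_models[[1L]]$codebook)
    block_index <- lapply(seq_along(ds$aliquots), function(m) {
      ((m - 1L) * nn + 1L):(m * nn)
    })
    names(block_index) <- ds$aliquots
    F_used <- NA_integer_
  }

  ctr <- centre_fused(feat_rows, train_samples)
  Xc <- ctr$H_centred
  y <- code_labels(ds$labels[train_samples], pos_class)

  K_chosen <- NA_integer_
  vip <- NULL
  if (config$classifier == "oplsda") {
    K_chosen <- if (!is.null(config$K_ortho)) as.integer(config$K_ortho) else {
      select_K_ortho(feat_rows, y, K_max = config$K_ortho_max)
    }
    model <- fit_oplsda(Xc, y, K_ortho = K_chosen)
    if (!is.null(config$vip_threshold)) {
      vip <- compute_vip(model, threshold = config$vip_threshold)
      model <- apply_vip_filter(model, vip, threshold = config$vip_threshold,
                                refit = config$refit_after_vip)
    }
    threshold <- model$threshold
  } else if (config$classifier == "svm") {
    yf <- factor(names_to_class(y), levels = c(attr(y, "coding")[["negative"]],
                                               attr(y, "coding")[["positive"]]))
    model <- fit_linear_svm(Xc, yf, box_constraint = 1)
    threshold <- 0
  } else {
    yf <- factor(names_to_class(y), levels = c(attr(y, "coding")[["negative"]],
                                               attr(y, "coding")[["positive"]]))
    model <- fit_lasso_logistic(Xc, yf, n_inner_folds = 10L,
                                lambda = config$lasso_lambda)
    threshold <- 0
  }

  structure(
    list(config = config, aliquots = ds$aliquots,
         train_samples = train_samples, scalers = sc$scalers,
         base_models = base_models, grids = grids, som_models = som_models,
         column_means = ctr$column_means, block_index = block_index,
         F = F_used, model = model, threshold = threshold,
         K_ortho = K_chosen, vip = vip,
         reference_class = ref_class, positive_class = pos_class,
         negative_class = setdiff(c(attr(y, "coding")), pos_class)),
    class = "fold_bundle"
  )
}

names_to_class <- function(y) {
  coding <- attr(y, "coding")
  ifelse(y > 0, coding[["positive"]], coding[["negative"]])
}

featurize_samples <- function(bundle, dataset, samples) {
  config <- bundle$config
  rows <- list()
  for (s in samples) {
    blocks <- list()
    for (a in bundle$aliquots) {
      fr <- arcsinh_if_raw(get_frame(dataset, s, a), config$cofactor)
      if (config$scheme == "cohort_reference") {
        fr <- apply_scaler(fr, bundle$scalers[[a]])
      } else {
        ind <- fr$individual_id
        smp <- dataset$samples[dataset$individuals == ind]
        frames <- lapply(smp, function(si) {
          arcsinh_if_raw(get_frame(dataset, si, a), config$cofactor)
        })
        fr <- paired_individual_scaler(frames)[[which(smp == s)]]
      }
      if (config$features == "histogram") {
        h <- histogram_sample(project_cells(fr, bundle$base_models[[a]]),
                              bundle$grids[[a]], sample_id = s, aliquot_id = a)
        blocks[[a]] <- unfold_histogram(h$values)
      } else {
        cnt <- count_node_assignments(fr$events, bundle$som_models[[a]])
        blocks[[a]] <- if (identical(config$som$normalize %||% "fraction",
                                     "fraction")) cnt / sum(cnt) else cnt
      }
    }
    rows[[s]] <- unlist(blocks, use.names = FALSE)
  }
  X <- do.call(rbind, rows)
  rownames(X) <- samples
  sweep(X, 2L, bundle$column_means, "-")
}

#' Score held-out samples with a fitted fold bundle
#'
#' Held-out frames pass through the training-fitted scalers, base models,
#' grids and column means, then through the fold's classifier.
#'
#' @param bundle A [fit_fold()] result.
#' @param dataset The full [study_dataset()].
#' @param samples Sample ids to score.
#' @return Named numeric vector of prediction scores (positive class
#'   above the bundle's `threshold`).
#' @export
predict_fold <- function(bundle, dataset, samples) {
  Xc <- featurize_samples(bundle, dataset, samples)
  scores <- switch(bundle$config$classifier,
    oplsda = predict(bundle$model, Xc),
    svm = predict_svm_scores(bundle$model, Xc),
    lasso = predict_lasso_scores(bundle$model, Xc))
  stats::setNames(as.vector(scores), samples)
}

# ---- double cross-validation ----------------------------------------------

cv_metrics <- function(truth, predicted, positive_class, negative_class) {
  pos <- truth == positive_class
  neg <- truth == negative_class
  list(accuracy = mean(predicted == truth),
       sensitivity = mean(predicted[pos] == truth[pos]),
       specificity = mean(predicted[neg] == truth[neg]))
}

#' Repeated stratified double cross-validation
#'
#' For every (repetition, fold) of the stored splits the entire pipeline
#' — scaler, PCA base models, histogram grids, fused-matrix centring,
#' orthogonal-component selection (internal leave-one-out), OPLS-DA and
#' VIP filter (or a comparator featurizer/classifier) — is fitted on the
#' training individuals only, and prediction scores are recorded for the
#' held-out individuals. Each sample therefore collects one test score
#' per repetition; the per-sample mean is the "mean prediction score"
#' used for the final classification and the reported metrics.
#'
#' @param dataset A [study_dataset()].
#' @param config A [pipeline_config()].
#' @param splits A [make_splits()] result (reused across all methods
#'   under comparison).
#' @param repetitions Subset of repetitions to run (default all).
#'
#' @return Object of class `cv_result` with `y_hat` (sample x repetition
#'   test scores), `mean_scores`, `threshold` (mean of the per-fold
#'   training thresholds), `predicted`, `accuracy`, `sensitivity`,
#'   `specificity`, `K_ortho` (repetition x fold) and `fold_thresholds`.
#' @export
run_double_cv <- function(dataset, config = pipeline_config(), splits,
                          repetitions = NULL) {
  stopifnot(inherits(splits, "cv_splits"))
  reps <- repetitions %||% seq_len(splits$n_repetitions)
  samples <- dataset$samples
  y_hat <- matrix(NA_real_, length(samples), length(reps),
                  dimnames = list(samples, NULL))
  K_mat <- matrix(NA_integer_, length(reps), splits$n_folds)
  thr_mat <- matrix(NA_real_, length(reps), splits$n_folds)
  for (ri in seq_along(reps)) {
    r <- reps[ri]
    for (f in seq_len(splits$n_folds)) {
      test <- intersect(test_samples(splits, r, f), samples)
      if (length(test) == 0L) next
      train <- setdiff(samples, test)
      bundle <- tryCatch(fit_fold(dataset, train, config),
        error = function(e) {
          cf_stop("cytofuse_cv_error", "repetition %d, fold %d: %s",
                  r, f, conditionMessage(e))
        })
      y_hat[test, ri] <- predict_fold(bundle, dataset, test)
      K_mat[ri, f] <- bundle$K_ortho
      thr_mat[ri, f] <- bundle$threshold
    }
  }
  pos <- default_positive_class(dataset, config)
  neg <- setdiff(dataset$classes, pos)
  mean_scores <- rowMeans(y_hat, na.rm = TRUE)
  threshold <- mean(thr_mat, na.rm = TRUE)
  predicted <- ifelse(mean_scores > threshold, pos, neg)
  met <- cv_metrics(dataset$labels[samples], predicted, pos, neg)
  structure(
    c(list(y_hat = y_hat, mean_scores = mean_scores, threshold = threshold,
           predicted = predicted, labels = dataset$labels[samples],
           K_ortho = K_mat, fold_thresholds = thr_mat,
           positive_class = pos, negative_class = neg,
           n_repetitions = length(reps)),
      met),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d samples, %d repetitions\n",
              length(x$mean_scores), x$n_repetitions))
  cat(sprintf("  accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Permutation p-value bound
#'
#' `p < (sum(null >= observed) + 1) / n`: the fraction of permuted-label
#' accuracies at least as high as the observed one, with the +1 guard of
#' the standard permutation bound.
#'
#' @param null_accuracies Vector of accuracies under permuted labels.
#' @param observed Observed (unpermuted) accuracy.
#' @param n Denominator (default: number of permutations supplied).
#' @return The p-value bound.
#' @export
perm_p_bound <- function(null_accuracies, observed, n = length(null_accuracies)) {
  (sum(null_accuracies >= observed, na.rm = TRUE) + 1) / n
}

#' Permutation test with fixed hyperparameters
#'
#' Class labels are permuted at the individual level (all samples of an
#' individual move together; for paired designs with both classes inside
#' each individual the pair's labels are swapped as a unit). For every
#' permutation the pipeline is refitted and scored on the stored splits
#' with the hyperparameters fixed to the values selected on the
#' unpermuted data (number of orthogonal components; lasso lambda), so no
#' inner selection loop is run. By default a single repetition of the
#' split design is used per permutation.
#'
#' @param dataset A [study_dataset()].
#' @param config A [pipeline_config()].
#' @param splits A [make_splits()] result.
#' @param observed_accuracy Accuracy of the unpermuted model (from
#'   [run_double_cv()]).
#' @param fixed_hyperparameters List with `K_ortho` (and/or `lambda`)
#'   taken from the unpermuted fit.
#' @param n_permutations Number of permutations (denominator of the
#'   p bound follows this value).
#' @param n_repetitions Split repetitions evaluated per permutation.
#' @param seed RNG seed for the permutations.
#'
#' @return Object of class `permutation_result` with `null_accuracies`,
#'   `observed_accuracy`, `p_bound`, `n_permutations`.
#' @export
permutation_test <- function(dataset, config, splits, observed_accuracy,
                             fixed_hyperparameters = list(),
                             n_permutations = 1000L, n_repetitions = 1L,
                             seed = 1L) {
  if (!is.null(fixed_hyperparameters$K_ortho)) {
    config$K_ortho <- as.integer(fixed_hyperparameters$K_ortho)
  }
  if (!is.null(fixed_hyperparameters$lambda)) {
    config$lasso_lambda <- fixed_hyperparameters$lambda
  }
  groups <- dataset$individuals
  group_ids <- unique(unname(groups))
  group_class <- vapply(group_ids, function(g) {
    paste(sort(unique(unname(dataset$labels[names(groups)[groups == g]]))),
          collapse = "+")
  }, "")
  single_class <- !grepl("+", group_class, fixed = TRUE)
  pos <- default_positive_class(dataset, config)
  neg <- setdiff(dataset$classes, pos)

  set.seed(seed)
  null_acc <- rep(NA_real_, n_permutations)
  for (b in seq_len(n_permutations)) {
    labels <- dataset$labels
    if (all(single_class)) {
      perm <- sample(group_class)
      for (gi in seq_along(group_ids)) {
        smp <- names(groups)[groups == group_ids[gi]]
        labels[smp] <- perm[gi]
      }
    } else {
      flip <- sample(c(TRUE, FALSE), length(group_ids), replace = TRUE)
      swap <- stats::setNames(c(pos, neg), c(neg, pos))
      for (gi in seq_along(group_ids)) {
        if (flip[gi]) {
          smp <- names(groups)[groups == group_ids[gi]]
          labels[smp] <- swap[labels[smp]]
        }
      }
    }
    ds_p <- relabel_study(dataset, labels)
    acc <- tryCatch({
      correct <- 0L
      total <- 0L
      for (r in seq_len(n_repetitions)) {
        for (f in seq_len(splits$n_folds)) {
          test <- intersect(test_samples(splits, r, f), ds_p$samples)
          if (length(test) == 0L) next
          train <- setdiff(ds_p$samples, test)
          bundle <- fit_fold(ds_p, train, config)
          sc <- predict_fold(bundle, ds_p, test)
          pred <- ifelse(sc > bundle$threshold, pos, neg)
          correct <- correct + sum(pred == ds_p$labels[test])
          total <- total + length(test)
        }
      }
      correct / total
    }, error = function(e) NA_real_)
    null_acc[b] <- acc
  }
  structure(
    list(null_accuracies = null_acc, observed_accuracy = observed_accuracy,
         p_bound = perm_p_bound(null_acc, observed_accuracy,
                                n = n_permutations),
         n_permutations = as.integer(n_permutations)),
    class = "permutation_result"
  )
}

#' Leave-one-panel-out accuracy contribution
#'
#' For each aliquot `d`, the %increase is the cross-validated accuracy of
#' the fusion model on all panels minus the accuracy of the fusion model
#' on all panels except `d`, in percentage points — how much including
#' that panel improves the fused model.
#'
#' @param dataset A [study_dataset()] with at least two aliquots.
#' @param config A [pipeline_config()].
#' @param splits Stored splits, reused for every sub-model.
#' @param repetitions Subset of repetitions (default all).
#' @param cv_all Optional precomputed full-fusion [run_double_cv()]
#'   result (avoids refitting).
#'
#' @return Named numeric vector of %increase per aliquot (percentage
#'   points), with attribute `accuracy_all`.
#' @export
panel_increase <- function(dataset, config = pipeline_config(), splits,
                           repetitions = NULL, cv_all = NULL) {
  if (length(dataset$aliquots) < 2L) {
    cf_stop("cytofuse_config_error",
            "panel contribution needs at least two aliquots")
  }
  cv_all <- cv_all %||% run_double_cv(dataset, config, splits, repetitions)
  out <- stats::setNames(numeric(length(dataset$aliquots)), dataset$aliquots)
  for (a in dataset$aliquots) {
    ds_wo <- subset_study(dataset, aliquots = setdiff(dataset$aliquots, a))
    cv_wo <- run_double_cv(ds_wo, config, splits, repetitions)
    out[a] <- 100 * (cv_all$accuracy - cv_wo$accuracy)
  }
  attr(out, "accuracy_all") <- cv_all$accuracy
  out
}
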