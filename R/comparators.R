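#' Fit a batch self-organising map
#'
#' Batch SOM with Euclidean distance on a rectangular grid (default
#' 10 x 10 = 100 nodes). The codebook is initialised on the plane of the
#' first two principal components of the training cells (deterministic
#' given the data, so batch training needs no RNG), then refined over
#' `n_epochs` batch passes with a Gaussian neighbourhood whose radius
#' shrinks linearly. One pass touches every training cell, so `n_epochs`
#' passes correspond to `n_epochs` times the number of training cells in
#' sequential-update steps (10 is the conventional setting).
#'
#' @param cells Pooled training cell matrix (cells x markers) of one
#'   aliquot.
#' @param grid_dim Integer pair, nodes per grid dimension.
#' @param n_epochs Number of batch passes.
#' @param radius Start/end neighbourhood radius in grid units (default
#'   `c(3, 0.5)` for a 10 x 10 grid, scaled with the grid diagonal).
#'
#' @return Object of class `som_model` with `codebook` (nodes x markers),
#'   `grid` (node coordinates), `grid_dim`, `quantization_errors` (one
#'   mean squared distance per epoch).
#' @export
fit_som <- function(cells, grid_dim = c(10L, 10L), n_epochs = 10L,
                    radius = NULL) {
  cells <- as.matrix(cells)
  n_nodes <- prod(grid_dim)
  if (nrow(cells) < n_nodes) {
    cf_stop("cytofuse_config_error",
            "fewer training cells (%d) than SOM nodes (%d)",
            nrow(cells), n_nodes)
  }
  gx <- rep(seq_len(grid_dim[1L]), times = grid_dim[2L])
  gy <- rep(seq_len(grid_dim[2L]), each = grid_dim[1L])
  grid <- cbind(gx, gy)
  grid_d2 <- as.matrix(stats::dist(grid))^2

  # PCA-plane initialisation spanning +-2 sd of the first two components
  pc <- stats::prcomp(cells, center = TRUE, scale. = FALSE, rank. = 2L)
  span <- function(g, n) if (n == 1L) 0 else 2 * (2 * (g - 1) / (n - 1) - 1)
  codebook <- matrix(rep(pc$center, each = n_nodes), n_nodes, ncol(cells))
  codebook <- codebook +
    outer(span(gx, grid_dim[1L]) * pc$sdev[1L], pc$rotation[, 1L]) +
    outer(span(gy, grid_dim[2L]) * pc$sdev[2L],
          if (ncol(pc$rotation) > 1L) pc$rotation[, 2L] else 0 * pc$rotation[, 1L])

  diag_len <- sqrt(sum((grid_dim - 1L)^2))
  radius <- radius %||% c(diag_len / 4, 0.5)
  cell_sq <- rowSums(cells^2)
  qe <- numeric(n_epochs)
  for (e in seq_len(n_epochs)) {
    r_e <- max(radius[1L] + (radius[2L] - radius[1L]) * (e - 1L) /
                 max(n_epochs - 1L, 1L), 1e-6)
    # nearest node per cell (argmin over ||x||^2 - 2 x.c + ||c||^2)
    cross <- cells %*% t(codebook)
    d2 <- outer(cell_sq, rowSums(codebook^2), "+") - 2 * cross
    bmu <- max.col(-d2, ties.method = "first")
    qe[e] <- mean(d2[cbind(seq_len(nrow(cells)), bmu)])
    # batch update: neighbourhood-weighted mean of all cells
    counts <- tabulate(bmu, nbins = n_nodes)
    sums <- matrix(0, n_nodes, ncol(cells))
    rs <- rowsum(cells, group = bmu)
    sums[as.integer(rownames(rs)), ] <- rs
    h <- exp(-grid_d2 / (2 * r_e^2))
    denom <- as.vector(h %*% counts)
    num <- h %*% sums
    upd <- denom > 1e-12
    codebook[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  structure(
    list(codebook = codebook, grid = grid, grid_dim = as.integer(grid_dim),
         n_epochs = as.integer(n_epochs), radius = radius,
         quantization_errors = qe, distance = "euclidean",
         aliquot_id = NA_character_),
    class = "som_model"
  )
}

# nearest-codebook counts for one frame's cells; ties -> lowest node index
count_node_assignments <- function(cells, som) {
  cells <- as.matrix(cells)
  d2 <- outer(rowSums(cells^2), rowSums(som$codebook^2), "+") -
    2 * cells %*% t(som$codebook)
  bmu <- max.col(-d2, ties.method = "first")
  tabulate(bmu, nbins = nrow(som$codebook))
}

#' Count cells per SOM node for every sample
#'
#' Assigns every cell of every frame to its Euclidean-nearest codebook
#' vector (ties broken by the lowest node index) and tabulates counts,
#' concatenating the per-aliquot blocks into a samples x (nodes * M)
#' matrix. Row block `m` sums to the sample's cell count in aliquot `m`.
#'
#' @param dataset A [study_dataset()].
#' @param som_models Named list (aliquot -> [fit_som()] model).
#' @param samples Sample ids (default all).
#'
#' @return List with `counts` matrix and `block_index`.
#' @export
count_cells_per_node <- function(dataset, som_models, samples = NULL) {
  samples <- samples %||% dataset$samples
  aliquots <- names(som_models)
  blocks <- lapply(aliquots, function(a) {
    som <- som_models[[a]]
    t(vapply(samples, function(s) {
      count_node_assignments(get_frame(dataset, s, a)$events, som)
    }, numeric(nrow(som$codebook))))
  })
  counts <- do.call(cbind, blocks)
  rownames(counts) <- samples
  nn <- nrow(som_models[[1L]]$codebook)
  block_index <- lapply(seq_along(aliquots), function(m) {
    ((m - 1L) * nn + 1L):(m * nn)
  })
  names(block_index) <- aliquots
  list(counts = counts, block_index = block_index)
}

#' Linear support vector machine
#'
#' Thin wrapper around `e1071::svm` with a linear kernel and box
#' constraint (cost) 1, exposing the per-feature weight vector for node
#' colouring. Decision scores are oriented so that the positive class
#' (second factor level) scores higher.
#'
#' @param features Feature matrix (samples x features).
#' @param y Two-level factor (second level = positive class).
#' @param box_constraint SVM cost parameter.
#' @return Object of class `linear_svm` with `fit`, `weights`, `sign`.
#' @export
fit_linear_svm <- function(features, y, box_constraint = 1) {
  y <- as.factor(y)
  if (nlevels(y) != 2L) {
    cf_stop("cytofuse_config_error", "SVM needs exactly two classes")
  }
  fit <- e1071::svm(x = features, y = y, kernel = "linear",
                    cost = box_constraint, scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  dv <- attr(stats::predict(fit, features, decision.values = TRUE),
             "decision.values")[, 1L]
  sgn <- if (mean(dv[y == levels(y)[2L]]) >= mean(dv[y == levels(y)[1L]])) 1 else -1
  structure(list(fit = fit, weights = sgn * w, sign = sgn, levels = levels(y)),
            class = "linear_svm")
}

predict_svm_scores <- function(model, newdata) {
  dv <- attr(stats::predict(model$fit, newdata, decision.values = TRUE),
             "decision.values")[, 1L]
  model$sign * dv
}

#' Lasso-regularised logistic regression
#'
#' `glmnet` logistic lasso with lambda selected at the minimum mean
#' binomial deviance in a stratified 10-fold inner cross-validation
#' (deterministic fold ids; deviance ties resolve to the larger, sparser
#' lambda). A fixed `lambda` skips the inner loop, as in the permutation
#' test.
#'
#' @param features Feature matrix (samples x features).
#' @param y Two-level factor (second level = positive class).
#' @param n_inner_folds Inner folds for the lambda search.
#' @param lambda Optional fixed lambda.
#' @return Object of class `lasso_logistic` with `fit`, `lambda`,
#'   `coefficients` (sparse vector incl. intercept), `cv` (the
#'   `cv.glmnet` object or `NULL`).
#' @export
fit_lasso_logistic <- function(features, y, n_inner_folds = 10L,
                               lambda = NULL) {
  y <- as.factor(y)
  if (nlevels(y) != 2L) {
    cf_stop("cytofuse_config_error", "lasso needs exactly two classes")
  }
  if (is.null(lambda)) {
    nf <- min(n_inner_folds, length(y))
    foldid <- deterministic_foldid(y, nf)
    cv <- glmnet::cv.glmnet(x = as.matrix(features), y = y,
                            family = "binomial", type.measure = "deviance",
                            foldid = foldid)
    lambda <- cv$lambda.min
  } else {
    cv <- NULL
  }
  fit <- glmnet::glmnet(x = as.matrix(features), y = y, family = "binomial",
                        lambda = lambda)
  structure(
    list(fit = fit, lambda = lambda,
         coefficients = as.vector(stats::coef(fit)), cv = cv,
         levels = levels(y)),
    class = "lasso_logistic"
  )
}

predict_lasso_scores <- function(model, newdata) {
  as.vector(stats::predict(model$fit, newx = as.matrix(newdata),
                           s = model$lambda, type = "link"))
}

#' OPLS-DA on SOM node counts
#'
#' Applies the same OPLS-DA top model to the node-count featurization:
#' node counts are normalised to unit sum per aliquot block, centred by
#' the training means, and passed to [fit_oplsda()].
#'
#' @param counts Node-count matrix (samples x nodes*M) with `block_index`
#'   as produced by [count_cells_per_node()].
#' @param block_index List of per-aliquot column indices.
#' @param y Class labels.
#' @param K_ortho Orthogonal components (default 0).
#' @return A [fit_oplsda()] model with attribute `column_means`.
#' @export
fit_oplsda_on_nodes <- function(counts, block_index, y, K_ortho = 0L) {
  X <- counts
  for (cols in block_index) {
    X[, cols] <- X[, cols] / rowSums(X[, cols, drop = FALSE])
  }
  mu <- colMeans(X)
  model <- fit_oplsda(sweep(X, 2L, mu, "-"), y, K_ortho = K_ortho)
  attr(model, "column_means") <- mu
  model
}

#' Minimum spanning tree over SOM codebook vectors
#'
#' Builds the Euclidean MST of the codebook (99 edges for 100 nodes) and
#' a deterministic force-directed (Kamada-Kawai) layout for plotting.
#'
#' @param som A [fit_som()] model.
#' @return Object of class `som_mst` with `edges` (data frame `from`,
#'   `to`, `weight`), `layout` (nodes x 2) and the `igraph` object.
#' @export
build_mst <- function(som) {
  stopifnot(inherits(som, "som_model"))
  d <- as.matrix(stats::dist(som$codebook))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(tree, names = FALSE)
  edges <- data.frame(from = as.integer(el[, 1L]), to = as.integer(el[, 2L]),
                      weight = igraph::E(tree)$weight)
  # seeding from the grid keeps the layout deterministic without touching
  # the global RNG state
  layout <- igraph::layout_with_kk(tree, coords = som$grid)
  structure(list(edges = edges, layout = layout, graph = tree,
                 n_nodes = nrow(som$codebook)),
            class = "som_mst")
}
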