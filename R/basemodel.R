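#' Fit a per-aliquot PCA base model
#'
#' Pools the cells of the training-fold frames of one aliquot (row
#' concatenation) and fits a centred, unscaled PCA. The first `K_base`
#' components define the score space in which per-sample histograms are
#' computed. Component signs are fixed deterministically (the
#' largest-magnitude loading element of each component is made positive)
#' so maps are reproducible across runs.
#'
#' @param training_frames List of scaled [aliquot_frame()]s of one
#'   aliquot (training fold only).
#' @param K_base Number of components (default 2; the downstream
#'   histogram and refolding machinery assume 2).
#'
#' @return Object of class `pca_base_model` with `aliquot_id`, `K_base`,
#'   `loadings` (markers x K_base, orthonormal), `column_means` and
#'   `explained_variance` (fraction per kept component).
#' @export
fit_base_model <- function(training_frames, K_base = 2L) {
  stopifnot(length(training_frames) >= 1L)
  mk <- training_frames[[1L]]$marker_names
  alq <- training_frames[[1L]]$aliquot_id
  for (fr in training_frames) {
    if (!identical(fr$marker_names, mk)) {
      cf_stop("cytofuse_marker_mismatch", "frames disagree on marker names")
    }
  }
  pooled <- do.call(rbind, lapply(training_frames, `[[`, "events"))
  if (nrow(pooled) <= K_base) {
    cf_stop("cytofuse_degenerate_data", "need more pooled cells than components")
  }
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < K_base || pc$sdev[K_base] < 1e-12 * pc$sdev[1L]) {
    cf_stop("cytofuse_degenerate_data",
            "training data rank below K_base = %d for aliquot %s", K_base, alq)
  }
  loadings <- pc$rotation[, seq_len(K_base), drop = FALSE]
  for (k in seq_len(K_base)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
  }
  structure(
    list(aliquot_id = alq, K_base = as.integer(K_base),
         loadings = loadings,
         column_means = stats::setNames(pc$center, mk),
         explained_variance = pc$sdev[seq_len(K_base)]^2 / sum(pc$sdev^2),
         marker_names = mk),
    class = "pca_base_model"
  )
}

#' Project cells into a base model's score space
#'
#' @param frame An [aliquot_frame()] (or plain cells x markers matrix with
#'   matching columns).
#' @param model A [fit_base_model()] result.
#'
#' @return Cells x K_base score matrix `(events - column_means) %*% loadings`.
#' @export
project_cells <- function(frame, model) {
  stopifnot(inherits(model, "pca_base_model"))
  ev <- if (inherits(frame, "aliquot_frame")) {
    if (!identical(frame$marker_names, model$marker_names)) {
      cf_stop("cytofuse_marker_mismatch", "frame markers do not match base model")
    }
    frame$events
  } else {
    as.matrix(frame)
  }
  if (ncol(ev) != length(model$column_means)) {
    cf_stop("cytofuse_marker_mismatch", "wrong number of markers for base model")
  }
  sweep(ev, 2L, model$column_means, "-") %*% model$loadings
}

# Mass-preserving 1D smoothing operator with reflecting boundaries:
# kernel weights falling outside the grid are folded back, so every
# column sums to exactly 1 and convolution conserves total mass.
smoothing_operator <- function(F, smoothing_sd) {
  if (smoothing_sd <= 0) return(diag(F))
  R <- ceiling(4 * smoothing_sd)
  offs <- -R:R
  w <- stats::dnorm(offs / smoothing_sd)
  w <- w / sum(w)
  S <- matrix(0, F, F)
  for (j in seq_len(F)) {
    tgt <- j + offs
    # reflect about the edges (1 and F) until inside
    while (any(tgt < 1L | tgt > F)) {
      tgt <- ifelse(tgt < 1L, 2L - tgt, tgt)
      tgt <- ifelse(tgt > F, 2L * F - tgt, tgt)
    }
    for (i in seq_along(tgt)) S[tgt[i], j] <- S[tgt[i], j] + w[i]
  }
  S
}

#' Build a histogram grid from training scores
#'
#' Defines per-dimension equal-width bin edges spanning the training
#' scores plus a margin, and precomputes the Gaussian smoothing operator.
#' The grid is fitted on training-fold scores only and reused unchanged
#' for held-out samples (out-of-range cells are clipped into edge bins).
#'
#' @param training_scores Pooled training score matrix (cells x 2).
#' @param F Bins per dimension (default 100; with densely sampled data
#'   500 is the method's default).
#' @param margin_fraction Margin added on each side, as a fraction of the
#'   training score range (default 0.05).
#' @param smoothing_sd Gaussian kernel width in bin units (default 2;
#'   truncated at 4 sd, reflecting boundaries). 0 disables smoothing.
#'
#' @return Object of class `histogram_grid` with `F`, `edges` (list of two
#'   length-`F + 1` increasing vectors), `smoothing_sd` and the operator.
#' @export
make_grid <- function(training_scores, F = 100L, margin_fraction = 0.05,
                      smoothing_sd = 2) {
  stopifnot(ncol(training_scores) == 2L)
  F <- as.integer(F)
  if (F < 2L) cf_stop("cytofuse_config_error", "F must be >= 2")
  edges <- lapply(1:2, function(d) {
    r <- range(training_scores[, d])
    if (diff(r) <= 0) {
      cf_stop("cytofuse_degenerate_data",
              "zero score range in histogram dimension %d", d)
    }
    m <- margin_fraction * diff(r)
    seq(r[1L] - m, r[2L] + m, length.out = F + 1L)
  })
  structure(
    list(F = F, edges = edges, smoothing_sd = smoothing_sd,
         smoother = smoothing_operator(F, smoothing_sd)),
    class = "histogram_grid"
  )
}

#' Compute a sample's smoothed unit-sum histogram
#'
#' Bins a sample's scores on the grid (cells outside the grid are clipped
#' into the edge bins so per-sample mass is conserved), smooths with the
#' grid's truncated Gaussian kernel under reflecting boundaries, and
#' normalises to unit sum.
#'
#' @param scores Cells x 2 score matrix from [project_cells()].
#' @param grid A [make_grid()] result.
#' @param sample_id,aliquot_id Identifiers attached to the result.
#'
#' @return Object of class `sample_histogram` with `values` (F x F,
#'   non-negative, summing to 1), `sample_id`, `aliquot_id`.
#' @export
histogram_sample <- function(scores, grid, sample_id = NA_character_,
                             aliquot_id = NA_character_) {
  stopifnot(inherits(grid, "histogram_grid"))
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) {
    cf_stop("cytofuse_zero_cell", "cannot histogram a sample with no cells")
  }
  F <- grid$F
  bin <- function(x, edges) {
    i <- findInterval(x, edges, rightmost.closed = TRUE)
    pmin(pmax(i, 1L), F)
  }
  i1 <- bin(scores[, 1L], grid$edges[[1L]])
  i2 <- bin(scores[, 2L], grid$edges[[2L]])
  counts <- matrix(tabulate(i1 + (i2 - 1L) * F, nbins = F * F), F, F)
  if (grid$smoothing_sd > 0) {
    counts <- grid$smoother %*% counts %*% t(grid$smoother)
  }
  vals <- counts / sum(counts)
  structure(
    list(values = vals, sample_id = as.character(sample_id),
         aliquot_id = as.character(aliquot_id), F = F),
    class = "sample_histogram"
  )
}

#' Fuse per-aliquot histograms into one matrix
#'
#' Unfolds each sample's F x F histogram row-major to a length-F^2 vector
#' and concatenates the blocks of all aliquots, giving the
#' samples x (F^2 * M) fused matrix H. Every sample must have exactly one
#' histogram per aliquot. Because each block row sums to 1 before
#' centring, every panel enters the fusion with equal a-priori weight.
#'
#' @param histograms List of [histogram_sample()] objects.
#' @param sample_ids Row order (default: order of first appearance).
#' @param aliquot_ids Block order (default: order of first appearance).
#'
#' @return Object of class `fused_matrix` with `H`, `row_ids`,
#'   `block_index` (aliquot -> column indices), `F`, `aliquots`.
#' @export
fuse_histograms <- function(histograms, sample_ids = NULL, aliquot_ids = NULL) {
  hs <- vapply(histograms, `[[`, "", "sample_id")
  ha <- vapply(histograms, `[[`, "", "aliquot_id")
  sample_ids <- sample_ids %||% unique(hs)
  aliquot_ids <- aliquot_ids %||% unique(ha)
  F <- unique(vapply(histograms, `[[`, 0L, "F"))
  if (length(F) != 1L) {
    cf_stop("cytofuse_config_error", "histograms disagree on F")
  }
  M <- length(aliquot_ids)
  idx <- stats::setNames(seq_along(histograms), paste(hs, ha, sep = "\r"))
  H <- matrix(NA_real_, length(sample_ids), F * F * M,
              dimnames = list(sample_ids, NULL))
  block_index <- list()
  for (m in seq_len(M)) {
    cols <- ((m - 1L) * F * F + 1L):(m * F * F)
    block_index[[aliquot_ids[m]]] <- cols
    for (i in seq_along(sample_ids)) {
      key <- paste(sample_ids[i], aliquot_ids[m], sep = "\r")
      j <- idx[key]
      if (is.na(j)) {
        cf_stop("cytofuse_incomplete_design",
                "missing histogram for sample %s, aliquot %s",
                sample_ids[i], aliquot_ids[m])
      }
      H[i, cols] <- unfold_histogram(histograms[[j]]$values)
    }
  }
  structure(
    list(H = H, row_ids = sample_ids, block_index = block_index,
         F = F, aliquots = aliquot_ids),
    class = "fused_matrix"
  )
}

#' Export a fused matrix as CSV with a JSON sidecar
#'
#' Writes the dense matrix `H` (rows named by sample) to CSV and the
#' structural metadata — aliquot block index, `F`, and optionally the
#' grid edges — to a JSON sidecar `<path>.json`.
#'
#' @param fused A [fuse_histograms()] result.
#' @param path CSV output path.
#' @param grids Optional named list of [make_grid()] objects whose edges
#'   are recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_fused_csv <- function(fused, path, grids = NULL) {
  stopifnot(inherits(fused, "fused_matrix"))
  utils::write.csv(as.data.frame(fused$H), path, row.names = TRUE)
  sidecar <- list(F = fused$F, aliquots = fused$aliquots,
                  block_index = fused$block_index,
                  row_ids = fused$row_ids,
                  grid_edges = if (!is.null(grids)) lapply(grids, `[[`, "edges"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Mean-centre a fused matrix with training means
#'
#' Column means are computed on the training rows only and subtracted
#' from all rows, so held-out rows are centred with training statistics.
#'
#' @param fused A [fuse_histograms()] result (or plain matrix with row
#'   names).
#' @param training_row_ids Row ids forming the training set.
#'
#' @return List with `H_centred` and `column_means`.
#' @export
centre_fused <- function(fused, training_row_ids) {
  H <- if (inherits(fused, "fused_matrix")) fused$H else as.matrix(fused)
  if (!all(training_row_ids %in% rownames(H))) {
    cf_stop("cytofuse_config_error", "unknown training row id")
  }
  mu <- colMeans(H[training_row_ids, , drop = FALSE])
  list(H_centred = sweep(H, 2L, mu, "-"), column_means = mu)
}
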