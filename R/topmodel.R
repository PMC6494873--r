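#' Encode binary class labels as a dummy vector
#'
#' @param labels Character/factor class labels.
#' @param positive_class Label coded +1 (default: `"case"` if present,
#'   otherwise the last of the sorted unique labels).
#' @return Named numeric vector in `{-1, +1}` with attribute `coding`.
#' @keywords internal
code_labels <- function(labels, positive_class = NULL) {
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L) {
    cf_stop("cytofuse_config_error",
            "need exactly two classes, got: %s", paste(classes, collapse = ", "))
  }
  positive_class <- positive_class %||%
    (if ("case" %in% classes) "case" else classes[2L])
  if (!positive_class %in% classes) {
    cf_stop("cytofuse_config_error", "positive class '%s' not in labels",
            positive_class)
  }
  negative_class <- setdiff(classes, positive_class)
  y <- ifelse(as.character(labels) == positive_class, 1, -1)
  names(y) <- names(labels)
  attr(y, "coding") <- c(negative = negative_class, positive = positive_class)
  y
}

#' Fit an OPLS-DA model
#'
#' Orthogonal PLS discriminant analysis for a binary response with one
#' predictive latent variable. The predictive weight is the (normalised)
#' covariance direction `w = X'y`; `K_ortho` y-orthogonal components are
#' then extracted iteratively (orthogonal weight = loading minus its
#' projection on `w`, normalised) and deflated from `X`, after which the
#' predictive component is fitted on the deflated matrix. With
#' `K_ortho = 0` the model is exactly one-component PLS-DA.
#'
#' @param X Training matrix, already mean-centred with training column
#'   means (rows = samples, e.g. the centred fused matrix H).
#' @param y Class labels (two classes) or a `{-1, +1}` vector from
#'   `code_labels()`.
#' @param K_ortho Number of orthogonal components (>= 0).
#' @param positive_class See `code_labels()`.
#'
#' @return Object of class `oplsda_model` with unit-norm predictive
#'   weights `w_top`, orthogonal `ortho_weights`/`ortho_loadings`,
#'   regression scalar `b`, `intercept`, classification `threshold`
#'   (midpoint of the training class mean scores), `fitted` training
#'   scores and bookkeeping needed for VIP filtering.
#' @export
fit_oplsda <- function(X, y, K_ortho = 0L, positive_class = NULL) {
  X <- as.matrix(X)
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    coding <- attr(y, "coding") %||% c(negative = "-1", positive = "1")
  } else {
    y <- code_labels(y, positive_class)
    coding <- attr(y, "coding")
  }
  if (length(unique(y)) < 2L) {
    cf_stop("cytofuse_config_error", "training labels contain a single class")
  }
  if (nrow(X) != length(y)) {
    cf_stop("cytofuse_config_error", "nrow(X) != length(y)")
  }
  if (K_ortho < 0L) cf_stop("cytofuse_config_error", "K_ortho must be >= 0")

  yc <- y - mean(y)
  w <- as.vector(crossprod(X, yc))
  nw <- l2norm(w)
  if (nw < 1e-300) cf_stop("cytofuse_degenerate_data", "X'y is zero")
  w <- w / nw

  p_dim <- ncol(X)
  Wo <- matrix(0, p_dim, 0L)
  Po <- matrix(0, p_dim, 0L)
  Xd <- X
  for (k in seq_len(K_ortho)) {
    t_pred <- as.vector(Xd %*% w)
    p_load <- as.vector(crossprod(Xd, t_pred)) / sum(t_pred^2)
    wo <- p_load - sum(w * p_load) * w
    nwo <- l2norm(wo)
    if (nwo < 1e-10 * max(l2norm(p_load), 1e-300)) {
      cf_stop("cytofuse_rank_error",
              "K_ortho = %d exceeds the orthogonal rank of the data", K_ortho)
    }
    wo <- wo / nwo
    to <- as.vector(Xd %*% wo)
    po <- as.vector(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo <- cbind(Wo, wo)
    Po <- cbind(Po, po)
  }

  t_pred <- as.vector(Xd %*% w)
  b <- sum(yc * t_pred) / sum(t_pred^2)
  intercept <- mean(y)
  fitted <- t_pred * b + intercept
  thr <- (mean(fitted[y > 0]) + mean(fitted[y < 0])) / 2

  structure(
    list(w_top = w, K_ortho = as.integer(K_ortho),
         ortho_weights = Wo, ortho_loadings = Po,
         b = b, intercept = intercept, threshold = thr,
         fitted = stats::setNames(fitted, names(y)),
         scores = t_pred, ortho_scores = if (K_ortho > 0) X %*% Wo else NULL,
         y = y, y_centred = yc, y_coding = coding,
         X = X, Xd = Xd, vip_filtered = FALSE),
    class = "oplsda_model"
  )
}

#' Predict OPLS-DA scores for new rows
#'
#' Sequentially removes each stored orthogonal component from the new
#' rows, then computes the prediction score
#' `y_hat = (row %*% w_top) * b + intercept`.
#'
#' @param object A fitted [fit_oplsda()] model.
#' @param newdata Rows centred with the *training* column means.
#' @param ... Unused.
#' @return Numeric vector of prediction scores.
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  X <- matrix(as.numeric(newdata), ncol = length(object$w_top))
  if (ncol(X) != length(object$w_top)) {
    cf_stop("cytofuse_config_error", "newdata has wrong number of columns")
  }
  for (k in seq_len(object$K_ortho)) {
    to <- as.vector(X %*% object$ortho_weights[, k])
    X <- X - tcrossprod(to, object$ortho_loadings[, k])
  }
  as.vector(X %*% object$w_top) * object$b + object$intercept
}

#' Select the number of orthogonal components by leave-one-out CV
#'
#' For every left-out training sample the model path `K = 0..K_max` is
#' fitted on the remaining samples (re-centred without the held-out row)
#' and the held-out prediction is classified with that model's midpoint
#' threshold. The smallest `K` minimising the leave-one-out
#' misclassification count is returned.
#'
#' @param H_train Uncentred training rows of the fused matrix.
#' @param y Training labels.
#' @param K_max Largest number of orthogonal components tried (default 5).
#' @param positive_class See `code_labels()`.
#'
#' @return Integer `K` in `0..K_max`.
#' @export
select_K_ortho <- function(H_train, y, K_max = 5L, positive_class = NULL) {
  X <- as.matrix(H_train)
  y <- if (is.numeric(y) && all(y %in% c(-1, 1))) y else code_labels(y, positive_class)
  n <- nrow(X)
  K_max <- as.integer(K_max)
  # The whole leave-one-out path runs in row-span (Gram) coordinates:
  # every OPLS vector is a combination of training rows, so one O(n^2 p)
  # Gram computation replaces O(n) refits on the n x p matrix. The primal
  # fit in fit_oplsda() is the reference; a unit test pins the two paths
  # to each other.
  G0 <- tcrossprod(X)
  errs <- matrix(NA, n, K_max + 1L)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) next
    Gs <- G0[-i, -i, drop = FALSE]
    rowm <- rowMeans(Gs)
    mm <- mean(Gs)
    G <- Gs - outer(rowm, rep(1, n - 1L)) - outer(rep(1, n - 1L), rowm) + mm
    gx <- G0[i, -i] - mean(G0[i, -i]) - rowm + mm
    yc <- ytr - mean(ytr)
    c_w <- yc / sqrt(sum(yc * (G %*% yc)))
    Gw <- as.vector(G %*% c_w)
    M <- diag(n - 1L)           # accumulated deflation: X_k = M %*% X_c
    d <- numeric(n - 1L)        # held-out row deflation coefficients
    for (k in 0:K_max) {
      if (k > 0L) {
        t_pred <- as.vector(M %*% Gw)
        c_p <- as.vector(crossprod(M, t_pred)) / sum(t_pred^2)
        c_wo <- c_p - sum(c_w * (G %*% c_p)) * c_w
        n2 <- sum(c_wo * (G %*% c_wo))
        if (n2 < 1e-20 * max(sum(c_p * (G %*% c_p)), 1e-300)) {
          errs[i, (k + 1L):(K_max + 1L)] <- errs[i, k]
          break
        }
        c_wo <- c_wo / sqrt(n2)
        to <- as.vector(M %*% (G %*% c_wo))
        c_po <- as.vector(crossprod(M, to)) / sum(to^2)
        xd_wo <- sum(gx * c_wo) - sum(d * (G %*% c_wo))
        d <- d + xd_wo * c_po
        M <- M - tcrossprod(to, c_po)
      }
      t_tr <- as.vector(M %*% Gw)
      b <- sum(yc * t_tr) / sum(t_tr^2)
      fit_tr <- t_tr * b + mean(ytr)
      thr <- (mean(fit_tr[ytr > 0]) + mean(fit_tr[ytr < 0])) / 2
      yhat <- (sum(gx * c_w) - sum(d * (G %*% c_w))) * b + mean(ytr)
      errs[i, k + 1L] <- as.integer((yhat > thr) != (y[i] > 0))
    }
  }
  total <- colSums(errs, na.rm = TRUE)
  as.integer(which.min(total) - 1L)  # which.min takes the first (smallest K) tie
}

#' Variable importance in projection
#'
#' For the single predictive component and unit-norm weights,
#' `VIP_f = sqrt(F_star * w_top_f^2)` where `F_star` is the total number
#' of fused variables (`F^2 * M`). Consequently `sum(VIP^2) = F_star`,
#' and a weight carrying exactly its "fair share" of the direction has
#' VIP 1 — the conventional selection threshold.
#'
#' @param model A fitted [fit_oplsda()] model.
#' @param threshold Selection threshold for the mask (default 1).
#'
#' @return Object of class `vip_result` with `vip`, `mask`
#'   (`vip >= threshold`), `F_star` and `threshold`.
#' @export
compute_vip <- function(model, threshold = 1) {
  stopifnot(inherits(model, "oplsda_model"))
  F_star <- length(model$w_top)
  vip <- sqrt(F_star * model$w_top^2)
  structure(
    list(vip = vip, mask = vip >= threshold, F_star = F_star,
         threshold = threshold),
    class = "vip_result"
  )
}

#' Sparsify an OPLS-DA model by its VIP
#'
#' Weights with VIP below the threshold are set to zero; the remaining
#' weight vector is re-normalised to unit norm and the regression scalar
#' `b` (and midpoint threshold) re-estimated on the training scores. The
#' orthogonal components are not refitted unless `refit = TRUE`, in
#' which case the whole OPLS-DA is refitted with the sub-threshold
#' columns of the training matrix zeroed out.
#'
#' @param model A fitted [fit_oplsda()] model.
#' @param vip Optional [compute_vip()] result (computed if missing).
#' @param threshold VIP threshold (default 1).
#' @param refit Refit orthogonal components on the filtered variables.
#'
#' @return The filtered `oplsda_model` (with `vip_filtered = TRUE`). If
#'   no variable survives, a warning is issued and the unfiltered model
#'   returned.
#' @export
apply_vip_filter <- function(model, vip = NULL, threshold = 1, refit = FALSE) {
  stopifnot(inherits(model, "oplsda_model"))
  vip <- vip %||% compute_vip(model, threshold)
  mask <- vip$vip >= threshold
  if (!any(mask)) {
    warning("VIP filter removed every variable; returning unfiltered model")
    return(model)
  }
  if (all(mask)) {
    model$vip_filtered <- TRUE
    return(model)
  }
  if (refit) {
    Xr <- model$X
    Xr[, !mask] <- 0
    out <- fit_oplsda(Xr, model$y, K_ortho = model$K_ortho)
    out$vip_filtered <- TRUE
    return(out)
  }
  w_f <- model$w_top
  w_f[!mask] <- 0
  w_f <- w_f / l2norm(w_f)
  t_f <- as.vector(model$Xd %*% w_f)
  b <- sum(model$y_centred * t_f) / sum(t_f^2)
  fitted <- t_f * b + model$intercept
  model$w_top <- w_f
  model$b <- b
  model$scores <- t_f
  model$fitted <- stats::setNames(fitted, names(model$y))
  model$threshold <- (mean(fitted[model$y > 0]) + mean(fitted[model$y < 0])) / 2
  model$vip_filtered <- TRUE
  model
}

#' Classify prediction scores against a threshold
#'
#' A sample is assigned the positive class iff its score exceeds the
#' threshold (set at fit time to the midpoint of the training class mean
#' scores).
#'
#' @param y_hat Numeric prediction scores.
#' @param model A fitted [fit_oplsda()] model, or a numeric threshold.
#' @return Character vector of class labels.
#' @export
classify_scores <- function(y_hat, model) {
  if (inherits(model, "oplsda_model")) {
    thr <- model$threshold
    coding <- model$y_coding
  } else {
    thr <- as.numeric(model)
    coding <- c(negative = "negative", positive = "positive")
  }
  ifelse(y_hat > thr, coding[["positive"]], coding[["negative"]])
}

#' Refold a fused weight vector into per-aliquot maps
#'
#' Inverts the row-major unfolding used by [fuse_histograms()]: block `m`
#' of the length-`F^2 * M` weight vector becomes slice `m` of an
#' `F x F x M` array — one leukocyte map per aliquot.
#'
#' @param w_top Fused weight vector (length `F^2 * M`).
#' @param F Bins per histogram dimension.
#' @param M Number of aliquots.
#' @param aliquot_ids Optional slice names.
#'
#' @return Object of class `weight_map`: an `F x F x M` array.
#' @export
refold_weights <- function(w_top, F, M, aliquot_ids = NULL) {
  if (length(w_top) != F * F * M) {
    cf_stop("cytofuse_config_error",
            "length(w_top) = %d but F^2 * M = %d", length(w_top), F * F * M)
  }
  W <- array(NA_real_, dim = c(F, F, M))
  for (m in seq_len(M)) {
    block <- w_top[((m - 1L) * F * F + 1L):(m * F * F)]
    W[, , m] <- refold_histogram(block, F)
  }
  if (!is.null(aliquot_ids)) dimnames(W) <- list(NULL, NULL, aliquot_ids)
  class(W) <- c("weight_map", class(W))
  W
}
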