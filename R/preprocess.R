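#' Arcsinh-transform an aliquot frame
#'
#' Applies the hyperbolic inverse sine `x -> asinh(x / cofactor)` to every
#' event value. The transform is odd and strictly monotone, compresses
#' high intensities roughly logarithmically and is near-linear around
#' zero, which keeps cells with negative (background-subtracted)
#' intensities usable.
#'
#' @param frame An [aliquot_frame()] in `raw` state.
#' @param cofactor Positive scale parameter (default 150, the usual choice
#'   for conventional fluorescence cytometry).
#'
#' @return The transformed frame (`transform_state = "arcsinh"`).
#' @export
arcsinh_transform <- function(frame, cofactor = 150) {
  stopifnot(inherits(frame, "aliquot_frame"))
  if (!is.numeric(cofactor) || cofactor <= 0) {
    cf_stop("cytofuse_config_error", "cofactor must be > 0")
  }
  if (frame$transform_state != "raw") {
    cf_stop("cytofuse_state_error",
            "arcsinh_transform expects a raw frame (got %s)",
            frame$transform_state)
  }
  frame$events <- asinh(frame$events / cofactor)
  frame$transform_state <- "arcsinh"
  frame
}

#' Fit a cohort reference scaler
#'
#' Computes per-marker medians and standard deviations over the pooled
#' cells of the reference-class individuals in the training fold. The
#' statistics are later applied unchanged to held-out samples, so no
#' test-set information leaks into the scaling.
#'
#' @param training_frames List of arcsinh-transformed [aliquot_frame()]s
#'   of one aliquot, reference-class training individuals only.
#'
#' @return List with `median`, `sd` (named per marker) and `marker_names`.
#' @export
fit_cohort_scaler <- function(training_frames) {
  if (length(training_frames) == 0L) {
    cf_stop("cytofuse_config_error", "no reference-class training frames")
  }
  mk <- training_frames[[1L]]$marker_names
  for (fr in training_frames) {
    stopifnot(inherits(fr, "aliquot_frame"))
    if (fr$transform_state != "arcsinh") {
      cf_stop("cytofuse_state_error", "cohort scaler expects arcsinh frames")
    }
    if (!identical(fr$marker_names, mk)) {
      cf_stop("cytofuse_marker_mismatch", "frames disagree on marker names")
    }
  }
  pooled <- do.call(rbind, lapply(training_frames, `[[`, "events"))
  med <- apply(pooled, 2L, stats::median)
  sds <- apply(pooled, 2L, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    cf_stop("cytofuse_degenerate_marker",
            "zero reference standard deviation for marker(s): %s",
            paste(mk[zero], collapse = ", "))
  }
  list(median = stats::setNames(med, mk), sd = stats::setNames(sds, mk),
       marker_names = mk)
}

#' Apply a fitted scaler to a frame
#'
#' @param frame An arcsinh-transformed [aliquot_frame()].
#' @param scaler A scaler from [fit_cohort_scaler()] (or any list with
#'   `median` and `sd` named per marker).
#'
#' @return The frame with `(x - median) / sd` applied per marker and
#'   `transform_state = "scaled"`.
#' @export
apply_scaler <- function(frame, scaler) {
  stopifnot(inherits(frame, "aliquot_frame"))
  if (frame$transform_state != "arcsinh") {
    cf_stop("cytofuse_state_error", "apply_scaler expects an arcsinh frame")
  }
  if (!identical(frame$marker_names, scaler$marker_names)) {
    cf_stop("cytofuse_marker_mismatch",
            "frame markers do not match the scaler")
  }
  frame$events <- sweep(sweep(frame$events, 2L, scaler$median, "-"),
                        2L, scaler$sd, "/")
  frame$transform_state <- "scaled"
  frame
}

#' Scale paired measurements of one individual
#'
#' For paired designs (e.g. pre/post challenge of the same individual),
#' the per-marker median and standard deviation are computed on the
#' pooled cells of that individual's paired measurements, and both frames
#' are scaled with those shared statistics. Scaling is strictly local to
#' the individual.
#'
#' @param frames_of_one_individual List of >= 2 arcsinh-transformed
#'   [aliquot_frame()]s of the same individual and aliquot (different
#'   samples/conditions).
#'
#' @return List of scaled frames in the input order.
#' @export
paired_individual_scaler <- function(frames_of_one_individual) {
  frames <- frames_of_one_individual
  if (length(frames) < 2L ||
      length(unique(vapply(frames, `[[`, "", "sample_id"))) < 2L) {
    cf_stop("cytofuse_pairing_error",
            "paired scaling needs >= 2 samples of the same individual")
  }
  ind <- unique(vapply(frames, `[[`, "", "individual_id"))
  alq <- unique(vapply(frames, `[[`, "", "aliquot_id"))
  if (length(ind) != 1L || length(alq) != 1L) {
    cf_stop("cytofuse_pairing_error",
            "paired scaling expects one individual and one aliquot")
  }
  mk <- frames[[1L]]$marker_names
  for (fr in frames) {
    if (fr$transform_state != "arcsinh") {
      cf_stop("cytofuse_state_error", "paired scaler expects arcsinh frames")
    }
    if (!identical(fr$marker_names, mk)) {
      cf_stop("cytofuse_marker_mismatch", "frames disagree on marker names")
    }
  }
  pooled <- do.call(rbind, lapply(frames, `[[`, "events"))
  med <- apply(pooled, 2L, stats::median)
  sds <- apply(pooled, 2L, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    cf_stop("cytofuse_degenerate_marker",
            "zero pooled standard deviation for marker(s): %s",
            paste(mk[zero], collapse = ", "))
  }
  scaler <- list(median = stats::setNames(med, mk),
                 sd = stats::setNames(sds, mk), marker_names = mk)
  lapply(frames, apply_scaler, scaler = scaler)
}

#' Parse a gate predicate
#'
#' A gate is a boolean combination of per-marker threshold comparisons,
#' written as an R expression over marker names, e.g.
#' `"CD3 < 1.5 & CD19 > 2"`. Only comparisons (`<`, `>`, `<=`, `>=`),
#' logical operators (`&`, `|`, `!`), parentheses, negation, marker names
#' and numeric literals are allowed.
#'
#' @param text Predicate string.
#' @return An object of class `gate_expression`.
#' @export
gate_expression <- function(text) {
  expr <- tryCatch(str2lang(text), error = function(e) {
    cf_stop("cytofuse_gate_error", "cannot parse gate '%s'", text)
  })
  allowed_ops <- c("<", ">", "<=", ">=", "&", "|", "!", "(", "-")
  markers <- character()
  walk <- function(e) {
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (!op %in% allowed_ops) {
        cf_stop("cytofuse_gate_error", "operator '%s' not allowed in gates", op)
      }
      for (i in seq_along(e)[-1L]) walk(e[[i]])
    } else if (is.name(e)) {
      markers <<- c(markers, as.character(e))
    } else if (!is.numeric(e)) {
      cf_stop("cytofuse_gate_error", "gate literals must be numeric")
    }
  }
  walk(expr)
  structure(list(expr = expr, text = text, markers = unique(markers)),
            class = "gate_expression")
}

#' Gate an aliquot frame
#'
#' Returns the subset of cells satisfying the predicate, preserving cell
#' order. An empty result is an error because downstream histograms are
#' undefined for zero cells.
#'
#' @param frame An [aliquot_frame()].
#' @param expr A [gate_expression()] or predicate string.
#'
#' @return The gated [aliquot_frame()].
#' @export
gate <- function(frame, expr) {
  stopifnot(inherits(frame, "aliquot_frame"))
  if (is.character(expr)) expr <- gate_expression(expr)
  stopifnot(inherits(expr, "gate_expression"))
  missing <- setdiff(expr$markers, frame$marker_names)
  if (length(missing)) {
    cf_stop("cytofuse_gate_error", "gate references unknown marker(s): %s",
            paste(missing, collapse = ", "))
  }
  env <- as.data.frame(frame$events)
  keep <- eval(expr$expr, envir = env)
  if (!is.logical(keep) || length(keep) != nrow(frame$events)) {
    cf_stop("cytofuse_gate_error", "gate did not evaluate to a per-cell logical")
  }
  if (!any(keep)) {
    cf_stop("cytofuse_zero_cell", "gate '%s' removed all cells", expr$text)
  }
  frame$events <- frame$events[keep, , drop = FALSE]
  attr(frame, "population") <- attr(frame, "population")[keep]
  frame
}

#' Scale every frame of a dataset
#'
#' Applies the configured centring/scaling scheme across a study dataset:
#' \describe{
#'   \item{`cohort_reference`}{per aliquot, a scaler is fitted on the
#'     pooled cells of reference-class *training* samples and applied to
#'     every sample (train and held-out alike).}
#'   \item{`paired_individual`}{per individual and aliquot, frames are
#'     scaled with that individual's pooled paired statistics; no
#'     training-fold dependence.}
#' }
#'
#' @param dataset A [study_dataset()] with arcsinh frames.
#' @param scheme `"cohort_reference"` or `"paired_individual"`.
#' @param reference_class Class label providing the reference statistics
#'   (cohort scheme only).
#' @param training_samples Sample ids of the training fold (cohort scheme
#'   only; default all samples).
#'
#' @return List with the scaled `dataset` and the per-aliquot `scalers`
#'   (cohort scheme) or `NULL`.
#' @export
scale_study <- function(dataset,
                        scheme = c("cohort_reference", "paired_individual"),
                        reference_class = NULL, training_samples = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "cohort_reference") {
    training_samples <- training_samples %||% dataset$samples
    reference_class <- reference_class %||% dataset$classes[1L]
    ref_samples <- training_samples[
      dataset$labels[training_samples] == reference_class]
    if (length(ref_samples) == 0L) {
      cf_stop("cytofuse_config_error",
              "no training samples of reference class '%s'", reference_class)
    }
    scalers <- list()
    for (a in dataset$aliquots) {
      ref_frames <- lapply(ref_samples, function(s) get_frame(dataset, s, a))
      scalers[[a]] <- fit_cohort_scaler(ref_frames)
    }
    for (key in names(dataset$frames)) {
      fr <- dataset$frames[[key]]
      dataset$frames[[key]] <- apply_scaler(fr, scalers[[fr$aliquot_id]])
    }
    list(dataset = dataset, scalers = scalers)
  } else {
    for (a in dataset$aliquots) {
      for (ind in unique(dataset$individuals)) {
        smp <- dataset$samples[dataset$individuals == ind]
        frames <- lapply(smp, function(s) get_frame(dataset, s, a))
        scaled <- paired_individual_scaler(frames)
        for (j in seq_along(smp)) {
          dataset$frames[[frame_key(smp[j], a)]] <- scaled[[j]]
        }
      }
    }
    list(dataset = dataset, scalers = NULL)
  }
}
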