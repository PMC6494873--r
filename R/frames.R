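#' Construct an aliquot frame
#'
#' An aliquot frame holds the event table (cells x markers) of one sample
#' measured in one aliquot (staining panel), together with its identifiers
#' and the state of the intensity scale.
#'
#' @param events Numeric matrix, one row per cell, one column per marker.
#'   No missing values are allowed and at least one cell must be present.
#' @param marker_names Character vector of unique marker labels, one per
#'   column of `events`.
#' @param sample_id,individual_id,aliquot_id Identifiers. `sample_id` is
#'   unique per measured sample; several samples may share an
#'   `individual_id` (e.g. paired pre/post measurements).
#' @param transform_state One of `"raw"`, `"arcsinh"`, `"scaled"`,
#'   recording which pre-processing steps the events have undergone.
#'
#' @return An object of class `aliquot_frame`.
#' @export
aliquot_frame <- function(events, marker_names, sample_id, individual_id,
                          aliquot_id,
                          transform_state = c("raw", "arcsinh", "scaled")) {
  transform_state <- match.arg(transform_state)
  events <- as.matrix(events)
  if (!is.numeric(events)) {
    cf_stop("cytofuse_invalid_frame", "events must be numeric")
  }
  if (nrow(events) < 1L) {
    cf_stop("cytofuse_zero_cell", "aliquot frame must contain at least one cell")
  }
  if (anyNA(events)) {
    cf_stop("cytofuse_invalid_frame", "events contain missing values")
  }
  marker_names <- as.character(marker_names)
  if (length(marker_names) != ncol(events)) {
    cf_stop("cytofuse_invalid_frame",
            "marker_names length (%d) != number of columns (%d)",
            length(marker_names), ncol(events))
  }
  if (anyDuplicated(marker_names)) {
    cf_stop("cytofuse_invalid_frame", "marker names must be unique")
  }
  colnames(events) <- marker_names
  structure(
    list(events = events, marker_names = marker_names,
         sample_id = as.character(sample_id),
         individual_id = as.character(individual_id),
         aliquot_id = as.character(aliquot_id),
         transform_state = transform_state),
    class = "aliquot_frame"
  )
}

#' @export
print.aliquot_frame <- function(x, ...) {
  cat(sprintf("<aliquot_frame> sample %s, aliquot %s: %d cells x %d markers (%s)\n",
              x$sample_id, x$aliquot_id, nrow(x$events),
              length(x$marker_names), x$transform_state))
  invisible(x)
}

frame_key <- function(sample_id, aliquot_id) paste(sample_id, aliquot_id, sep = "\r")

#' Construct a study dataset
#'
#' A study dataset is a manifest-backed collection of aliquot frames: every
#' measured sample contributes one frame per aliquot, and every sample
#' carries a binary class label.
#'
#' @param frames List of [aliquot_frame()] objects.
#' @param manifest Data frame with columns `individual_id`, `sample_id`,
#'   `class` and optionally `aliquot_id`/`path`; one row per
#'   (sample, aliquot) or one row per sample. Class labels must take
#'   exactly two values across the study.
#'
#' @return An object of class `study_dataset` with components `frames`
#'   (keyed by sample and aliquot), `manifest`, `samples`, `aliquots`,
#'   `labels` (named by sample), `individuals` (named by sample) and
#'   `classes` (sorted unique labels).
#' @export
study_dataset <- function(frames, manifest) {
  stopifnot(is.list(frames), is.data.frame(manifest))
  need <- c("individual_id", "sample_id", "class")
  if (!all(need %in% names(manifest))) {
    cf_stop("cytofuse_invalid_manifest", "manifest must have columns %s",
            paste(need, collapse = ", "))
  }
  keyed <- list()
  for (fr in frames) {
    if (!inherits(fr, "aliquot_frame")) {
      cf_stop("cytofuse_invalid_frame", "all frames must be aliquot_frame objects")
    }
    keyed[[frame_key(fr$sample_id, fr$aliquot_id)]] <- fr
  }
  aliquots <- unique(vapply(frames, `[[`, "", "aliquot_id"))
  sm <- unique(manifest[c("individual_id", "sample_id", "class")])
  if (anyDuplicated(sm$sample_id)) {
    cf_stop("cytofuse_invalid_manifest", "conflicting class/individual for a sample id")
  }
  labels <- stats::setNames(as.character(sm$class), sm$sample_id)
  individuals <- stats::setNames(as.character(sm$individual_id), sm$sample_id)
  classes <- sort(unique(labels))
  structure(
    list(frames = keyed, manifest = manifest,
         samples = as.character(sm$sample_id), aliquots = aliquots,
         labels = labels, individuals = individuals, classes = classes),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d samples x %d aliquots (%s); classes: %s\n",
              length(x$samples), length(x$aliquots),
              paste(x$aliquots, collapse = ", "),
              paste(sprintf("%s=%d", x$classes, table(x$labels)[x$classes]),
                    collapse = ", ")))
  invisible(x)
}

#' Retrieve one frame of a study dataset
#'
#' @param dataset A [study_dataset()].
#' @param sample_id,aliquot_id Identifiers of the frame.
#' @return The matching [aliquot_frame()].
#' @export
get_frame <- function(dataset, sample_id, aliquot_id) {
  fr <- dataset$frames[[frame_key(sample_id, aliquot_id)]]
  if (is.null(fr)) {
    cf_stop("cytofuse_incomplete_design", "no frame for sample %s, aliquot %s",
            sample_id, aliquot_id)
  }
  fr
}

#' Subset a study dataset
#'
#' Restrict a dataset to given samples and/or aliquots; used by the
#' cross-validation loop (training folds) and the leave-one-panel-out
#' accuracy contribution.
#'
#' @param dataset A [study_dataset()].
#' @param samples Sample ids to keep (default all).
#' @param aliquots Aliquot ids to keep (default all).
#' @return A [study_dataset()] restricted to the selection.
#' @export
subset_study <- function(dataset, samples = NULL, aliquots = NULL) {
  samples <- samples %||% dataset$samples
  aliquots <- aliquots %||% dataset$aliquots
  stopifnot(all(samples %in% dataset$samples), all(aliquots %in% dataset$aliquots))
  frames <- list()
  for (s in samples) {
    for (a in aliquots) {
      key <- frame_key(s, a)
      if (!is.null(dataset$frames[[key]])) frames[[key]] <- dataset$frames[[key]]
    }
  }
  manifest <- dataset$manifest[dataset$manifest$sample_id %in% samples, , drop = FALSE]
  if ("aliquot_id" %in% names(manifest)) {
    manifest <- manifest[manifest$aliquot_id %in% aliquots, , drop = FALSE]
  }
  out <- study_dataset(unname(frames), manifest)
  out$aliquots <- aliquots       # preserve requested aliquot order
  out$samples <- samples
  out$labels <- out$labels[samples]
  out$individuals <- out$individuals[samples]
  out
}

#' Replace the class labels of a study dataset
#'
#' Used by the permutation test: frames are untouched, only the labels in
#' the manifest change.
#'
#' @param dataset A [study_dataset()].
#' @param labels Named character vector (names = sample ids) of new labels.
#' @return The relabelled [study_dataset()].
#' @export
relabel_study <- function(dataset, labels) {
  stopifnot(setequal(names(labels), dataset$samples))
  dataset$labels[names(labels)] <- as.character(labels)
  dataset$manifest$class <-
    dataset$labels[as.character(dataset$manifest$sample_id)]
  dataset$classes <- sort(unique(dataset$labels))
  dataset
}
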