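#' Read an event table from CSV
#'
#' The CSV has one row per cell and a header of marker names.
#'
#' @param path CSV file.
#' @param sample_id,individual_id,aliquot_id Identifiers for the frame.
#' @param transform_state Scale state of the stored values.
#' @return An [aliquot_frame()].
#' @export
read_aliquot_csv <- function(path, sample_id, individual_id, aliquot_id,
                             transform_state = "raw") {
  df <- utils::read.csv(path, check.names = FALSE)
  aliquot_frame(as.matrix(df), colnames(df), sample_id, individual_id,
                aliquot_id, transform_state = transform_state)
}

#' @rdname read_aliquot_csv
#' @param frame Frame to write.
#' @export
write_aliquot_csv <- function(frame, path) {
  utils::write.csv(as.data.frame(frame$events), path, row.names = FALSE)
  invisible(path)
}

# ---- minimal FCS 3.1 -------------------------------------------------------

fcs_text_segment <- function(kw, delim = "/") {
  paste0(delim, paste0(names(kw), delim, unname(kw), delim, collapse = ""))
}

#' Write a minimal FCS 3.1 file
#'
#' List-mode, single dataset, 32-bit little-endian floats, `$PnN` set to
#' the marker names. Only the keywords required by the standard are
#' written; spillover/compensation and analysis segments are not.
#'
#' @param frame An [aliquot_frame()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(frame, path) {
  ev <- frame$events
  n_par <- ncol(ev)
  kw <- c("$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = as.character(n_par),
          "$TOT" = as.character(nrow(ev)))
  for (j in seq_len(n_par)) {
    kw[sprintf("$P%dN", j)] <- frame$marker_names[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- "262144"
  }
  # fixed-width data offsets so the TEXT size is stable while we fill them in
  kw["$BEGINDATA"] <- "00000000"
  kw["$ENDDATA"] <- "00000000"
  kw["$BEGINANALYSIS"] <- "0"
  kw["$ENDANALYSIS"] <- "0"
  kw["$BEGINSTEXT"] <- "0"
  kw["$ENDSTEXT"] <- "0"

  header_len <- 58L
  text <- fcs_text_segment(kw)
  text_begin <- header_len
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * length(ev) - 1L
  kw["$BEGINDATA"] <- sprintf("%08d", data_begin)
  kw["$ENDDATA"] <- sprintf("%08d", data_end)
  text <- fcs_text_segment(kw)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(ev)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 file
#'
#' Supports list-mode datasets with float (`$DATATYPE F`/`D`) or integer
#' (`I`, byte-aligned widths) data and either byte order. Marker names
#' come from `$PnS` when present, else `$PnN`.
#'
#' @param path FCS file.
#' @param sample_id,individual_id,aliquot_id Identifiers for the frame.
#' @param transform_state Scale state of the stored values.
#' @return An [aliquot_frame()].
#' @export
read_fcs <- function(path, sample_id, individual_id, aliquot_id,
                     transform_state = "raw") {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  header <- rawToChar(raw_all[1:58])
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    cf_stop("cytofuse_io_error", "unsupported FCS version '%s'", version)
  }
  off <- function(i) {
    as.integer(trimws(substr(header, 11L + (i - 1L) * 8L, 10L + i * 8L)))
  }
  text_begin <- off(1L); text_end <- off(2L)
  data_begin <- off(3L); data_end <- off(4L)
  text <- rawToChar(raw_all[(text_begin + 1L):(text_end + 1L)])
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2L, length(parts), 2L)],
                        toupper(parts[seq(1L, length(parts), 2L)]))
  if (data_begin == 0L) data_begin <- as.integer(kw[["$BEGINDATA"]])
  if (data_end == 0L) data_end <- as.integer(kw[["$ENDDATA"]])
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  bytes <- raw_all[(data_begin + 1L):(data_end + 1L)]
  vals <- if (dtype == "F") {
    readBin(bytes, "numeric", n = n_par * n_tot, size = 4L, endian = endian)
  } else if (dtype == "D") {
    readBin(bytes, "numeric", n = n_par * n_tot, size = 8L, endian = endian)
  } else if (dtype == "I") {
    size <- as.integer(kw[["$P1B"]]) %/% 8L
    readBin(bytes, "integer", n = n_par * n_tot, size = size,
            endian = endian, signed = size > 2L)
  } else {
    cf_stop("cytofuse_io_error", "unsupported $DATATYPE '%s'", dtype)
  }
  ev <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  kval <- function(name) if (name %in% names(kw)) kw[[name]] else NULL
  marker <- vapply(seq_len(n_par), function(j) {
    kval(sprintf("$P%dS", j)) %||% kval(sprintf("$P%dN", j)) %||%
      sprintf("P%d", j)
  }, "")
  aliquot_frame(ev, marker, sample_id, individual_id, aliquot_id,
                transform_state = transform_state)
}

# ---- study-level I/O -------------------------------------------------------

#' Write a study to disk (per-sample files + manifest)
#'
#' One file per (sample, aliquot) plus `manifest.csv` with columns
#' `individual_id`, `sample_id`, `class`, `aliquot_id`, `path`,
#' `transform_state`.
#'
#' @param dataset A [study_dataset()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"fcs"`.
#' @return Path of the manifest, invisibly.
#' @export
write_study <- function(dataset, dir, format = c("csv", "fcs")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in dataset$samples) {
    for (a in dataset$aliquots) {
      fr <- get_frame(dataset, s, a)
      fn <- sprintf("%s_%s.%s", s, a, format)
      p <- file.path(dir, fn)
      if (format == "csv") write_aliquot_csv(fr, p) else write_fcs(fr, p)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = fr$individual_id, sample_id = s,
        class = unname(dataset$labels[s]), aliquot_id = a, path = fn,
        transform_state = fr$transform_state, stringsAsFactors = FALSE)
    }
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a study from a manifest
#'
#' @param manifest_path Manifest CSV (columns `individual_id`,
#'   `sample_id`, `class`, `aliquot_id`, `path`, optional
#'   `transform_state`); paths are resolved relative to the manifest.
#' @return A [study_dataset()].
#' @export
read_study <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  frames <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    p <- if (file.exists(row$path)) row$path else file.path(base, row$path)
    if (!file.exists(p)) {
      cf_stop("cytofuse_io_error", "missing aliquot file '%s' for sample %s",
              row$path, row$sample_id)
    }
    state <- if ("transform_state" %in% names(manifest)) {
      row$transform_state
    } else "raw"
    frames[[i]] <- if (grepl("\\.fcs$", p, ignore.case = TRUE)) {
      read_fcs(p, row$sample_id, row$individual_id, row$aliquot_id, state)
    } else {
      read_aliquot_csv(p, row$sample_id, row$individual_id, row$aliquot_id,
                       state)
    }
  }
  study_dataset(frames, manifest)
}
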