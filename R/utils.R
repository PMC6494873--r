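#' @keywords internal
"_PACKAGE"

# stop() with a condition class so callers can test for specific failures
cf_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "cytofuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

l2norm <- function(x) sqrt(sum(x^2))

# Row-major unfolding of an F x F histogram to a length-F^2 vector, and back.
# Row-major means bin (f1, f2) lands at position (f1 - 1) * F + f2.
unfold_histogram <- function(h) as.vector(t(h))

refold_histogram <- function(v, F) {
  stopifnot(length(v) == F * F)
  t(matrix(v, nrow = F, ncol = F))
}

# Deterministic stratified fold ids (used where an inner CV needs folds but
# results must not depend on the RNG state, e.g. glmnet lambda selection).
deterministic_foldid <- function(y, n_folds) {
  fid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fid
}

`%||%` <- function(a, b) if (is.null(a)) b else a
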