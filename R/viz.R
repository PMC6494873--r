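open_figure_device <- function(file, width = 7, height = 6) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    png = grDevices::png(file, width = width, height = height, units = "in",
                         res = 150),
    pdf = grDevices::pdf(file, width = width, height = height),
    svg = grDevices::svg(file, width = width, height = height),
    cf_stop("cytofuse_config_error", "unsupported figure format '%s'", ext))
}

#' Density level enclosing a mass fraction
#'
#' For a discrete unit-sum histogram, returns the largest bin value `L`
#' such that the bins with value `>= L` together hold at least `fraction`
#' of the total mass. Drawing the contour at `L` therefore encloses (at
#' least) that fraction of the cells.
#'
#' @param values Non-negative histogram values (any shape).
#' @param fraction Target mass fraction in (0, 1), default 0.80.
#' @return The density level.
#' @export
contour_mass_level <- function(values, fraction = 0.80) {
  if (fraction <= 0 || fraction >= 1) {
    cf_stop("cytofuse_config_error", "contour fraction must be in (0, 1)")
  }
  v <- sort(as.vector(values), decreasing = TRUE)
  cs <- cumsum(v) / sum(v)
  v[which(cs >= fraction)[1L]]
}

#' Plot per-individual mean prediction scores
#'
#' Scatter of the mean prediction score of every individual with class
#' glyphs/colours and the classification threshold as a horizontal line;
#' samples on the wrong side of the line are the misclassified ones.
#'
#' @param mean_scores Named numeric vector (one score per sample).
#' @param labels Named class labels.
#' @param threshold Classification threshold.
#' @param positive_class Class plotted in blue above the threshold
#'   (default: `"case"` when present).
#' @param file Optional output path (`.png`, `.pdf` or `.svg`); when
#'   `NULL`, draws on the current device.
#' @return Invisibly, the data frame that was plotted.
#' @export
plot_scores <- function(mean_scores, labels, threshold,
                        positive_class = NULL, file = NULL) {
  labels <- labels[names(mean_scores)]
  classes <- sort(unique(labels))
  positive_class <- positive_class %||%
    (if ("case" %in% classes) "case" else classes[2L])
  if (!is.null(file)) {
    open_figure_device(file)
    on.exit(grDevices::dev.off())
  }
  is_pos <- labels == positive_class
  col <- ifelse(is_pos, "#2166ac", "#b2182b")
  pch <- ifelse(is_pos, 4L, 1L)
  graphics::plot(seq_along(mean_scores), mean_scores, col = col, pch = pch,
                 xlab = "individual", ylab = "mean prediction score",
                 main = "Mean prediction scores")
  graphics::abline(h = threshold, lty = 2L)
  graphics::legend("topleft",
                   legend = c(positive_class,
                              setdiff(classes, positive_class), "threshold"),
                   col = c("#2166ac", "#b2182b", "black"),
                   pch = c(4L, 1L, NA), lty = c(NA, NA, 2L), bty = "n")
  invisible(data.frame(sample = names(mean_scores), score = mean_scores,
                       label = labels))
}

#' Plot a per-aliquot leukocyte map
#'
#' Diverging-colour image of one aliquot's refolded weight slice
#' (positive weights in blue: cells overrepresented in the positive
#' class; negative in red), overlaid with the base model's PCA loadings
#' as labelled arrows and, optionally, per-class contours enclosing a
#' target fraction of the class-mean histogram.
#'
#' @param weight_map A [refold_weights()] array.
#' @param aliquot Aliquot id (slice name) or index.
#' @param base_model The aliquot's [fit_base_model()].
#' @param grid The aliquot's [make_grid()].
#' @param class_histograms Optional named list (class -> mean F x F
#'   histogram) for the contours.
#' @param contour_fraction Mass fraction enclosed by the contours.
#' @param arrow_scale Loading arrows are drawn at `arrow_scale` times the
#'   score half-range (fixed documented scale; default 0.4).
#' @param file Optional output path.
#' @return Invisibly, the plotted weight slice.
#' @export
plot_leukocyte_map <- function(weight_map, aliquot, base_model, grid,
                               class_histograms = NULL,
                               contour_fraction = 0.80, arrow_scale = 0.4,
                               file = NULL) {
  M_names <- dimnames(weight_map)[[3L]]
  m <- if (is.character(aliquot)) match(aliquot, M_names) else as.integer(aliquot)
  if (is.na(m) || m < 1L || m > dim(weight_map)[3L]) {
    cf_stop("cytofuse_config_error", "unknown aliquot '%s'", aliquot)
  }
  W <- weight_map[, , m]
  centres <- lapply(1:2, function(d) {
    e <- grid$edges[[d]]
    (e[-1L] + e[-length(e)]) / 2
  })
  if (!is.null(file)) {
    open_figure_device(file)
    on.exit(grDevices::dev.off())
  }
  lim <- max(abs(W), 1e-12)
  pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(255L)
  graphics::image(centres[[1L]], centres[[2L]], W, zlim = c(-lim, lim),
                  col = pal, xlab = "PC1 score", ylab = "PC2 score",
                  main = sprintf("Leukocyte map, aliquot %s",
                                 if (is.character(aliquot)) aliquot else
                                   M_names[m] %||% m))
  if (!is.null(class_histograms)) {
    cls_col <- c("#2166ac", "#b2182b", "#4daf4a", "#984ea3")
    for (ci in seq_along(class_histograms)) {
      h <- class_histograms[[ci]]
      lev <- contour_mass_level(h, contour_fraction)
      graphics::contour(centres[[1L]], centres[[2L]], h, levels = lev,
                        add = TRUE, drawlabels = FALSE,
                        col = cls_col[(ci - 1L) %% 4L + 1L], lwd = 2L)
    }
  }
  L <- base_model$loadings
  span <- arrow_scale * min(diff(range(centres[[1L]])),
                            diff(range(centres[[2L]]))) / 2
  sc <- span / max(sqrt(rowSums(L^2)))
  ctr <- c(mean(range(centres[[1L]])), mean(range(centres[[2L]])))
  for (j in seq_len(nrow(L))) {
    graphics::arrows(ctr[1L], ctr[2L], ctr[1L] + sc * L[j, 1L],
                     ctr[2L] + sc * L[j, 2L], length = 0.08)
    graphics::text(ctr[1L] + 1.1 * sc * L[j, 1L],
                   ctr[2L] + 1.1 * sc * L[j, 2L],
                   base_model$marker_names[j], cex = 0.7)
  }
  invisible(W)
}

#' Plot a SOM minimum spanning tree with pie-chart nodes
#'
#' MST layout with node backgrounds coloured by the sign/magnitude of a
#' per-node statistic (e.g. classifier coefficient: blue positive, red
#' negative) and pie wedges proportional to the node's non-negative
#' rescaled mean marker expression.
#'
#' @param som A [fit_som()] model.
#' @param mst A [build_mst()] result.
#' @param node_stat Numeric vector (one value per node).
#' @param node_profiles Nodes x markers matrix of mean expressions
#'   (default: the codebook).
#' @param marker_names Wedge labels for the legend.
#' @param file Optional output path.
#' @return Invisibly, the layout coordinates.
#' @export
plot_som_tree <- function(som, mst, node_stat,
                          node_profiles = NULL, marker_names = NULL,
                          file = NULL) {
  node_profiles <- node_profiles %||% som$codebook
  marker_names <- marker_names %||%
    colnames(node_profiles) %||% sprintf("m%d", seq_len(ncol(node_profiles)))
  n <- nrow(som$codebook)
  stopifnot(length(node_stat) == n)
  xy <- mst$layout
  xy <- sweep(xy, 2L, apply(xy, 2L, min))
  xy <- sweep(xy, 2L, pmax(apply(xy, 2L, max), 1e-9), "/")
  if (!is.null(file)) {
    open_figure_device(file)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.05, 1.05),
                 axes = FALSE, xlab = "", ylab = "",
                 main = "SOM minimum spanning tree")
  for (i in seq_len(nrow(mst$edges))) {
    graphics::segments(xy[mst$edges$from[i], 1L], xy[mst$edges$from[i], 2L],
                       xy[mst$edges$to[i], 1L], xy[mst$edges$to[i], 2L],
                       col = "grey70")
  }
  lim <- max(abs(node_stat), 1e-12)
  bg_pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(255L)
  r_node <- 0.02
  wedge_pal <- grDevices::hcl.colors(ncol(node_profiles), "Dark 3")
  for (i in seq_len(n)) {
    bg <- bg_pal[1L + round(254 * (node_stat[i] + lim) / (2 * lim))]
    graphics::symbols(xy[i, 1L], xy[i, 2L], circles = 1.6 * r_node,
                      inches = FALSE, add = TRUE, bg = bg, fg = NA)
    prof <- node_profiles[i, ] - min(node_profiles)
    if (sum(prof) <= 0) prof <- rep(1, length(prof))
    ang <- 2 * pi * c(0, cumsum(prof) / sum(prof))
    for (j in seq_along(prof)) {
      th <- seq(ang[j], ang[j + 1L], length.out = 16L)
      graphics::polygon(c(xy[i, 1L], xy[i, 1L] + r_node * cos(th)),
                        c(xy[i, 2L], xy[i, 2L] + r_node * sin(th)),
                        col = wedge_pal[j], border = NA)
    }
  }
  graphics::legend("bottomright", legend = marker_names, fill = wedge_pal,
                   cex = 0.6, bty = "n")
  invisible(xy)
}
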