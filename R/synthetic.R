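#' Define a cell population template
#'
#' A population template describes one cell population within one aliquot
#' panel: a multivariate-normal cluster of marker expressions (on the
#' transformed, post-arcsinh scale) and its baseline abundance.
#'
#' @param aliquot_id Aliquot (panel) the population belongs to.
#' @param name Population label (e.g. `"mature_neutrophil"`).
#' @param mean Named numeric vector of marker means on the transformed
#'   scale; names are the aliquot's marker names.
#' @param covariance Symmetric positive-semidefinite marker covariance
#'   matrix.
#' @param base_abundance Baseline fraction of cells in `[0, 1]`. The
#'   abundances of all templates of one aliquot must sum to 1.
#'
#' @return An object of class `population_template`.
#' @export
population_template <- function(aliquot_id, name, mean, covariance,
                                base_abundance) {
  mean <- unlist(mean)
  covariance <- as.matrix(covariance)
  if (is.null(names(mean))) {
    cf_stop("cytofuse_invalid_template", "population mean must be a named vector")
  }
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8))) {
    cf_stop("cytofuse_invalid_template",
            "covariance of population '%s' is not symmetric", name)
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    cf_stop("cytofuse_invalid_template",
            "covariance of population '%s' is not positive semidefinite", name)
  }
  if (nrow(covariance) != length(mean)) {
    cf_stop("cytofuse_invalid_template",
            "covariance dimension does not match mean length")
  }
  if (base_abundance < 0 || base_abundance > 1) {
    cf_stop("cytofuse_invalid_template", "base_abundance must be in [0, 1]")
  }
  structure(
    list(aliquot_id = as.character(aliquot_id), name = as.character(name),
         mean = mean, covariance = covariance,
         base_abundance = base_abundance),
    class = "population_template"
  )
}

#' Define a simulation scenario
#'
#' Collects the knobs of the synthetic multi-panel study generator: group
#' sizes, cells per sample, class effects on population abundances (logit
#' shifts), latent per-individual factor loadings that carry cross-panel
#' covariance, class shifts of marker means, and biological noise.
#'
#' @param n_per_class Integer pair: number of individuals in
#'   (control, case); each must be at least 2.
#' @param cells_per_sample Cells drawn per sample (>= 100).
#' @param abundance_effects Named list: class label -> named numeric vector
#'   of per-population logit shifts.
#' @param latent_loadings Named numeric vector: population -> coefficient
#'   on the latent per-individual factor `u_i ~ N(0, 1)` shared across all
#'   of an individual's aliquots.
#' @param marker_shift_effects Named list: class label -> named list
#'   (population -> numeric marker mean shift vector).
#' @param noise_sd Standard deviation of the per-individual,
#'   per-population abundance-logit noise.
#' @param seed Integer RNG seed; identical seeds give bit-identical studies.
#' @param emit_raw If `TRUE`, events are emitted on the raw intensity scale
#'   via `sinh(x) * cofactor` so that the arcsinh pre-processing path is
#'   exercised end-to-end.
#' @param cofactor Cofactor used when `emit_raw = TRUE` (default 150).
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_per_class = c(20L, 20L),
                            cells_per_sample = 2000L,
                            abundance_effects = list(),
                            latent_loadings = numeric(),
                            marker_shift_effects = list(),
                            noise_sd = 0.25, seed = 1L,
                            emit_raw = FALSE, cofactor = 150) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 2L || any(n_per_class < 2L)) {
    cf_stop("cytofuse_invalid_config", "n_per_class must be two integers >= 2")
  }
  if (cells_per_sample < 100L) {
    cf_stop("cytofuse_invalid_config", "cells_per_sample must be >= 100")
  }
  if (noise_sd < 0) cf_stop("cytofuse_invalid_config", "noise_sd must be >= 0")
  structure(
    list(n_per_class = n_per_class,
         cells_per_sample = as.integer(cells_per_sample),
         abundance_effects = abundance_effects,
         latent_loadings = latent_loadings,
         marker_shift_effects = marker_shift_effects,
         noise_sd = noise_sd, seed = as.integer(seed),
         emit_raw = isTRUE(emit_raw), cofactor = cofactor),
    class = "scenario_config"
  )
}

mvn_draw <- function(n, mu, sigma) {
  if (n == 0L) return(matrix(numeric(0), 0L, length(mu)))
  matrix(MASS::mvrnorm(n, mu = mu, Sigma = sigma), ncol = length(mu),
         byrow = FALSE)
}

#' Simulate a multi-panel case-control cytometry study
#'
#' Draws one study with known ground truth. For each individual `i` a
#' latent factor `u_i ~ N(0, 1)` is drawn and shared across aliquots.
#' Per aliquot, population fractions follow a softmax of
#' `log(base_abundance) + class effect + loading * u_i + noise`; cell
#' counts per population are multinomial and events are multivariate
#' normal around the population template.
#'
#' @param templates List of [population_template()] objects covering at
#'   least one aliquot; abundances within each aliquot must sum to 1.
#' @param config A [scenario_config()].
#'
#' @return A [study_dataset()] with one sample per individual and one
#'   frame per (individual, aliquot). Each frame carries attributes
#'   `population` (per-cell population label), `population_fractions`
#'   (the post-noise expected fractions used for the multinomial draw)
#'   and `population_counts`. The dataset carries attribute `latent_u`.
#' @export
simulate_study <- function(templates, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(templates) == 0L) {
    cf_stop("cytofuse_invalid_template", "no population templates supplied")
  }
  for (tp in templates) {
    if (!inherits(tp, "population_template")) {
      cf_stop("cytofuse_invalid_template",
              "templates must be population_template objects")
    }
  }
  aliquots <- unique(vapply(templates, `[[`, "", "aliquot_id"))
  by_aliquot <- lapply(aliquots, function(a) {
    templates[vapply(templates, `[[`, "", "aliquot_id") == a]
  })
  names(by_aliquot) <- aliquots
  for (a in aliquots) {
    tps <- by_aliquot[[a]]
    if (length(tps) == 0L) cf_stop("cytofuse_invalid_template", "empty aliquot %s", a)
    ab <- sum(vapply(tps, `[[`, 0, "base_abundance"))
    if (abs(ab - 1) > 1e-9) {
      cf_stop("cytofuse_invalid_template",
              "abundances of aliquot %s sum to %.6f, not 1", a, ab)
    }
    mk <- lapply(tps, function(t) names(t$mean))
    if (!all(vapply(mk, identical, TRUE, mk[[1]]))) {
      cf_stop("cytofuse_invalid_template",
              "populations of aliquot %s disagree on marker names", a)
    }
  }

  set.seed(config$seed)
  classes <- c(rep("control", config$n_per_class[1L]),
               rep("case", config$n_per_class[2L]))
  n_ind <- length(classes)
  ids <- sprintf("ind%03d", seq_len(n_ind))
  u <- stats::rnorm(n_ind)

  frames <- vector("list", n_ind * length(aliquots))
  k <- 0L
  for (i in seq_len(n_ind)) {
    cls <- classes[i]
    for (a in aliquots) {
      tps <- by_aliquot[[a]]
      pop_names <- vapply(tps, `[[`, "", "name")
      logits <- log(vapply(tps, `[[`, 0, "base_abundance"))
      eff <- config$abundance_effects[[cls]]
      if (!is.null(eff)) {
        hit <- intersect(names(eff), pop_names)
        logits[match(hit, pop_names)] <-
          logits[match(hit, pop_names)] + eff[hit]
      }
      load <- config$latent_loadings
      if (length(load)) {
        hit <- intersect(names(load), pop_names)
        logits[match(hit, pop_names)] <-
          logits[match(hit, pop_names)] + load[hit] * u[i]
      }
      logits <- logits + stats::rnorm(length(logits), 0, config$noise_sd)
      frac <- softmax(logits)
      counts <- as.vector(stats::rmultinom(1L, config$cells_per_sample, frac))
      blocks <- vector("list", length(tps))
      for (p in seq_along(tps)) {
        mu <- tps[[p]]$mean
        shift <- config$marker_shift_effects[[cls]][[pop_names[p]]]
        if (!is.null(shift)) mu <- mu + shift
        blocks[[p]] <- mvn_draw(counts[p], mu, tps[[p]]$covariance)
      }
      ev <- do.call(rbind, blocks)
      state <- "arcsinh"
      if (config$emit_raw) {
        ev <- sinh(ev) * config$cofactor
        state <- "raw"
      }
      fr <- aliquot_frame(ev, names(tps[[1L]]$mean),
                          sample_id = ids[i], individual_id = ids[i],
                          aliquot_id = a, transform_state = state)
      attr(fr, "population") <- rep(pop_names, counts)
      attr(fr, "population_fractions") <- stats::setNames(frac, pop_names)
      attr(fr, "population_counts") <- stats::setNames(counts, pop_names)
      k <- k + 1L
      frames[[k]] <- fr
    }
  }

  manifest <- data.frame(
    individual_id = rep(ids, each = length(aliquots)),
    sample_id = rep(ids, each = length(aliquots)),
    class = rep(classes, each = length(aliquots)),
    aliquot_id = rep(aliquots, times = n_ind),
    path = NA_character_,
    stringsAsFactors = FALSE
  )
  out <- study_dataset(frames, manifest)
  attr(out, "latent_u") <- stats::setNames(u, ids)
  out
}

#' Built-in simulation scenarios
#'
#' Three study designs with two four-marker panels and three populations
#' per panel:
#' \describe{
#'   \item{`null`}{no class effect at all; class-conditional distributions
#'     are identical by construction.}
#'   \item{`single_panel_effect`}{the abundance of the `immature`
#'     population in panel `A1` is shifted from an expected 10\% in
#'     controls to 30\% in cases; nothing else differs.}
#'   \item{`cross_panel_only`}{`immature` (panel `A1`) loads +2 and
#'     `activated` (panel `A2`) loads -2 on the shared latent factor,
#'     and `activated` additionally carries a +1.6 logit class effect
#'     (30 individuals per class). The latent variance dominates each
#'     marginal, so each panel alone is weakly informative, while a
#'     fused model can cancel the latent factor across panels and
#'     recover the class effect.}
#' }
#'
#' @param name One of `"null"`, `"single_panel_effect"`,
#'   `"cross_panel_only"`.
#' @param seed Seed stored in the returned config.
#'
#' @return List with elements `templates` and `config`.
#' @export
scenario_preset <- function(name = c("null", "single_panel_effect",
                                     "cross_panel_only"),
                            seed = 1L) {
  if (!is.character(name) || !name[1L] %in%
      c("null", "single_panel_effect", "cross_panel_only")) {
    cf_stop("cytofuse_unknown_preset", "unknown preset '%s'", name[1L])
  }
  name <- name[1L]

  m1 <- c("CD16", "CD62L", "CD11b", "CD64")
  m2 <- c("CD38", "CD25", "CD45RO", "CD127")
  cov1 <- diag(0.16, 4L) + 0.03
  make_templates <- function(ab1) {
    list(
      population_template("A1", "mature",
        stats::setNames(c(2.6, 2.5, 1.2, 0.4), m1), cov1, ab1[1L]),
      population_template("A1", "immature",
        stats::setNames(c(0.9, 2.3, 0.7, 1.9), m1), cov1, ab1[2L]),
      population_template("A1", "banded",
        stats::setNames(c(2.4, 0.7, 2.1, 0.9), m1), cov1, ab1[3L]),
      population_template("A2", "naive",
        stats::setNames(c(2.2, 0.5, 0.6, 1.8), m2), cov1, 0.50),
      population_template("A2", "activated",
        stats::setNames(c(1.0, 2.4, 2.2, 0.8), m2), cov1, 0.25),
      population_template("A2", "memory",
        stats::setNames(c(0.6, 1.0, 2.5, 2.3), m2), cov1, 0.25)
    )
  }

  out <- switch(
    name,
    null = list(
      templates = make_templates(c(0.55, 0.10, 0.35)),
      config = scenario_config(seed = seed)
    ),
    single_panel_effect = list(
      # a richer A1 panel: the -20% abundance compensation forced by the
      # simplex is spread over six background populations, as in real blood
      # where one expanding subset dilutes many others a little
      templates = c(local({
        # broad background clusters (sd ~0.6 per marker) dilute the forced
        # abundance compensation over many bins; the planted immature
        # population stays tight (sd ~0.4) as activation subsets tend to be
        cov_bg <- diag(0.36, 4L) + 0.04
        list(
          population_template("A1", "immature",
            stats::setNames(c(0.9, 2.3, 0.7, 1.9), m1), cov1, 0.10),
          population_template("A1", "mature",
            stats::setNames(c(2.6, 2.5, 1.2, 0.4), m1), cov_bg, 0.14),
          population_template("A1", "banded",
            stats::setNames(c(2.4, 0.7, 2.1, 0.9), m1), cov_bg, 0.13),
          population_template("A1", "mono_classical",
            stats::setNames(c(0.5, 1.2, 2.6, 2.4), m1), cov_bg, 0.13),
          population_template("A1", "mono_nonclassical",
            stats::setNames(c(3.2, 1.4, 2.8, 1.5), m1), cov_bg, 0.12),
          population_template("A1", "eosinophil",
            stats::setNames(c(0.3, 3.0, 1.8, 0.3), m1), cov_bg, 0.13),
          population_template("A1", "pmn_activated",
            stats::setNames(c(1.6, 0.2, 3.1, 2.8), m1), cov_bg, 0.12),
          population_template("A1", "lymph_contaminant",
            stats::setNames(c(1.4, 1.6, 0.3, 1.1), m1), cov_bg, 0.13))
      }),
        make_templates(c(0.55, 0.10, 0.35))[4:6]),
      config = scenario_config(
        # log(0.30/0.70) - log(0.10/0.90): expected 10% (control) vs
        # 30% (case) abundance of the immature population, panel A1 only
        abundance_effects = list(case = c(immature = log(27 / 7))),
        seed = seed
      )
    ),
    cross_panel_only = list(
      # matched base abundances of the two latent-coupled populations keep
      # the latent factor's effect on the two panels' fractions of similar
      # magnitude, so a linear fused model can cancel it
      templates = make_templates(c(0.42, 0.30, 0.28)),
      config = scenario_config(
        n_per_class = c(30L, 30L),
        abundance_effects = list(case = c(activated = 1.6)),
        latent_loadings = c(immature = 2.0, activated = -2.0),
        noise_sd = 0.05,
        seed = seed
      )
    )
  )
  out
}

#' Histogram bins covered by a population's score-space region
#'
#' Maps a population template through a fitted per-aliquot PCA base model
#' and marks the histogram bins whose centres fall inside the population's
#' `level` probability ellipse in score space. Used to check that the
#' discriminant weight mass concentrates on a planted population.
#'
#' @param template A [population_template()].
#' @param model A [fit_base_model()] result for the template's aliquot.
#' @param grid A [make_grid()] result.
#' @param scaler Optional cohort scaler (from [fit_cohort_scaler()])
#'   applied to the template mean/covariance before projection.
#' @param level Probability mass of the ellipse (default 0.95).
#'
#' @return Logical F x F matrix: `TRUE` where the bin centre lies inside
#'   the ellipse.
#' @export
population_bin_mask <- function(template, model, grid, scaler = NULL,
                                level = 0.95) {
  mu <- template$mean
  sigma <- template$covariance
  if (!is.null(scaler)) {
    mu <- (mu - scaler$median) / scaler$sd
    sigma <- diag(1 / scaler$sd) %*% sigma %*% diag(1 / scaler$sd)
  }
  L <- model$loadings
  mu_s <- as.vector((mu - model$column_means) %*% L)
  sig_s <- t(L) %*% sigma %*% L
  centres1 <- (grid$edges[[1L]][-1L] + grid$edges[[1L]][-(grid$F + 1L)]) / 2
  centres2 <- (grid$edges[[2L]][-1L] + grid$edges[[2L]][-(grid$F + 1L)]) / 2
  pts <- cbind(rep(centres1, times = grid$F), rep(centres2, each = grid$F))
  d2 <- stats::mahalanobis(pts, center = mu_s, cov = sig_s)
  inside <- d2 <= stats::qchisq(level, df = 2L)
  matrix(inside, nrow = grid$F, ncol = grid$F)  # [f1, f2] indexing
}
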