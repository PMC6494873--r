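# Small fixtures built in code: two-panel templates with two populations
# each, and a reduced pipeline configuration that keeps unit tests fast.

tiny_templates <- function() {
  m1 <- c("CD16", "CD62L")
  m2 <- c("CD38", "CD25")
  cv <- diag(0.09, 2L)
  list(
    population_template("P1", "popA", stats::setNames(c(0.5, 2.0), m1), cv, 0.4),
    population_template("P1", "popB", stats::setNames(c(2.2, 0.6), m1), cv, 0.6),
    population_template("P2", "popC", stats::setNames(c(1.8, 1.8), m2), cv, 0.5),
    population_template("P2", "popD", stats::setNames(c(0.3, 0.4), m2), cv, 0.5)
  )
}

tiny_study <- function(seed = 1L, n_per_class = c(4L, 4L), cells = 300L,
                       effects = list(), ...) {
  simulate_study(tiny_templates(),
                 scenario_config(n_per_class = n_per_class,
                                 cells_per_sample = cells,
                                 abundance_effects = effects,
                                 seed = seed, ...))
}

tiny_config <- function(...) {
  pipeline_config(F = 20L, smoothing_sd = 1, K_ortho_max = 2L, ...)
}

two_blob_cells <- function(n = 600L, seed = 5L) {
  set.seed(seed)
  rbind(matrix(stats::rnorm(n, 0, 0.3), ncol = 2),
        matrix(stats::rnorm(n, 4, 0.3), ncol = 2))
}

# a frame built directly from a matrix, for preprocessing tests
frame_from <- function(events, markers = paste0("m", seq_len(ncol(events))),
                       sample = "s1", individual = "i1", aliquot = "a1",
                       state = "arcsinh") {
  aliquot_frame(events, markers, sample, individual, aliquot,
                transform_state = state)
}
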