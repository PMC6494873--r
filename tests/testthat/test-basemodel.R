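scaled_frames <- function(seed = 1L, n = 3L, cells = 200L, p = 4L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    frame_from(matrix(stats::rnorm(cells * p), ncol = p),
               markers = paste0("m", seq_len(p)),
               sample = paste0("s", i), individual = paste0("s", i),
               state = "arcsinh")
  })
}

test_that("base model PCA recovers exact low-rank structure", {
  set.seed(2)
  basis <- qr.Q(qr(matrix(rnorm(16), 4)))[, 1:2]
  scores <- matrix(rnorm(600), ncol = 2) %*% diag(c(3, 1))
  fr <- frame_from(scores %*% t(basis), markers = paste0("m", 1:4))
  bm <- fit_base_model(list(fr), K_base = 2L)
  expect_equal(sum(bm$explained_variance), 1, tolerance = 1e-9)
  expect_equal(crossprod(bm$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # deterministic sign: largest-magnitude loading element positive
  for (k in 1:2) expect_gt(bm$loadings[which.max(abs(bm$loadings[, k])), k], 0)
  # projected training scores are centred
  sc <- project_cells(fr, bm)
  expect_equal(colMeans(sc), c(0, 0), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rank-deficient training data is rejected", {
  fr <- frame_from(cbind(1:50, (1:50) * 2, (1:50) * 3, 1:50),
                   markers = paste0("m", 1:4))
  expect_error(fit_base_model(list(fr), K_base = 2L),
               class = "cytofuse_degenerate_data")
})

test_that("projection is linear and exact for the training pool", {
  frames <- scaled_frames()
  bm <- fit_base_model(frames, K_base = 2L)
  pooled <- do.call(rbind, lapply(frames, `[[`, "events"))
  sc <- project_cells(pooled, bm)
  expect_equal(sc, sweep(pooled, 2, bm$column_means) %*% bm$loadings)
  # frame equal to the column means projects to zero
  expect_equal(as.vector(project_cells(matrix(bm$column_means, 1), bm)),
               c(0, 0), tolerance = 1e-12)
  # linearity
  a <- 2.5
  expect_equal(project_cells(a * pooled, bm) - project_cells(0 * pooled, bm),
               a * (project_cells(pooled, bm) - project_cells(0 * pooled, bm)),
               tolerance = 1e-10)
  expect_error(project_cells(pooled[, 1:3], bm),
               class = "cytofuse_marker_mismatch")
})

test_that("grids span the training scores with equal-width bins", {
  sc <- cbind(seq(0, 1, length.out = 11), seq(0, 1, length.out = 11))
  g <- make_grid(sc, F = 10L, margin_fraction = 0, smoothing_sd = 0)
  expect_equal(g$edges[[1L]], seq(0, 1, by = 0.1))
  expect_equal(g$edges[[2L]], seq(0, 1, by = 0.1))
  expect_error(make_grid(cbind(rep(1, 5), 1:5), F = 10L),
               class = "cytofuse_degenerate_data")
  expect_equal(make_grid(sc)$F, 100L)  # documented default
})

test_that("histograms are unit-sum, mass-preserving under smoothing, order-invariant", {
  set.seed(3)
  sc <- matrix(rnorm(800), ncol = 2)
  g <- make_grid(sc, F = 25L, smoothing_sd = 2)
  h <- histogram_sample(sc, g)
  expect_equal(sum(h$values), 1, tolerance = 1e-12)
  expect_true(all(h$values >= 0))
  # smoothing operator conserves mass exactly (reflecting boundaries)
  expect_equal(colSums(g$smoother), rep(1, 25L), tolerance = 1e-12)
  # permutation of cells leaves the histogram unchanged
  h2 <- histogram_sample(sc[sample(nrow(sc)), ], g)
  expect_equal(h$values, h2$values, tolerance = 1e-14)
  # all cells in one interior bin without smoothing -> single bin = 1
  g0 <- make_grid(sc, F = 25L, smoothing_sd = 0)
  one <- histogram_sample(matrix(c(0.01, 0.01), 1), g0)
  expect_equal(sum(one$values == 1), 1L)
  expect_equal(sum(one$values), 1)
  # out-of-range cells are clipped into edge bins, not dropped
  far <- histogram_sample(matrix(c(99, 99, -99, -99), 2, byrow = TRUE), g0)
  expect_equal(sum(far$values), 1, tolerance = 1e-12)
  expect_equal(far$values[25L, 25L], 0.5)
  expect_equal(far$values[1L, 1L], 0.5)
  expect_error(histogram_sample(matrix(numeric(0), 0, 2), g0),
               class = "cytofuse_zero_cell")
})

test_that("fusion concatenates unfolded blocks to an I x F^2*M matrix", {
  set.seed(4)
  hists <- list()
  for (s in paste0("s", 1:3)) {
    for (a in c("P1", "P2")) {
      g <- make_grid(matrix(rnorm(100), ncol = 2), F = 10L, smoothing_sd = 0)
      hists[[length(hists) + 1L]] <-
        histogram_sample(matrix(rnorm(60), ncol = 2), g, s, a)
    }
  }
  fused <- fuse_histograms(hists)
  expect_equal(dim(fused$H), c(3L, 200L))
  expect_equal(fused$block_index$P1, 1:100)
  expect_equal(fused$block_index$P2, 101:200)
  # block sums are 1 per row before centring
  expect_equal(rowSums(fused$H[, 1:100]), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(fused$H[, 101:200]), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # single aliquot reduces to the original single-panel design
  f1 <- fuse_histograms(hists[vapply(hists, `[[`, "", "aliquot_id") == "P1"])
  expect_equal(dim(f1$H), c(3L, 100L))
  # missing (sample, aliquot) pair
  expect_error(fuse_histograms(hists[-1L]),
               class = "cytofuse_incomplete_design")
})

test_that("unfold and refold are mutually inverse and row-major", {
  set.seed(5)
  X <- matrix(rnorm(49), 7, 7)
  expect_equal(cytofuse:::refold_histogram(cytofuse:::unfold_histogram(X), 7L), X)
  # row-major: bin (f1, f2) lands at position (f1-1)*F + f2
  expect_equal(cytofuse:::unfold_histogram(X)[(3 - 1) * 7 + 5], X[3, 5])
})

test_that("fused-matrix centring uses training rows only", {
  set.seed(6)
  H <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  H[, 5] <- 2  # constant column
  ctr <- centre_fused(H, paste0("s", 1:5))
  expect_equal(colMeans(ctr$H_centred[1:5, ]), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ctr$column_means, colMeans(H[1:5, ]))
  # test rows are centred with the training means, not their own
  expect_equal(ctr$H_centred[6, ], H[6, ] - colMeans(H[1:5, ]))
  expect_true(all(ctr$H_centred[, 5] == 0))
})
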