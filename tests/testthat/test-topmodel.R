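# Independent single-component PLS-DA oracle (NIPALS closed form):
# w = X'y / ||X'y||, t = X w, prediction q = y't / t't.
pls1_oracle_predict <- function(X, y, Xnew) {
  yc <- y - mean(y)
  w <- as.vector(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  t <- as.vector(X %*% w)
  q <- sum(yc * t) / sum(t^2)
  as.vector(Xnew %*% w) * q + mean(y)
}

random_problem <- function(seed, n = 20L, p = 200L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(-1, 1), length.out = n)
  X[, 1:5] <- X[, 1:5] + 0.5 * y
  X <- sweep(X, 2L, colMeans(X))
  list(X = X, y = y)
}

test_that("K_ortho = 0 reproduces one-component PLS-DA exactly", {
  for (s in 1:10) {
    pr <- random_problem(s)
    m <- fit_oplsda(pr$X, pr$y, K_ortho = 0L)
    expect_equal(unname(m$fitted), pls1_oracle_predict(pr$X, pr$y, pr$X),
                 tolerance = 1e-10)
    expect_equal(sqrt(sum(m$w_top^2)), 1, tolerance = 1e-10)
  }
})

test_that("predictive scores are orthogonal to every orthogonal component", {
  for (s in 1:5) {
    pr <- random_problem(s + 20)
    m <- fit_oplsda(pr$X, pr$y, K_ortho = 3L)
    for (k in 1:3) {
      to <- m$ortho_scores[, k]
      expect_lt(abs(sum(m$scores * to)),
                1e-8 * sqrt(sum(m$scores^2)) * sqrt(sum(to^2)))
    }
    # training predictions are reproduced by predict()
    expect_equal(unname(predict(m, pr$X)), unname(m$fitted), tolerance = 1e-10)
  }
})

test_that("a single informative column is found and separates perfectly", {
  set.seed(7)
  n <- 16L
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(0, n, 10L)
  X[, 4L] <- y  # y exactly linear in column 4
  X[, -4L] <- matrix(rnorm(n * 9L), n) * 1e-6
  X <- sweep(X, 2L, colMeans(X))
  m <- fit_oplsda(X, y, K_ortho = 0L)
  expect_gt(abs(m$w_top[4L]), 0.999)
  # least-squares oracle on the informative column: fitted = y exactly
  expect_equal(unname(m$fitted), unname(stats::lm.fit(cbind(X[, 4L]), y)$fitted.values),
               tolerance = 1e-6)
  expect_true(all(sign(m$fitted) == sign(y)))
})

test_that("degenerate inputs are rejected", {
  pr <- random_problem(1)
  expect_error(fit_oplsda(pr$X, rep(1, 20)), class = "cytofuse_config_error")
  # K_ortho beyond the orthogonal rank
  X <- matrix(rnorm(8), 4, 2)
  X <- sweep(X, 2, colMeans(X))
  y <- c(-1, -1, 1, 1)
  expect_error(fit_oplsda(X, y, K_ortho = 3L), class = "cytofuse_rank_error")
})

test_that("dual-coordinate LOO selection matches a brute-force primal LOO", {
  primal_loo_errs <- function(X, y, K_max) {
    n <- nrow(X)
    errs <- matrix(NA, n, K_max + 1L)
    for (i in seq_len(n)) {
      Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
      mu <- colMeans(Xtr)
      Xc <- sweep(Xtr, 2L, mu); xte <- X[i, ] - mu
      yc <- ytr - mean(ytr)
      w <- as.vector(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
      Xd <- Xc; xd <- xte
      for (k in 0:K_max) {
        if (k > 0L) {
          t <- as.vector(Xd %*% w)
          p <- as.vector(crossprod(Xd, t)) / sum(t^2)
          wo <- p - sum(w * p) * w
          nwo <- sqrt(sum(wo^2))
          if (nwo < 1e-10 * max(sqrt(sum(p^2)), 1e-300)) {
            errs[i, (k + 1L):(K_max + 1L)] <- errs[i, k]
            break
          }
          wo <- wo / nwo
          to <- as.vector(Xd %*% wo)
          po <- as.vector(crossprod(Xd, to)) / sum(to^2)
          Xd <- Xd - tcrossprod(to, po)
          xd <- xd - sum(xd * wo) * po
        }
        t <- as.vector(Xd %*% w)
        b <- sum(yc * t) / sum(t^2)
        f <- t * b + mean(ytr)
        thr <- (mean(f[ytr > 0]) + mean(f[ytr < 0])) / 2
        yh <- sum(xd * w) * b + mean(ytr)
        errs[i, k + 1L] <- as.integer((yh > thr) != (y[i] > 0))
      }
    }
    colSums(errs)
  }
  for (s in 1:6) {
    pr <- random_problem(s + 50, n = 14L, p = 30L)
    errs <- primal_loo_errs(pr$X, pr$y, 3L)
    expect_identical(select_K_ortho(pr$X, pr$y, K_max = 3L),
                     as.integer(which.min(errs) - 1L))
  }
})

test_that("LOO selection returns K = 0 without orthogonal structure and respects K_max", {
  set.seed(12)
  n <- 20L
  y <- rep(c(-1, 1), each = n / 2)
  X <- outer(y, rep(1, 30)) + matrix(rnorm(n * 30, sd = 0.1), n)
  expect_identical(select_K_ortho(X, y, K_max = 3L), 0L)
  for (s in 1:5) {
    pr <- random_problem(s + 70, n = 12L, p = 25L)
    expect_lte(select_K_ortho(pr$X, pr$y, K_max = 2L), 2L)
  }
})

test_that("VIP follows its closed form and sums of squares equal F*", {
  stub <- function(w) structure(list(w_top = w), class = "oplsda_model")
  # uniform unit-norm weights -> VIP exactly 1 everywhere
  v <- compute_vip(stub(rep(1 / sqrt(50), 50)))
  expect_equal(v$vip, rep(1, 50), tolerance = 1e-12)
  # concentrated weight: w = (1,0,0,0) -> VIP = (2,0,0,0)
  v2 <- compute_vip(stub(c(1, 0, 0, 0)))
  expect_equal(v2$vip, c(2, 0, 0, 0))
  expect_equal(v2$mask, c(TRUE, FALSE, FALSE, FALSE))
  # sum VIP^2 = F* for random unit-norm vectors
  set.seed(13)
  for (i in 1:10) {
    w <- rnorm(123); w <- w / sqrt(sum(w^2))
    expect_equal(sum(compute_vip(stub(w))$vip^2), 123, tolerance = 1e-8)
  }
  # degenerate all-zero weights
  expect_equal(compute_vip(stub(rep(0, 4)))$vip, rep(0, 4))
})

test_that("the VIP filter zeroes exactly the sub-threshold weights", {
  pr <- random_problem(31)
  m <- fit_oplsda(pr$X, pr$y, K_ortho = 1L)
  vip <- compute_vip(m)
  mf <- apply_vip_filter(m, vip)
  expect_true(all(mf$w_top[!vip$mask] == 0))
  expect_true(all(mf$w_top[vip$mask] != 0))
  expect_equal(sqrt(sum(mf$w_top^2)), 1, tolerance = 1e-10)
  # retained weights keep their relative proportions (zeroing, no refit)
  keep <- vip$mask
  expect_equal(mf$w_top[keep],
               m$w_top[keep] / sqrt(sum(m$w_top[keep]^2)), tolerance = 1e-12)
  # an all-pass filter leaves the model unchanged
  m0 <- fit_oplsda(pr$X, pr$y, K_ortho = 0L)
  expect_warning(unf <- apply_vip_filter(m0, threshold = 1e9))
  expect_equal(unf$w_top, m0$w_top)
})

test_that("classification uses the midpoint threshold and is monotone", {
  set.seed(14)
  X <- rbind(matrix(rnorm(50, -1, 0.2), 10), matrix(rnorm(50, 1, 0.2), 10))
  X <- sweep(X, 2L, colMeans(X))
  y <- rep(c(-1, 1), each = 10)
  m <- fit_oplsda(X, y, K_ortho = 0L)
  # symmetric training scores -> threshold ~0; mean row -> score 0
  expect_equal(m$threshold, 0, tolerance = 1e-10)
  expect_equal(unname(predict(m, matrix(0, 1, 5))), 0, tolerance = 1e-12)
  lab <- classify_scores(c(-0.5, 0.5), m)
  expect_identical(unname(lab), c("-1", "1"))
  # raising a score never flips positive -> negative
  sc <- seq(-1, 1, length.out = 21)
  pos <- classify_scores(sc, m) == m$y_coding[["positive"]]
  expect_true(all(diff(pos) >= 0))
  # a score at a class's training mean is assigned that class
  mu_pos <- mean(m$fitted[y > 0])
  expect_identical(unname(classify_scores(mu_pos, m)), "1")
})

test_that("weight refolding inverts fusion indexing", {
  set.seed(15)
  F <- 6L; M <- 3L
  w <- rnorm(F * F * M)
  W <- refold_weights(w, F, M, aliquot_ids = c("a", "b", "c"))
  expect_equal(dim(W), c(F, F, M))
  # weight for bin (f1, f2) of aliquot m sits at block start + row-major offset
  for (m in 1:M) {
    for (probe in list(c(2L, 5L), c(6L, 1L))) {
      f1 <- probe[1L]; f2 <- probe[2L]
      expect_equal(unname(W[f1, f2, m]),
                   w[(m - 1L) * F * F + (f1 - 1L) * F + f2])
    }
  }
  # M = 1 reduces to a single map
  W1 <- refold_weights(w[1:(F * F)], F, 1L)
  expect_equal(dim(W1), c(F, F, 1L))
  expect_error(refold_weights(w, F, 2L), class = "cytofuse_config_error")
})

test_that("a cell landing in a positively weighted bin raises the score", {
  pr <- random_problem(33)
  m <- fit_oplsda(pr$X, pr$y, K_ortho = 0L)
  F <- 10L; M <- 2L
  W <- refold_weights(m$w_top, F, M)
  base_row <- matrix(0, 1, 200)
  y0 <- predict(m, base_row)
  eps <- 1e-3
  set.seed(16)
  for (j in sample(200, 20)) {
    pert <- base_row
    pert[1, j] <- eps
    dy <- predict(m, pert) - y0
    m_idx <- (j - 1L) %/% (F * F) + 1L
    off <- (j - 1L) %% (F * F)
    f1 <- off %/% F + 1L
    f2 <- off %% F + 1L
    expect_equal(sign(dy), sign(W[f1, f2, m_idx] * m$b))
  }
})
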