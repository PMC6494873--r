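test_that("arcsinh transform matches its closed form and is odd and monotone", {
  fr <- frame_from(matrix(c(0, 150, -150, 300, 75, 1500), ncol = 2),
                   state = "raw")
  out <- arcsinh_transform(fr, cofactor = 150)
  expect_identical(out$transform_state, "arcsinh")
  expect_equal(unname(out$events[1L, 1L]), 0)
  expect_equal(unname(out$events[2L, 1L]), log(1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(out$events[3L, 1L]), -asinh(1), tolerance = 1e-12)  # odd
  x <- sort(stats::runif(50, -500, 5000))
  y <- asinh(x / 150)
  expect_true(all(diff(y) > 0))  # strictly monotone
  # round trip
  expect_equal(sinh(out$events) * 150, fr$events, tolerance = 1e-12)
})

test_that("arcsinh transform validates inputs", {
  fr <- frame_from(matrix(1:4, 2), state = "raw")
  expect_error(arcsinh_transform(fr, cofactor = 0),
               class = "cytofuse_config_error")
  done <- arcsinh_transform(fr, 150)
  expect_error(arcsinh_transform(done, 150), class = "cytofuse_state_error")
})

test_that("cohort scaler computes pooled reference medians and SDs", {
  f1 <- frame_from(cbind(c(1, 2), c(5, 5.5)), sample = "s1")
  f2 <- frame_from(cbind(3, 6), sample = "s2")
  sc <- fit_cohort_scaler(list(f1, f2))
  expect_equal(unname(sc$median), c(2, 5.5))
  expect_equal(unname(sc$sd), c(stats::sd(1:3), stats::sd(c(5, 5.5, 6))))
})

test_that("zero-variance reference markers raise a named error", {
  f <- frame_from(cbind(c(1, 2, 3), c(7, 7, 7)), markers = c("CD16", "CD62L"))
  err <- tryCatch(fit_cohort_scaler(list(f)), error = identity)
  expect_s3_class(err, "cytofuse_degenerate_marker")
  expect_match(conditionMessage(err), "CD62L")
})

test_that("scaling centres the median, inverts exactly, and is identity for unit stats", {
  set.seed(5)
  f <- frame_from(matrix(rnorm(40, 3, 2), ncol = 2))
  sc <- fit_cohort_scaler(list(f))
  out <- apply_scaler(f, sc)
  expect_identical(out$transform_state, "scaled")
  expect_equal(apply(out$events, 2L, stats::median), c(m1 = 0, m2 = 0),
               tolerance = 1e-12)
  # round trip
  back <- sweep(sweep(out$events, 2L, sc$sd, "*"), 2L, sc$median, "+")
  expect_equal(back, f$events, tolerance = 1e-12)
  # identity scaler
  id <- list(median = c(m1 = 0, m2 = 0), sd = c(m1 = 1, m2 = 1),
             marker_names = c("m1", "m2"))
  expect_equal(apply_scaler(f, id)$events, f$events)
  # frame equal to the medians everywhere -> all zeros
  fm <- frame_from(matrix(rep(sc$median, each = 3), ncol = 2))
  expect_true(all(apply_scaler(fm, sc)$events == 0))
})

test_that("cohort scaler depends only on reference-class training cells", {
  ds <- tiny_study(seed = 6L)
  train <- ds$samples[1:6]
  sc1 <- scale_study(ds, reference_class = "control",
                     training_samples = train)$scalers
  # corrupt every non-training frame; the scaler must not change
  ds2 <- ds
  for (key in names(ds2$frames)) {
    fr <- ds2$frames[[key]]
    if (!fr$sample_id %in% train) {
      fr$events <- fr$events * 100 + 7
      ds2$frames[[key]] <- fr
    }
  }
  sc2 <- scale_study(ds2, reference_class = "control",
                     training_samples = train)$scalers
  expect_identical(sc1, sc2)
})

test_that("paired scaling pools an individual's measurements and is local", {
  set.seed(8)
  pre <- frame_from(matrix(rnorm(60, 1), ncol = 2), sample = "pre")
  post <- frame_from(matrix(rnorm(60, 2), ncol = 2), sample = "post")
  out <- paired_individual_scaler(list(pre, post))
  pooled <- rbind(out[[1L]]$events, out[[2L]]$events)
  expect_equal(apply(pooled, 2L, stats::median), c(m1 = 0, m2 = 0),
               tolerance = 1e-12)
  # identical pre and post frames scale to identical outputs
  pre2 <- pre; post2 <- pre; post2$sample_id <- "post"
  out2 <- paired_individual_scaler(list(pre2, post2))
  expect_equal(out2[[1L]]$events, out2[[2L]]$events)
  # single condition -> pairing error
  expect_error(paired_individual_scaler(list(pre)),
               class = "cytofuse_pairing_error")
})

test_that("gates subset rows per predicate and preserve order", {
  ev <- cbind(CD3 = c(1, 3, 2, 5, 0.5, 4, 2.5, 1.5, 3.5, 0.1),
              CD19 = seq(0.1, 1, by = 0.1))
  fr <- frame_from(ev, markers = c("CD3", "CD19"))
  g <- gate(fr, "CD3 > 2.6")
  expect_equal(nrow(g$events), 4L)
  expect_equal(unname(g$events[, "CD3"]), c(3, 5, 4, 3.5))  # order preserved
  # always-true predicate is the identity
  expect_equal(gate(fr, "CD3 > -100")$events, fr$events)
  # conjunction equals sequential gating
  both <- gate(fr, "CD3 > 2.6 & CD19 < 0.65")
  seqg <- gate(gate(fr, "CD3 > 2.6"), "CD19 < 0.65")
  expect_equal(both$events, seqg$events)
})

test_that("gate errors: empty result, unknown marker, disallowed syntax", {
  fr <- frame_from(cbind(CD3 = c(1, 2)), markers = "CD3")
  expect_error(gate(fr, "CD3 > 99"), class = "cytofuse_zero_cell")
  expect_error(gate(fr, "CD8 > 1"), class = "cytofuse_gate_error")
  expect_error(gate_expression("system('ls')"), class = "cytofuse_gate_error")
  expect_error(gate_expression("CD3 == 1"), class = "cytofuse_gate_error")
})

test_that("gating commutes with the arcsinh transform", {
  set.seed(11)
  raw <- frame_from(matrix(stats::runif(100, 0, 2000), ncol = 2),
                    markers = c("CD3", "CD19"), state = "raw")
  thr_raw <- 600
  thr_t <- asinh(thr_raw / 150)
  a <- arcsinh_transform(gate(raw, sprintf("CD3 > %f", thr_raw)), 150)
  b <- gate(arcsinh_transform(raw, 150), sprintf("CD3 > %.15f", thr_t))
  expect_equal(a$events, b$events, tolerance = 1e-12)
})
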