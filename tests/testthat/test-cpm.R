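test_that("edge vectorization is row-wise upper-triangle with diagonal and invertible", {
  m3 <- matrix(c(1, 2, 3, 2, 4, 5, 3, 5, 6), 3, 3)
  v3 <- vectorize_edges(m3)
  expect_length(v3, 6)                       # (9 + 3) / 2
  expect_equal(as.vector(v3), c(1, 2, 3, 4, 5, 6))   # row-wise order
  imap <- attr(v3, "index_map")
  expect_equal(imap[2, ], c(x = 1, y = 2))
  expect_equal(unflatten_edges(v3), m3)

  # V = 268 gives the standard feature length
  expect_equal((268^2 + 268) / 2, 36046)
  set.seed(2)
  m <- matrix(rnorm(25), 5, 5); m <- (m + t(m)) / 2
  expect_equal(unflatten_edges(vectorize_edges(m)), m)
  expect_error(vectorize_edges(matrix(rnorm(9), 3, 3)), "symmetric")
})

test_that("CPM edge screening keeps planted signal and controls false positives", {
  set.seed(12)
  n <- 200; e <- 400
  feats <- matrix(rnorm(n * e), n, e)
  y <- 0.9 * feats[, 7] + rnorm(n, 0, sqrt(1 - 0.81))
  model <- cpm_train(feats, y, p_threshold = 0.001)
  expect_true(7 %in% model$positive_edges)

  # null outcome: expected false positives ~ E * alpha = 1
  set.seed(13)
  counts <- vapply(1:5, function(i) {
    y0 <- rnorm(n)
    m0 <- cpm_train(matrix(rnorm(n * 1000), n, 1000), y0, p_threshold = 0.001)
    length(m0$positive_edges) + length(m0$negative_edges)
  }, 0)
  expect_lt(mean(counts), 5)

  # threshold 1 selects every varying edge
  m_all <- cpm_train(feats[, 1:50], y, p_threshold = 1)
  expect_equal(length(m_all$positive_edges) + length(m_all$negative_edges), 50)

  # constant features dropped with a warning
  feats_const <- cbind(feats[, 1:20], 5)
  expect_warning(cpm_train(feats_const, y, p_threshold = 0.5), "constant")
})

test_that("CPM prediction applies strengths and the linear fit deterministically", {
  # hand-computed two-subject check: one positive edge (col 1), one negative
  # (col 2); training fit y = b0 + b1 * pos + b2 * neg
  set.seed(14)
  n <- 30
  feats <- matrix(rnorm(n * 3), n, 3)
  y <- 2 * feats[, 1] - 1.5 * feats[, 2] + rnorm(n, 0, 0.05)
  model <- cpm_train(feats, y, p_threshold = 0.001)
  expect_equal(model$positive_edges, 1L)
  expect_equal(model$negative_edges, 2L)
  new <- rbind(c(1, 0.5, 0), c(-0.3, 2, 1))
  cf <- model$coefficients
  expect_equal(predict(model, new),
               c(cf["intercept"] + cf["positive"] * 1 + cf["negative"] * 0.5,
                 cf["intercept"] + cf["positive"] * -0.3 + cf["negative"] * 2),
               ignore_attr = TRUE)
  # training predictions positively related to y by construction
  expect_gte(cor(predict(model, feats), y), 0)
  expect_error(predict(model, new[, 1:2]), "mismatch")

  # no surviving edges: constant prediction at the training mean, flagged
  set.seed(15)
  y0 <- rnorm(n)
  m0 <- cpm_train(matrix(rnorm(n * 20), n, 20), y0, p_threshold = 1e-9)
  expect_true(m0$flag)
  expect_equal(predict(m0, matrix(rnorm(40), 2, 20)), rep(mean(y0), 2))
})

test_that("ridge baseline shrinks to the training mean and finds planted signal", {
  set.seed(16)
  n <- 80; e <- 30
  feats <- matrix(rnorm(n * e), n, e)
  beta <- c(rep(0.6, 5), rep(0, e - 5))
  y <- as.vector(feats %*% beta) + rnorm(n, 0, 1)
  tr <- 1:60; te <- 61:80

  # huge penalty: predictions collapse to (near) the training mean
  big <- ridge_baseline(feats[tr, ], y[tr], feats[te, ],
                        lambda = c(1e7, 1e6), seed = 2)
  expect_lt(max(abs(big$predictions - mean(y[tr]))), 0.05)

  # cross-validated penalty recovers held-out signal
  fit <- ridge_baseline(feats[tr, ], y[tr], feats[te, ], seed = 2)
  expect_gt(cor(fit$predictions, y[te]), 0.3)

  expect_error(ridge_baseline(matrix(1, 20, 3), rnorm(20),
                              matrix(1, 2, 3)), "degenerate")
})

test_that("cpm_crossval produces the long accuracy table on shared splits", {
  dat <- tiny_dataset(seed = 18, V = 10, N = 60, P = 2, cross_cov = 0.3,
                      biomarker_nodes = 1:5)
  acc <- cpm_crossval(dat$connectomes, dat$behavior, n_repeats = 2,
                      p_threshold = 0.05, seed = 5, category = "Cat")
  expect_equal(nrow(acc), 4)
  expect_named(acc, c("condition", "category", "indicator", "repeat_index",
                      "accuracy"), ignore.order = TRUE)
  acc2 <- cpm_crossval(dat$connectomes, dat$behavior, n_repeats = 2,
                       p_threshold = 0.05, seed = 5, category = "Cat")
  expect_identical(acc, acc2)
})

test_that("selected CPM edges export as node-pair edge lists", {
  dat <- tiny_dataset(seed = 33, V = 8, N = 50, P = 1, cross_cov = 0.35,
                      biomarker_nodes = 1:4)
  feats <- edge_features(dat$connectomes)
  y <- behavior_matrix(dat$behavior)[, 1]
  model <- suppressWarnings(cpm_train(feats, y, p_threshold = 0.2))
  edges <- tidy(model)
  expect_true(all(c("node_x", "node_y", "sign") %in% names(edges)))
  expect_equal(nrow(edges),
               length(model$positive_edges) + length(model$negative_edges))
  expect_true(all(edges$node_x <= edges$node_y))
})
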