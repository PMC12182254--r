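test_that("train/test splits have the stated sizes and are reproducible", {
  ids190 <- sprintf("P%03d", 1:190)
  plan <- make_split(ids190, fraction = 0.9, seed = 3)
  expect_length(plan$train_ids, 171)
  expect_length(plan$test_ids, 19)
  expect_length(intersect(plan$train_ids, plan$test_ids), 0)
  expect_setequal(c(plan$train_ids, plan$test_ids), ids190)

  plan10 <- make_split(sprintf("P%02d", 1:10), fraction = 0.9, seed = 1)
  expect_length(plan10$train_ids, 9)

  expect_identical(make_split(ids190, seed = 7), make_split(ids190, seed = 7))
  expect_error(make_split(ids190, fraction = 1.2), "between 0 and 1")
  expect_error(make_split(sprintf("P%d", 1:5)), "at least 10")
})

test_that("accuracy is the sample correlation with an undefined-value flag", {
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_equal(accuracy(1:5, -(1:5)), -1)
  # hand computation: cor((1,2,3,4), (2,1,4,3)) = 0.6
  expect_equal(accuracy(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(accuracy(rep(1, 5), 1:5)))
  expect_true(is.na(accuracy(1:2, 2:1)))
  # invariant under positive affine rescaling of predictions
  set.seed(9)
  p <- rnorm(20); o <- rnorm(20)
  expect_equal(accuracy(3 * p + 7, o), accuracy(p, o))
})

test_that("restart selection maximizes the criterion with first-index ties", {
  expect_equal(select_best_init(list("a"), 0.3), 1)
  expect_equal(select_best_init(list("a", "b", "c"), c(0.2, 0.5, 0.5)), 2)
  expect_error(select_best_init(list(), numeric(0)), "no fits")
})

test_that("transductive prediction approaches the ceiling in the small-noise regime", {
  des <- simulation_design(V = 20, N = 200, P = 2, biomarker_nodes = 1:10,
                           cross_cov = 0.3, tau2 = 0.02, sigma2 = 0.02,
                           seed = 31)
  # near-deterministic regime: ceiling close to 1
  ceiling <- theoretical_ceiling(des)
  expect_gt(ceiling, 0.9)
  dat <- simulate_dataset(des)
  accs <- vapply(1:2, function(r) {
    plan <- make_split(dat$connectomes$subject_ids, seed = 31 + r)
    fp <- fit_predict(dat$connectomes, dat$behavior, plan,
                      fast_config(seed = 40 + r, n_burn = 300, n_samples = 500))
    mean(fp$accuracy$accuracy)
  }, 0)
  # 20-subject test sets: allow small-sample noise around the ceiling
  expect_gt(mean(accs), ceiling - 0.1)
  # fixed seed: identical predictions
  plan <- make_split(dat$connectomes$subject_ids, seed = 32)
  cfg <- fast_config(seed = 33, n_burn = 100, n_samples = 150)
  fp1 <- fit_predict(dat$connectomes, dat$behavior, plan, cfg)
  fp2 <- fit_predict(dat$connectomes, dat$behavior, plan, cfg)
  expect_identical(fp1$predictions$predicted, fp2$predictions$predicted)
})

test_that("prediction is transductive: test connectomes matter, masked behavior reproduces the protocol", {
  dat <- tiny_dataset(seed = 41, V = 8, N = 40, cross_cov = 0.4,
                      biomarker_nodes = 1:4)
  plan <- make_split(dat$connectomes$subject_ids, seed = 42)
  cfg <- fast_config(seed = 43, n_burn = 150, n_samples = 250)
  fp <- fit_predict(dat$connectomes, dat$behavior, plan, cfg)
  # masked behavior: fitting on the pre-masked table gives the same result
  masked <- mask_behavior(dat$behavior, plan$test_ids)
  fit_direct <- run_mcmc(dat$connectomes, masked, cfg)
  test_rows <- dat$connectomes$subject_ids %in% plan$test_ids
  expect_equal(
    fp$predictions$predicted[fp$predictions$role == "test" &
                               fp$predictions$indicator == "ind01"],
    unname(fit_direct$kappa_mean[test_rows] + fit_direct$e_mean[1]))
  # replacing the test subjects' connectomes changes predictions
  perturbed <- dat$connectomes
  scramble <- dat$connectomes$values[test_rows, , , drop = FALSE]
  perturbed$values[test_rows, , ] <- scramble[rev(seq_len(sum(test_rows))), , ]
  fp_pert <- fit_predict(perturbed, dat$behavior, plan, cfg)
  expect_false(isTRUE(all.equal(
    fp$predictions$predicted[fp$predictions$role == "test"],
    fp_pert$predictions$predicted[fp_pert$predictions$role == "test"])))
})

test_that("accuracies are centred at zero when the generating cross-covariance is zero", {
  des <- simulation_design(V = 8, N = 60, P = 1, biomarker_nodes = integer(0),
                           cross_cov = 0, seed = 51)
  dat <- simulate_dataset(des)
  cv <- crossval(dat$connectomes, dat$behavior, n_repeats = 5,
                 config = fast_config(seed = 52, n_burn = 100,
                                      n_samples = 200))
  accs <- cv$accuracy$accuracy
  # test sets have 6 subjects; mean over repeats within 2 SE of 0
  expect_lt(abs(mean(accs, na.rm = TRUE)), 2 / sqrt(3) / sqrt(5) * 2)
})

test_that("crossval returns the long accuracy table and is reproducible", {
  dat <- tiny_dataset(seed = 61, V = 8, N = 30, P = 2, cross_cov = 0.3)
  cfg <- fast_config(seed = 62, n_burn = 60, n_samples = 100)
  cv <- crossval(dat$connectomes, dat$behavior, n_repeats = 2, config = cfg,
                 category = "SimCat")
  expect_named(cv$accuracy, c("condition", "category", "repeat_index",
                              "indicator", "accuracy"),
               ignore.order = TRUE)
  expect_equal(nrow(cv$accuracy), 2 * 2)   # repeats x indicators
  expect_equal(unique(cv$accuracy$category), "SimCat")
  expect_equal(nrow(cv$covariances), 2 * 8)
  cv2 <- crossval(dat$connectomes, dat$behavior, n_repeats = 2, config = cfg,
                  category = "SimCat")
  expect_identical(cv$accuracy, cv2$accuracy)
})

test_that("averaging connectomes is the entrywise mean with matched subjects", {
  dat <- tiny_dataset(seed = 71, V = 6, N = 12)
  same <- average_connectomes(list(dat$connectomes, dat$connectomes))
  expect_equal(same$values, dat$connectomes$values)
  expect_equal(same$condition, "Average")

  neg <- dat$connectomes
  neg$values <- -neg$values
  zero <- average_connectomes(list(dat$connectomes, neg))
  expect_equal(max(abs(zero$values)), 0)

  other <- tiny_dataset(seed = 72, V = 6, N = 11)$connectomes
  expect_error(average_connectomes(list(dat$connectomes, other)), "share")
})
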