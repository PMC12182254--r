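test_that("build_sigma produces the planted structure and enforces SPD", {
  des <- simulation_design(V = 5, N = 10, P = 2, biomarker_nodes = c(2, 4),
                           cross_cov = 0.4, seed = 1)
  s <- build_sigma(des)
  expect_equal(dim(s), c(6, 6))
  expect_equal(s[6, ], c(0, 0.4, 0, 0.4, 0, 1))
  expect_equal(s[2, 6], 0.4)
  expect_true(all(eigen(s, only.values = TRUE)$values > 0))

  # cross_cov = 0: block diagonal
  s0 <- build_sigma(simulation_design(V = 4, N = 10, P = 1,
                                      biomarker_nodes = integer(0),
                                      cross_cov = 0, seed = 1))
  expect_equal(s0, diag(5))

  # near the SPD boundary with one biomarker still has positive eigenvalues
  des99 <- simulation_design(V = 2, N = 10, P = 1, biomarker_nodes = 1,
                             cross_cov = 0.99, seed = 1)
  expect_true(all(eigen(build_sigma(des99), only.values = TRUE)$values > 0))

  # beyond the bound: error names the feasible limit
  expect_error(
    simulation_design(V = 4, N = 10, P = 1, biomarker_nodes = 1:4,
                      cross_cov = 0.55, seed = 1),
    "sqrt\\(gamma_var")
})

test_that("simulated data obeys the generative equations in the noiseless limit", {
  des <- simulation_design(V = 6, N = 5, P = 3, biomarker_nodes = 1:2,
                           cross_cov = 0.3, tau2 = 1e-12, sigma2 = 1e-12,
                           seed = 5)
  dat <- simulate_dataset(des)
  g <- dat$truth$Gamma; d <- dat$truth$d
  for (j in 1:5) {
    m <- dat$connectomes$values[j, , ]
    mu <- d[j] + tcrossprod(g[j, ])
    off <- upper.tri(m)
    expect_equal(m[off], mu[off], tolerance = 1e-5)
  }
  b <- behavior_matrix(dat$behavior)
  expect_equal(unname(b - dat$truth$kappa),
               unname(t(replicate(5, dat$truth$e))), tolerance = 1e-5)
  # symmetric with zero diagonal
  expect_equal(dat$connectomes$values[1, , ], t(dat$connectomes$values[1, , ]))
  expect_equal(diag(dat$connectomes$values[2, , ]), rep(0, 6))
})

test_that("simulated moments match the design at large N", {
  des <- simulation_design(V = 3, N = 20000, P = 1, biomarker_nodes = 1,
                           cross_cov = 0.5, tau2 = 0.4, seed = 9)
  dat <- simulate_dataset(des)
  u <- cbind(dat$truth$Gamma, dat$truth$kappa)
  emp <- cov(u)
  mc_se <- 3 / sqrt(des$N)
  expect_lt(max(abs(emp - dat$truth$Sigma)), 3 * mc_se)

  # edge residual variance close to tau2 (pooled over N * V(V-1)/2 edges)
  resid <- vapply(seq_len(des$N), function(j) {
    m <- dat$connectomes$values[j, , ]
    mu <- dat$truth$d[j] + tcrossprod(dat$truth$Gamma[j, ])
    m[upper.tri(m)] - mu[upper.tri(m)]
  }, numeric(3))
  expect_lt(abs(var(as.vector(resid)) / des$tau2 - 1), 0.05)
})

test_that("simulation is reproducible and condition sets share behaviors", {
  des <- simulation_design(V = 5, N = 12, P = 2, seed = 3,
                           biomarker_nodes = 1:2, cross_cov = 0.2)
  expect_identical(simulate_dataset(des)$connectomes$values,
                   simulate_dataset(des)$connectomes$values)

  designs <- list(
    A = simulation_design(V = 5, N = 12, P = 2, biomarker_nodes = 1:2,
                          cross_cov = 0.3, condition = "A", seed = 1),
    B = simulation_design(V = 5, N = 12, P = 2, biomarker_nodes = 4:5,
                          cross_cov = 0.1, condition = "B", seed = 1)
  )
  multi <- simulate_conditions(designs, seed = 8)
  expect_named(multi$connectomes, c("A", "B"))
  # one shared behavior table; subject alignment across conditions
  expect_identical(multi$connectomes$A$subject_ids,
                   multi$connectomes$B$subject_ids)
  expect_equal(nrow(multi$behavior), 12)
  # per-condition latents correlate with the shared kappa as designed
  expect_error(simulate_conditions(list(
    simulation_design(V = 5, N = 12, P = 2, seed = 1),
    simulation_design(V = 5, N = 13, P = 2, seed = 1))), "share")
})

test_that("theoretical ceiling follows its closed form and is monotone in cross-covariance", {
  expect_equal(theoretical_ceiling(
    simulation_design(V = 4, N = 10, P = 1, biomarker_nodes = integer(0),
                      cross_cov = 0, seed = 1)), 0)

  # V=2, one biomarker, unit variances, sigma2 = 1: 0.6 / sqrt(2)
  des <- simulation_design(V = 2, N = 10, P = 1, biomarker_nodes = 1,
                           cross_cov = 0.6, sigma2 = 1, seed = 1)
  expect_equal(theoretical_ceiling(des), 0.6 / sqrt(2), tolerance = 1e-12)

  # explained variance equal to kappa variance, sigma2 -> 0: ceiling -> 1
  des1 <- simulation_design(V = 2, N = 10, P = 1, biomarker_nodes = 1,
                            cross_cov = 0.999, sigma2 = 1e-12, seed = 1)
  expect_equal(theoretical_ceiling(des1), 0.999, tolerance = 1e-3)

  ceilings <- vapply(seq(0, 0.55, by = 0.05), function(cc) {
    theoretical_ceiling(simulation_design(
      V = 10, N = 10, P = 1, biomarker_nodes = 1:3, cross_cov = cc, seed = 1))
  }, 0)
  expect_true(all(diff(ceilings) >= 0))
})

test_that("a dense exchangeable node block stays SPD and feeds the ceiling formula", {
  des <- simulation_design(V = 6, N = 10, P = 1, biomarker_nodes = 1:2,
                           cross_cov = 0.3, gamma_offdiag = 0.4, seed = 2)
  s <- build_sigma(des)
  expect_equal(s[1, 2], 0.4)
  expect_true(all(eigen(s, only.values = TRUE)$values > 0))
  expect_true(theoretical_ceiling(des) > 0 && theoretical_ceiling(des) < 1)
  # strongly negative exchangeable correlation is infeasible
  expect_error(simulation_design(V = 6, N = 10, P = 1, biomarker_nodes = 1,
                                 cross_cov = 0.1, gamma_offdiag = -0.5,
                                 seed = 2), "non-SPD")
})
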