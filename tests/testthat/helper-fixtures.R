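# Shared fixtures: tiny simulated datasets and fast sampler settings.

fast_config <- function(seed = 1, n_burn = 200, n_samples = 400, n_inits = 1) {
  mcmc_config(n_burn = n_burn, n_samples = n_samples, n_inits = n_inits,
              seed = seed)
}

tiny_dataset <- function(seed = 1, V = 8, N = 40, P = 2, cross_cov = 0.25,
                         biomarker_nodes = 1:3, ...) {
  simulate_dataset(simulation_design(
    V = V, N = N, P = P, biomarker_nodes = biomarker_nodes,
    cross_cov = cross_cov, seed = seed, ...))
}

# Independent brute-force edge log-likelihood: double loop over subjects
# and unordered pairs.
brute_connectivity_loglik <- function(cvals, d, Gamma, tau2) {
  total <- 0
  for (j in seq_len(dim(cvals)[1])) {
    v <- dim(cvals)[2]
    for (x in seq_len(v - 1)) {
      for (y in (x + 1):v) {
        mu <- d[j] + Gamma[j, x] * Gamma[j, y]
        total <- total + dnorm(cvals[j, x, y], mu, sqrt(tau2), log = TRUE)
      }
    }
  }
  total
}

# Independent cell-sum oracle for the behavior likelihood.
brute_behavior_loglik <- function(b, e, kappa, sigma2) {
  total <- 0
  for (j in seq_len(nrow(b))) {
    for (p in seq_len(ncol(b))) {
      if (!is.na(b[j, p])) {
        total <- total + dnorm(b[j, p], e[p] + kappa[j], sqrt(sigma2),
                               log = TRUE)
      }
    }
  }
  total
}

# Generic MVN log-density via Cholesky, independent of the package's
# implementation path.
mvn_logdens <- function(x, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}
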