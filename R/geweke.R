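#' Joint-distribution (Geweke) validity check of the Gibbs sampler
#'
#' Compares two ways of sampling from the joint distribution of
#' (parameters, latents, data): the marginal-conditional sampler draws
#' parameters and latents from the prior and data from the likelihood
#' (exact iid draws), while the successive-conditional sampler alternates
#' a data draw given the current parameters with one Gibbs sweep given the
#' fresh data. If every conditional update is correct, both produce the
#' same joint distribution, so moments of any parameter functional agree
#' up to Monte Carlo error.
#'
#' The functionals compared are `log(tau2)`, `log(sigma2)` and the latent
#' node-behavior correlation `Sigma[1, V+1] / sqrt(Sigma[1,1] *
#' Sigma[V+1, V+1])`; the variance-stabilized transforms are used because
#' the raw inverse-gamma and inverse-Wishart priors have heavy tails.
#' Standard errors for the (autocorrelated) successive chain use batch
#' means.
#'
#' @param V,N,P Problem dimensions (small, e.g. V = 4, N = 8).
#' @param n_draws Draws per sampler.
#' @param priors A [prior_spec()].
#' @param seed RNG seed.
#' @return Tibble with one row per functional: means under both samplers
#'   and the Geweke `z` statistic.
#' @export
geweke_check <- function(V = 4, N = 8, P = 2, n_draws = 5000,
                         priors = prior_spec(), seed = 1) {
  priors <- resolve_priors(priors, V)
  set.seed(seed)

  draw_prior <- function() {
    sigma <- riwish(priors$iw_df, priors$iw_scale)
    m <- stats::rnorm(V, 0, sqrt(priors$m_var))
    u <- MASS::mvrnorm(N, rep(0, V + 1), sigma)
    u <- matrix(u, nrow = N)
    list(
      state = list(Gamma = sweep(u[, seq_len(V), drop = FALSE], 2, m, `+`),
                   kappa = u[, V + 1]),
      params = list(
        d = stats::rnorm(N, 0, sqrt(priors$d_var)),
        e = stats::rnorm(P, 0, sqrt(priors$e_var)),
        m = m,
        tau2 = rinvgamma1(priors$ig_shape, priors$ig_rate),
        sigma2 = rinvgamma1(priors$ig_shape, priors$ig_rate),
        Sigma = sigma
      )
    )
  }

  draw_data <- function(state, params) {
    vals <- array(0, dim = c(N, V, V))
    ut <- upper.tri(matrix(0, V, V))
    for (j in seq_len(N)) {
      mu <- params$d[j] + tcrossprod(state$Gamma[j, ])
      m <- mu * 0
      m[ut] <- mu[ut] + stats::rnorm(sum(ut), 0, sqrt(params$tau2))
      vals[j, , ] <- m + t(m)
    }
    b <- outer(state$kappa, params$e, `+`) +
      matrix(stats::rnorm(N * P, 0, sqrt(params$sigma2)), N, P)
    colnames(b) <- sprintf("ind%02d", seq_len(P))
    list(connectomes = connectome_set(vals), behavior = b)
  }

  functionals <- function(params) {
    s <- params$Sigma
    c(log_tau2 = log(params$tau2),
      log_sigma2 = log(params$sigma2),
      cross_correlation = s[1, V + 1] / sqrt(s[1, 1] * s[V + 1, V + 1]))
  }

  # marginal-conditional: iid prior draws
  mc <- matrix(0, n_draws, 3)
  for (i in seq_len(n_draws)) {
    mc[i, ] <- functionals(draw_prior()$params)
  }

  # successive-conditional: data draw then one Gibbs sweep
  sc <- matrix(0, n_draws, 3)
  cur <- draw_prior()
  for (i in seq_len(n_draws)) {
    dat <- draw_data(cur$state, cur$params)
    sw <- gibbs_sweep(cur$state, cur$params, dat$connectomes, dat$behavior,
                      priors)
    cur <- list(state = sw$state, params = sw$params)
    sc[i, ] <- functionals(cur$params)
  }

  batch_se <- function(x, n_batches = 50) {
    bs <- floor(length(x) / n_batches)
    bm <- vapply(seq_len(n_batches), function(k) {
      mean(x[((k - 1) * bs + 1):(k * bs)])
    }, 0)
    stats::sd(bm) / sqrt(n_batches)
  }

  tibble::tibble(
    functional = c("log_tau2", "log_sigma2", "cross_correlation"),
    mean_marginal = colMeans(mc),
    mean_successive = colMeans(sc),
    z = vapply(1:3, function(k) {
      se <- sqrt(stats::sd(mc[, k])^2 / n_draws + batch_se(sc[, k])^2)
      (mean(mc[, k]) - mean(sc[, k])) / se
    }, 0)
  )
}
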