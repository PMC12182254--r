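#' Model log-likelihoods and latent prior density
#'
#' The generative model has three parts. Each unordered node pair (x < y)
#' of subject j contributes a Gaussian edge observation
#' c[x,y,j] ~ N(d[j] + gamma[x,j] * gamma[y,j], tau2): a subject intercept
#' plus the rank-1 (eigenmodel) product of the two nodes' latent positions.
#' Each observed behavior indicator contributes
#' b[j,p] ~ N(e[p] + kappa[j], sigma2), so all indicators of one category
#' load on a single latent score kappa[j]. The latent vector
#' (gamma[1..V,j], kappa[j]) is iid MVN(0, Sigma) across subjects; the last
#' row/column of Sigma couples nodes to behavior and is the node-level
#' biomarker quantity the model reports.
#'
#' @param connectomes A [connectome_set] (diagonals are ignored).
#' @param d Numeric vector of per-subject connectivity intercepts (length N).
#' @param Gamma Numeric N x V matrix of latent node positions.
#' @param tau2 Edge noise variance (> 0).
#' @return The scalar log-likelihood / log prior density.
#' @name model-density
NULL

#' @rdname model-density
#' @export
connectivity_loglik <- function(connectomes, d, Gamma, tau2) {
  stopifnot(inherits(connectomes, "connectome_set"))
  n <- n_subjects(connectomes); v <- n_nodes(connectomes)
  if (length(d) != n || !identical(dim(Gamma), c(n, v))) {
    stop("dimension mismatch between connectomes, d and Gamma")
  }
  if (!all(is.finite(d)) || !all(is.finite(Gamma))) stop("non-finite input")
  if (!is.finite(tau2) || tau2 <= 0) stop("tau2 must be a positive number")
  ut <- upper.tri(matrix(0, v, v))
  ll <- 0
  for (j in seq_len(n)) {
    mu <- d[j] + tcrossprod(Gamma[j, ])
    r <- connectomes$values[j, , ][ut] - mu[ut]
    ll <- ll + sum(stats::dnorm(r, 0, sqrt(tau2), log = TRUE))
  }
  ll
}

#' @rdname model-density
#' @param behavior Behavior tibble or numeric N x P matrix; `NA` entries are
#'   missing and contribute nothing.
#' @param e Numeric vector of per-indicator intercepts (length P).
#' @param kappa Numeric vector of latent behavior scores (length N).
#' @param sigma2 Behavior noise variance (> 0).
#' @export
behavior_loglik <- function(behavior, e, kappa, sigma2) {
  b <- if (is.matrix(behavior)) behavior else behavior_matrix(behavior)
  if (length(e) != ncol(b) || length(kappa) != nrow(b)) {
    stop("dimension mismatch between behavior, e and kappa")
  }
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be a positive number")
  mu <- outer(kappa, e, `+`)
  obs <- !is.na(b)
  if (!any(obs)) return(0)
  sum(stats::dnorm(b[obs], mu[obs], sqrt(sigma2), log = TRUE))
}

#' @rdname model-density
#' @param Sigma (V+1) x (V+1) symmetric positive-definite latent covariance.
#' @export
latent_logprior <- function(Gamma, kappa, Sigma) {
  stopifnot(is.matrix(Gamma), length(kappa) == nrow(Gamma))
  u <- cbind(Gamma, kappa)
  p <- ncol(u)
  if (!identical(dim(Sigma), c(p, p))) stop("Sigma must be (V+1) x (V+1)")
  ch <- chol_spd(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  z <- backsolve(ch, t(u), transpose = TRUE)     # ch' z = u'
  quad <- colSums(z^2)
  sum(-0.5 * (p * log(2 * pi) + logdet + quad))
}

# Cholesky with an SPD check: smallest eigenvalue must exceed
# -1e-8 * largest; a 1e-8 ridge is added before factorization.
chol_spd <- function(Sigma, tol = 1e-8) {
  if (max(abs(Sigma - t(Sigma))) > 1e-6) stop("Sigma is not symmetric")
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev))) stop("Sigma is not positive definite")
  chol((Sigma + t(Sigma)) / 2 + diag(tol, nrow(Sigma)))
}

#' Joint log posterior density (up to the prior normalizing constants)
#'
#' Sum of the connectivity and behavior log-likelihoods, the latent MVN log
#' prior, and the parameter log priors. Used for trace monitoring.
#'
#' @inheritParams connectivity_loglik
#' @inheritParams behavior_loglik
#' @param Sigma Latent covariance matrix.
#' @param priors A [prior_spec()].
#' @keywords internal
joint_logpost <- function(connectomes, behavior, d, e, Gamma, kappa,
                          tau2, sigma2, Sigma, priors,
                          m = rep(0, ncol(Gamma))) {
  connectivity_loglik(connectomes, d, Gamma, tau2) +
    behavior_loglik(behavior, e, kappa, sigma2) +
    latent_logprior(sweep(Gamma, 2, m, `-`), kappa, Sigma) +
    sum(stats::dnorm(m, 0, sqrt(priors$m_var), log = TRUE)) +
    sum(stats::dnorm(d, 0, sqrt(priors$d_var), log = TRUE)) +
    sum(stats::dnorm(e, 0, sqrt(priors$e_var), log = TRUE)) +
    dinvgamma_log(tau2, priors$ig_shape, priors$ig_rate) +
    dinvgamma_log(sigma2, priors$ig_shape, priors$ig_rate)
}

dinvgamma_log <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}
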