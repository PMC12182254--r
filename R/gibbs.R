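#' Prior specification for the joint model
#'
#' Weakly informative conjugate priors that admit a pure Gibbs sampler:
#' normal priors on the intercepts and the latent mean pattern,
#' inverse-gamma priors on the two noise variances, and an
#' inverse-Wishart prior on the latent covariance.
#'
#' @param d_var,e_var Prior variances of the connectivity and behavior
#'   intercepts (default 100).
#' @param m_var Prior variance of each entry of the latent mean pattern
#'   `m` (default 100).
#' @param ig_shape,ig_rate Inverse-gamma shape/rate shared by `tau2` and
#'   `sigma2` (default 2 and 1, prior mean 1).
#' @param iw_df Inverse-Wishart degrees of freedom; default `V + 3`
#'   (resolved when the data dimension is known), giving prior mean
#'   identity.
#' @param iw_scale Inverse-Wishart scale matrix; default identity.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(d_var = 100, e_var = 100, m_var = 100,
                       ig_shape = 2, ig_rate = 1,
                       iw_df = NULL, iw_scale = NULL) {
  structure(list(d_var = d_var, e_var = e_var, m_var = m_var,
                 ig_shape = ig_shape, ig_rate = ig_rate,
                 iw_df = iw_df, iw_scale = iw_scale),
            class = "prior_spec")
}

resolve_priors <- function(priors, v) {
  priors$iw_df <- priors$iw_df %||% (v + 3)
  priors$iw_scale <- priors$iw_scale %||% diag(v + 1)
  priors$m_var <- priors$m_var %||% 100
  priors
}

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1, shape = shape, rate = rate)

# Inverse-Wishart draw: Sigma^{-1} ~ Wishart(df, solve(scale))
riwish <- function(df, scale) {
  w <- stats::rWishart(1, df, chol2inv(chol(scale)))[, , 1]
  s <- chol2inv(chol(w))
  (s + t(s)) / 2
}

#' One blocked Gibbs sweep of the joint model
#'
#' The latent prior is `(gamma_j, kappa_j) ~ MVN((m, 0), Sigma)`: `m` is a
#' population mean pattern of latent node positions (the shared
#' connectivity backbone every subject deviates from) with a conjugate
#' normal prior. Estimating `m` rather than fixing it to zero is what
#' identifies each subject's latent sign: without it, the edge likelihood
#' (which only sees products `gamma_x gamma_y`) makes the reflection of a
#' behavior-free subject an exact posterior symmetry and transductive
#' prediction impossible.
#'
#' One sweep updates, in order: each node column of `Gamma` (exact
#' Gaussian conditional; the rank-1 edge term is bilinear), a per-subject
#' sign-flip Metropolis move on `Gamma[j, ]` (accepted by the latent
#' prior ratio; the edge likelihood is sign-invariant, so this hops
#' between a subject's sign modes, and the estimated backbone makes the
#' coherent mode the probable one), `kappa` (conditional Gaussian;
#' subjects with fully missing behavior draw from the `Gamma`-conditional
#' alone, which makes held-out prediction transductive), the intercepts
#' `d` and `e` (conjugate normal), an interweaving recentering of the
#' weakly identified `(e, kappa)` shift direction, the latent mean `m`
#' (conjugate MVN), `tau2` and `sigma2` (conjugate inverse-gamma), and
#' `Sigma` (conjugate inverse-Wishart on the centered latent rows).
#'
#' @param state List with `Gamma` (N x V) and `kappa` (length N).
#' @param params List with `d`, `e`, `m`, `tau2`, `sigma2`, `Sigma`.
#' @param connectomes A [connectome_set].
#' @param behavior Numeric N x P matrix (NA = missing) or behavior tibble.
#' @param priors A resolved [prior_spec()].
#' @return List with updated `state` and `params`.
#' @export
gibbs_sweep <- function(state, params, connectomes, behavior, priors) {
  b <- if (is.matrix(behavior)) behavior else behavior_matrix(behavior)
  cvals <- connectomes$values
  n <- dim(cvals)[1]; v <- dim(cvals)[2]
  G <- state$Gamma; kappa <- state$kappa
  d <- params$d; e <- params$e
  m <- params$m %||% rep(0, v)
  tau2 <- params$tau2; sigma2 <- params$sigma2; Sigma <- params$Sigma
  priors <- resolve_priors(priors, v)

  # flat N x (V*V) view; column of entry (x, y) is x + (y-1)*V
  cmat <- matrix(cvals, n, v * v)
  ut <- which(upper.tri(matrix(0, v, v)), arr.ind = TRUE)
  xs <- ut[, 1]; ys <- ut[, 2]
  cedges <- cmat[, xs + (ys - 1) * v, drop = FALSE]      # N x n_edges

  Omega <- tryCatch(chol2inv(chol_spd(Sigma)),
                    error = function(err) stop("Sigma block: ", conditionMessage(err)))

  obs <- !is.na(b)
  m_j <- rowSums(obs)

  ## --- Gamma, one node column at a time (vectorized over subjects)
  for (x in seq_len(v)) {
    cx <- cmat[, x + (seq_len(v) - 1) * v, drop = FALSE]
    cg <- rowSums(cx * G)                                 # sum_y c[x,y,j] g[y,j]
    sg <- rowSums(G^2) - G[, x]^2
    bx <- cg - d * (rowSums(G) - G[, x])
    w <- cbind(sweep(G, 2, m, `-`), kappa)                # centered latents
    w_omega <- w %*% Omega[, x]                           # sum_k Omega[k,x] w[k,j]
    prec <- Omega[x, x] + sg / tau2
    mu <- (bx / tau2 + Omega[x, x] * m[x] -
             (w_omega[, 1] - Omega[x, x] * w[, x])) / prec
    G[, x] <- stats::rnorm(n, mu, 1 / sqrt(prec))
  }

  ## --- per-subject sign-flip Metropolis move
  # The edge likelihood only sees products gamma_x gamma_y, so it is
  # invariant under Gamma[j, ] -> -Gamma[j, ]; the latent prior around
  # the backbone m (and the kappa coupling) is what prefers one mode.
  # Accepting the flip by the prior ratio lets subjects escape a
  # misaligned orientation.
  w <- cbind(sweep(G, 2, m, `-`), kappa)
  w_flip <- cbind(sweep(-G, 2, m, `-`), kappa)
  q_cur <- rowSums((w %*% Omega) * w)
  q_flip <- rowSums((w_flip %*% Omega) * w_flip)
  flip <- log(stats::runif(n)) < -0.5 * (q_flip - q_cur)
  G[flip, ] <- -G[flip, , drop = FALSE]

  ## --- kappa
  tcross <- as.numeric(sweep(G, 2, m, `-`) %*% Omega[seq_len(v), v + 1])
  resid_b <- sweep(b, 2, e, `-`)
  s_j <- rowSums(resid_b, na.rm = TRUE)
  prec_k <- Omega[v + 1, v + 1] + m_j / sigma2
  mu_k <- (s_j / sigma2 - tcross) / prec_k
  kappa <- stats::rnorm(n, mu_k, 1 / sqrt(prec_k))

  ## --- d (per-subject intercept)
  ne <- v * (v - 1) / 2
  sum_c <- rowSums(cedges)
  sum_gg <- 0.5 * (rowSums(G)^2 - rowSums(G^2))
  prec_d <- ne / tau2 + 1 / priors$d_var
  mu_d <- ((sum_c - sum_gg) / tau2) / prec_d
  d <- stats::rnorm(n, mu_d, 1 / sqrt(prec_d))

  ## --- e (per-indicator intercept)
  resid_k <- b - kappa
  n_p <- colSums(obs)
  s_p <- colSums(resid_k, na.rm = TRUE)
  prec_e <- n_p / sigma2 + 1 / priors$e_var
  e <- stats::rnorm(length(e), (s_p / sigma2) / prec_e, 1 / sqrt(prec_e))

  ## --- interweaving recentering of the (e, kappa) shift direction
  # The behavior likelihood only sees e_p + kappa_j, so a constant can
  # shift between the kappa mean and the intercepts almost freely under
  # the weak e prior; sampling the shift c: (kappa + c, e - c) from its
  # exact Gaussian conditional keeps that direction well mixed.
  tcross <- as.numeric(sweep(G, 2, m, `-`) %*% Omega[seq_len(v), v + 1])
  prec_c <- n * Omega[v + 1, v + 1] + length(e) / priors$e_var
  mu_c <- (sum(e) / priors$e_var -
             sum(tcross + Omega[v + 1, v + 1] * kappa)) / prec_c
  cshift <- stats::rnorm(1, mu_c, 1 / sqrt(prec_c))
  kappa <- kappa + cshift
  e <- e - cshift

  ## --- latent mean pattern m (conjugate MVN given centered structure)
  o_gg <- Omega[seq_len(v), seq_len(v)]
  o_gk <- Omega[seq_len(v), v + 1]
  prec_m <- n * o_gg + diag(1 / priors$m_var, v)
  lin_m <- o_gg %*% colSums(G) + o_gk * sum(kappa)
  ch_m <- chol(prec_m)
  mean_m <- backsolve(ch_m, backsolve(ch_m, lin_m, transpose = TRUE))
  m <- as.numeric(mean_m + backsolve(ch_m, stats::rnorm(v)))

  ## --- tau2
  resid_c <- cedges - d - G[, xs, drop = FALSE] * G[, ys, drop = FALSE]
  ssr <- sum(resid_c^2)
  tau2 <- rinvgamma1(priors$ig_shape + n * ne / 2, priors$ig_rate + ssr / 2)

  ## --- sigma2
  mu_b <- outer(kappa, e, `+`)
  ssb <- sum((b[obs] - mu_b[obs])^2)
  sigma2 <- rinvgamma1(priors$ig_shape + sum(obs) / 2, priors$ig_rate + ssb / 2)

  ## --- Sigma (inverse-Wishart on the centered latent rows)
  u <- cbind(sweep(G, 2, m, `-`), kappa)
  Sigma <- riwish(priors$iw_df + n, priors$iw_scale + crossprod(u))

  list(state = list(Gamma = G, kappa = kappa),
       params = list(d = d, e = e, m = m, tau2 = tau2, sigma2 = sigma2,
                     Sigma = Sigma),
       stats = list(ssr = ssr, ssb = ssb, n_edges_total = n * ne,
                    n_obs = sum(obs)))
}

# Chain initialization. "spectral" seeds Gamma with each subject's rank-1
# eigen fit (signs aligned across subjects) and m with the aligned mean
# pattern, which puts the chain close to the high-density region;
# "random" draws everything fresh. `spread` scales the jitter, so
# repeated spectral inits with different seeds give dispersed restarts.
init_chain <- function(n, v, p, b = NULL, spread = 1,
                       method = c("spectral", "random"), connectomes = NULL) {
  method <- match.arg(method)
  e0 <- if (is.null(b)) rep(0, p) else {
    cm <- colMeans(b, na.rm = TRUE)
    ifelse(is.finite(cm), cm, 0)
  }
  if (method == "random" || is.null(connectomes)) {
    gam <- matrix(stats::rnorm(n * v, 0, spread), n, v)
    kap <- stats::rnorm(n, 0, spread)
    d0 <- stats::rnorm(n, 0, 0.5 * spread)
    m0 <- stats::rnorm(v, 0, 0.25 * spread)
  } else {
    cvals <- connectomes$values
    gam <- matrix(0, n, v)
    d0 <- numeric(n)
    for (j in seq_len(n)) {
      mj <- cvals[j, , ]
      d0[j] <- mean(mj[upper.tri(mj)])
      eg <- eigen(mj - d0[j] * (1 - diag(v)), symmetric = TRUE)
      i1 <- which.max(abs(eg$values))
      gam[j, ] <- sqrt(abs(eg$values[i1])) * eg$vectors[, i1]
    }
    # align subject signs to the common pattern: seed with subject 1,
    # then re-align to the sample mean pattern (robust to a noisy seed)
    for (j in seq_len(n)[-1]) {
      if (sum(gam[j, ] * gam[1, ]) < 0) gam[j, ] <- -gam[j, ]
    }
    for (pass in 1:3) {
      ref <- colMeans(gam)
      sgn <- as.numeric(gam %*% ref) < 0
      if (!any(sgn)) break
      gam[sgn, ] <- -gam[sgn, , drop = FALSE]
    }
    kap <- if (is.null(b)) stats::rnorm(n, 0, spread) else {
      km <- rowMeans(sweep(b, 2, e0, `-`), na.rm = TRUE)
      ifelse(is.finite(km), km, 0)
    }
    gam <- gam + matrix(stats::rnorm(n * v, 0, 0.1 * spread), n, v)
    kap <- kap + stats::rnorm(n, 0, 0.1 * spread)
    d0 <- d0 + stats::rnorm(n, 0, 0.1 * spread)
    m0 <- colMeans(gam)
  }
  list(
    state = list(Gamma = gam, kappa = kap),
    params = list(
      d = d0,
      e = e0 + stats::rnorm(p, 0, 0.1 * spread),
      m = m0,
      tau2 = exp(stats::rnorm(1, 0, 0.25)),
      sigma2 = exp(stats::rnorm(1, 0, 0.25)),
      Sigma = diag(v + 1)
    )
  )
}
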