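#' Simulation design for synthetic connectome-behavior data
#'
#' Describes one scanning condition's generative setting. Defaults mirror
#' the planted-biomarker recovery setting used throughout the package's
#' validation: 150 subjects, 30 nodes, 4 indicators, edge and behavior
#' noise variances 0.5, and a cross-covariance of 0.3 between the latent
#' behavior score and the latent positions of 10 biomarker nodes.
#'
#' @param V Number of nodes.
#' @param N Number of subjects.
#' @param P Number of behavior indicators.
#' @param biomarker_nodes Integer indices of nodes carrying behavior signal
#'   (default: the first `min(10, V)` nodes).
#' @param cross_cov Latent covariance between each biomarker node position
#'   and the behavior score (0 for all other nodes).
#' @param gamma_var Latent position variance (Sigma diagonal for nodes).
#' @param kappa_var Latent behavior score variance.
#' @param tau2 Edge noise variance.
#' @param sigma2 Behavior noise variance.
#' @param d_spread,e_spread Standard deviations of the subject and
#'   indicator intercepts.
#' @param gamma_offdiag Common correlation among node latent deviations
#'   (default 0: diagonal node block). A nonzero value gives a dense
#'   exchangeable node-node block, useful for robustness checks.
#' @param mu_scale Standard deviation of the per-node population backbone
#'   pattern: latent positions are `gamma_j = mu + delta_j` with
#'   `mu[x] ~ N(0, mu_scale^2)` drawn once per dataset and `delta_j` the
#'   MVN deviation governed by `Sigma`. A nonzero backbone emulates the
#'   common connectivity structure shared by real subjects and is what
#'   makes subject orientation (and hence transductive prediction)
#'   identifiable; `mu_scale = 0` gives exchangeable-sign latents.
#' @param condition Condition label.
#' @param seed RNG seed.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(V = 30, N = 150, P = 4,
                              biomarker_nodes = NULL, cross_cov = 0.3,
                              gamma_var = 1, kappa_var = 1,
                              tau2 = 0.5, sigma2 = 0.5,
                              d_spread = 0.5, e_spread = 0.5,
                              mu_scale = 1, gamma_offdiag = 0,
                              condition = "Sim", seed = 1) {
  stopifnot(V >= 2, N >= 1, P >= 1, gamma_var > 0, kappa_var > 0,
            tau2 > 0, sigma2 > 0, d_spread >= 0, e_spread >= 0,
            mu_scale >= 0, abs(gamma_offdiag) < 1)
  if (is.null(biomarker_nodes)) biomarker_nodes <- seq_len(min(10, V))
  stopifnot(all(biomarker_nodes %in% seq_len(V)) || length(biomarker_nodes) == 0)
  design <- structure(
    list(V = V, N = N, P = P, biomarker_nodes = as.integer(biomarker_nodes),
         cross_cov = cross_cov, gamma_var = gamma_var, kappa_var = kappa_var,
         tau2 = tau2, sigma2 = sigma2, d_spread = d_spread,
         e_spread = e_spread, mu_scale = mu_scale,
         gamma_offdiag = gamma_offdiag,
         condition = condition, seed = as.integer(seed)),
    class = "simulation_design")
  build_sigma(design)   # validates SPD early
  design
}

#' Latent covariance matrix implied by a simulation design
#'
#' Builds the (V+1) x (V+1) latent covariance: node variances on the
#' diagonal, the behavior score variance in the last position, the
#' cross-covariance in the last row/column for biomarker nodes and 0
#' elsewhere; node-node off-diagonals are 0.
#'
#' @param design A [simulation_design()].
#' @return A symmetric positive-definite matrix.
#' @export
build_sigma <- function(design) {
  v <- design$V
  rho <- design$gamma_offdiag %||% 0
  gg <- matrix(rho * design$gamma_var, v, v)
  diag(gg) <- design$gamma_var
  sigma <- rbind(cbind(gg, rep(0, v)), c(rep(0, v), design$kappa_var))
  sigma[v + 1, design$biomarker_nodes] <- design$cross_cov
  sigma[design$biomarker_nodes, v + 1] <- design$cross_cov
  # Schur complement of the kappa entry: with a diagonal node block this
  # is SPD iff kappa_var > m * cross_cov^2 / gamma_var (m biomarker
  # nodes); the dense case is checked by eigendecomposition below
  m <- length(design$biomarker_nodes)
  if (m > 0 && rho == 0) {
    bound <- sqrt(design$gamma_var * design$kappa_var / m)
    if (abs(design$cross_cov) >= bound) {
      stop(sprintf(
        "cross_cov %.4f makes Sigma non-SPD; |cross_cov| must be below sqrt(gamma_var * kappa_var / n_biomarkers) = %.4f",
        design$cross_cov, bound))
    }
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) {
    stop("design parameters make Sigma non-SPD (smallest eigenvalue <= 0)")
  }
  sigma
}

#' Simulate a connectome-behavior dataset under the generative model
#'
#' Draws a per-node backbone pattern `mu`, latent deviations
#' `(delta_j, kappa_j)` iid MVN(0, Sigma), sets `gamma_j = mu + delta_j`,
#' draws subject and indicator intercepts, then edges
#' `c[x,y,j] = d_j + gamma_x gamma_y + N(0, tau2)` (symmetric, zero
#' diagonal) and behaviors `b[j,p] = e_p + kappa_j + N(0, sigma2)`. The
#' backbone shifts the latent mean only, so all covariances (including the
#' planted node-behavior cross-covariances) follow `Sigma` exactly.
#'
#' @param design A [simulation_design()].
#' @return List with `connectomes` ([connectome_set]), `behavior` (tibble),
#'   and `truth` (Gamma, kappa, d, e, Sigma and the design).
#' @export
simulate_dataset <- function(design) {
  sigma <- build_sigma(design)
  set.seed(design$seed)
  n <- design$N; v <- design$V; p <- design$P
  mu <- stats::rnorm(v, 0, design$mu_scale)
  u <- MASS::mvrnorm(n, rep(0, v + 1), sigma)
  u <- matrix(u, nrow = n)
  gam <- sweep(u[, seq_len(v), drop = FALSE], 2, mu, `+`)
  kappa <- u[, v + 1]
  d <- stats::rnorm(n, 0, design$d_spread)
  e <- stats::rnorm(p, 0, design$e_spread)
  vals <- array(0, dim = c(n, v, v))
  ut <- upper.tri(matrix(0, v, v))
  for (j in seq_len(n)) {
    mu <- d[j] + tcrossprod(gam[j, ])
    noise <- matrix(0, v, v)
    noise[ut] <- stats::rnorm(sum(ut), 0, sqrt(design$tau2))
    m <- mu * 0
    m[ut] <- mu[ut] + noise[ut]
    m <- m + t(m)
    vals[j, , ] <- m
  }
  b <- outer(kappa, e, `+`) + matrix(stats::rnorm(n * p, 0, sqrt(design$sigma2)), n, p)
  colnames(b) <- sprintf("ind%02d", seq_len(p))
  behavior <- tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)))
  behavior <- dplyr::bind_cols(behavior, tibble::as_tibble(b))
  list(
    connectomes = connectome_set(vals, subject_ids = behavior$subject_id,
                                 condition = design$condition),
    behavior = behavior,
    truth = list(Gamma = gam, kappa = kappa, d = d, e = e, Sigma = sigma,
                 mu = mu, design = design)
  )
}

#' Simulate several conditions sharing subjects and behaviors
#'
#' Emulates a multi-condition scanning study: a single latent behavior
#' score and behavior table shared by all conditions, with each condition's
#' latent node positions drawn from its own conditional distribution given
#' the shared score. Condition-specific cross-covariance therefore controls
#' how much behavioral signal each condition's connectomes carry.
#'
#' @param designs Named list of [simulation_design()] objects sharing
#'   `N`, `P`, `kappa_var`, `sigma2` and `e_spread`.
#' @param seed Master seed (overrides per-design seeds for the shared
#'   draws).
#' @return List with `connectomes` (named list of [connectome_set]),
#'   `behavior` (one shared tibble) and `truth`.
#' @export
simulate_conditions <- function(designs, seed = 1) {
  stopifnot(length(designs) >= 1)
  ref <- designs[[1]]
  for (dd in designs) {
    if (dd$N != ref$N || dd$P != ref$P || dd$kappa_var != ref$kappa_var ||
        dd$sigma2 != ref$sigma2) {
      stop("designs must share N, P, kappa_var and sigma2")
    }
  }
  set.seed(seed)
  n <- ref$N; p <- ref$P
  v_max <- max(vapply(designs, `[[`, 0, "V"))
  mu_all <- stats::rnorm(v_max, 0, ref$mu_scale)   # one brain backbone
  kappa <- stats::rnorm(n, 0, sqrt(ref$kappa_var))
  e <- stats::rnorm(p, 0, ref$e_spread)
  b <- outer(kappa, e, `+`) + matrix(stats::rnorm(n * p, 0, sqrt(ref$sigma2)), n, p)
  colnames(b) <- sprintf("ind%02d", seq_len(p))
  subject_ids <- sprintf("S%03d", seq_len(n))
  behavior <- dplyr::bind_cols(tibble::tibble(subject_id = subject_ids),
                               tibble::as_tibble(b))
  sets <- list(); truths <- list()
  if (is.null(names(designs))) {
    names(designs) <- vapply(designs, `[[`, "", "condition")
  }
  for (nm in names(designs)) {
    dd <- designs[[nm]]
    sigma <- build_sigma(dd)
    v <- dd$V
    s_gk <- sigma[seq_len(v), v + 1]
    mu_g <- outer(kappa / dd$kappa_var, s_gk)         # E[delta | kappa]
    cond_cov <- sigma[seq_len(v), seq_len(v)] - tcrossprod(s_gk) / dd$kappa_var
    gam <- mu_g + MASS::mvrnorm(n, rep(0, v), cond_cov)
    gam <- sweep(matrix(gam, nrow = n), 2, mu_all[seq_len(v)], `+`)
    d <- stats::rnorm(n, 0, dd$d_spread)
    vals <- array(0, dim = c(n, v, v))
    ut <- upper.tri(matrix(0, v, v))
    for (j in seq_len(n)) {
      mu <- d[j] + tcrossprod(gam[j, ])
      m <- mu * 0
      m[ut] <- mu[ut] + stats::rnorm(sum(ut), 0, sqrt(dd$tau2))
      m <- m + t(m)
      vals[j, , ] <- m
    }
    sets[[nm]] <- connectome_set(vals, subject_ids = subject_ids,
                                 condition = dd$condition)
    truths[[nm]] <- list(Gamma = gam, d = d, Sigma = sigma, design = dd)
  }
  list(connectomes = sets, behavior = behavior,
       truth = list(kappa = kappa, e = e, mu = mu_all, conditions = truths))
}

#' Theoretical prediction ceiling of a simulation design
#'
#' The maximum correlation attainable between any predictor built from the
#' latent node positions and a single behavior indicator, in the
#' noiseless-connectome limit:
#' `sqrt(S_kg %*% solve(S_gg) %*% S_gk) / sqrt(S_kk + sigma2)`,
#' where the S blocks partition the latent covariance between node
#' positions (g) and the behavior score (k).
#'
#' @param design A [simulation_design()].
#' @return A number in `[0, 1]`.
#' @export
theoretical_ceiling <- function(design) {
  sigma <- build_sigma(design)
  v <- design$V
  s_gg <- sigma[seq_len(v), seq_len(v)]
  s_gk <- sigma[seq_len(v), v + 1]
  expl <- as.numeric(crossprod(s_gk, solve(s_gg, s_gk)))
  sqrt(expl) / sqrt(sigma[v + 1, v + 1] + design$sigma2)
}
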