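#' MCMC configuration
#'
#' Defaults follow the fitting protocol used throughout the package: 5000
#' burn-in sweeps, 15,000 retained samples, 10 random initializations.
#' Test-scale runs pass much smaller values.
#'
#' @param n_burn Burn-in sweeps discarded (default 5000).
#' @param n_samples Retained (post-thinning) samples (default 15000).
#' @param thin Thinning interval (default 1).
#' @param n_inits Number of random restarts used by [fit_predict()]
#'   (default 10).
#' @param seed Integer RNG seed.
#' @param n_chains_for_rhat Number of split segments used for the
#'   split-chain potential scale reduction diagnostic (default 2).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 5000, n_samples = 15000, thin = 1,
                        n_inits = 10, seed = 1, n_chains_for_rhat = 2) {
  stopifnot(n_burn >= 0, n_samples >= 1, thin >= 1, n_inits >= 1,
            n_chains_for_rhat >= 2)
  structure(list(n_burn = as.integer(n_burn), n_samples = as.integer(n_samples),
                 thin = as.integer(thin), n_inits = as.integer(n_inits),
                 seed = as.integer(seed),
                 n_chains_for_rhat = as.integer(n_chains_for_rhat)),
            class = "mcmc_config")
}

#' Fit the joint connectome-behavior model by MCMC
#'
#' Runs the blocked Gibbs sampler ([gibbs_sweep()]): random initialization,
#' `n_burn` discarded sweeps, then `n_samples` retained sweeps (thinned).
#' The headline output is `node_covariances`, the posterior mean of
#' `Sigma[v, V+1]` for each node: the covariance between the node's latent
#' position and the latent behavior score, the model's biomarker strength.
#'
#' @param connectomes A [connectome_set].
#' @param behavior Behavior tibble (see [behavior_matrix()]); `NA` entries
#'   are treated as missing and imputed transductively.
#' @param config An [mcmc_config()].
#' @param priors A [prior_spec()].
#' @param init Optional list with `state`/`params` overriding the random
#'   initialization (the seed still governs the sweep randomness).
#' @return An object of class `latentsna_mcmc` with elements
#'   `node_covariances`, `summary` (posterior means/sds of `tau2`, `sigma2`,
#'   `d`, `e`), `rhat` (split-chain diagnostics), `traces` (retained draws
#'   of `tau2`, `sigma2`, node covariances and the joint log posterior),
#'   `kappa_mean`, `e_mean`, and the configuration.
#' @export
run_mcmc <- function(connectomes, behavior, config = mcmc_config(),
                     priors = prior_spec(), init = NULL) {
  stopifnot(inherits(connectomes, "connectome_set"))
  b <- behavior_matrix(behavior)
  check_alignment(connectomes, behavior)
  n <- n_subjects(connectomes); v <- n_nodes(connectomes); p <- ncol(b)
  priors <- resolve_priors(priors, v)

  set.seed(config$seed)
  if (is.null(init)) init <- init_chain(n, v, p, b, connectomes = connectomes)
  state <- init$state; params <- init$params

  n_keep <- config$n_samples
  tr_tau2 <- numeric(n_keep); tr_sigma2 <- numeric(n_keep)
  tr_cross <- matrix(0, n_keep, v)
  tr_lp <- numeric(n_keep)
  kappa_sum <- numeric(n); e_sum <- numeric(p)
  d_sum <- numeric(n); d_sq <- numeric(n); e_sq <- numeric(p)

  total <- config$n_burn + n_keep * config$thin
  kept <- 0
  align_ref <- NULL
  for (it in seq_len(total)) {
    sw <- gibbs_sweep(state, params, connectomes, b, priors)
    state <- sw$state; params <- sw$params
    if (!all(is.finite(c(params$tau2, params$sigma2, state$kappa)))) {
      stop("numerical overflow in sampler at iteration ", it)
    }
    if (it > config$n_burn && (it - config$n_burn) %% config$thin == 0) {
      kept <- kept + 1
      tr_tau2[kept] <- params$tau2
      tr_sigma2[kept] <- params$sigma2
      # The joint density is invariant under flipping every subject's Gamma
      # together with the sign of Sigma's cross block, so node-behavior
      # covariances are identified only up to a global sign. Retained draws
      # are aligned to the orientation of the first retained draw
      # (mixture-relabeling style) so that mode switches do not cancel in
      # the posterior mean.
      crossvec <- params$Sigma[seq_len(v), v + 1]
      if (kept == 1) {
        align_ref <- crossvec
      } else if (sum(crossvec * align_ref) < 0) {
        crossvec <- -crossvec
      }
      tr_cross[kept, ] <- crossvec
      # Gaussian likelihood terms from the sweep's residual sums, plus the
      # latent prior and parameter priors at the current draw.
      st <- sw$stats
      tr_lp[kept] <-
        -0.5 * st$n_edges_total * log(2 * pi * params$tau2) -
        st$ssr / (2 * params$tau2) -
        0.5 * st$n_obs * log(2 * pi * params$sigma2) -
        st$ssb / (2 * params$sigma2) +
        latent_logprior(sweep(state$Gamma, 2, params$m, `-`), state$kappa,
                        params$Sigma) +
        sum(stats::dnorm(params$m, 0, sqrt(priors$m_var), log = TRUE)) +
        sum(stats::dnorm(params$d, 0, sqrt(priors$d_var), log = TRUE)) +
        sum(stats::dnorm(params$e, 0, sqrt(priors$e_var), log = TRUE)) +
        dinvgamma_log(params$tau2, priors$ig_shape, priors$ig_rate) +
        dinvgamma_log(params$sigma2, priors$ig_shape, priors$ig_rate)
      kappa_sum <- kappa_sum + state$kappa
      e_sum <- e_sum + params$e
      d_sum <- d_sum + params$d
      d_sq <- d_sq + params$d^2
      e_sq <- e_sq + params$e^2
    }
  }

  # Orientation convention for the reported equivalence class: the summed
  # covariance over the highest-magnitude decile of nodes is non-negative.
  node_cov <- colMeans(tr_cross)
  lead <- order(abs(node_cov), decreasing = TRUE)[seq_len(min(10, v))]
  if (sum(node_cov[lead]) < 0) {
    tr_cross <- -tr_cross
    node_cov <- -node_cov
  }
  names(node_cov) <- as.character(connectomes$node_ids)
  rhat <- c(
    tau2 = split_rhat(tr_tau2, config$n_chains_for_rhat),
    sigma2 = split_rhat(tr_sigma2, config$n_chains_for_rhat),
    stats::setNames(apply(tr_cross, 2, split_rhat, config$n_chains_for_rhat),
                    paste0("cov_", connectomes$node_ids))
  )

  structure(list(
    node_covariances = node_cov,
    summary = list(
      tau2_mean = mean(tr_tau2), tau2_sd = stats::sd(tr_tau2),
      sigma2_mean = mean(tr_sigma2), sigma2_sd = stats::sd(tr_sigma2),
      d_mean = d_sum / kept, d_sd = sqrt(pmax(d_sq / kept - (d_sum / kept)^2, 0)),
      e_mean = e_sum / kept, e_sd = sqrt(pmax(e_sq / kept - (e_sum / kept)^2, 0))
    ),
    rhat = rhat,
    traces = list(tau2 = tr_tau2, sigma2 = tr_sigma2,
                  node_covariances = tr_cross, logpost = tr_lp),
    kappa_mean = kappa_sum / kept,
    e_mean = e_sum / kept,
    condition = connectomes$condition,
    node_ids = connectomes$node_ids,
    subject_ids = connectomes$subject_ids,
    indicator_names = colnames(b),
    config = config
  ), class = "latentsna_mcmc")
}

#' @export
print.latentsna_mcmc <- function(x, ...) {
  cat(sprintf(
    "<latentsna_mcmc> condition '%s': %d subjects, %d nodes, %d draws\n",
    x$condition, length(x$subject_ids), length(x$node_ids),
    length(x$traces$tau2)))
  cat(sprintf("  tau2 %.3f  sigma2 %.3f  mean Rhat %.3f\n",
              x$summary$tau2_mean, x$summary$sigma2_mean, mean(x$rhat)))
  invisible(x)
}

#' Tidy the node-level biomarker output of a fitted model
#'
#' @param x A `latentsna_mcmc` object.
#' @param ... Unused.
#' @return Tibble with `node_id`, `covariance` (posterior mean of the
#'   node-behavior entry of the latent covariance) and its split-chain
#'   `rhat`.
#' @export
tidy.latentsna_mcmc <- function(x, ...) {
  tibble::tibble(
    node_id = x$node_ids,
    covariance = unname(x$node_covariances),
    rhat = unname(x$rhat[paste0("cov_", x$node_ids)])
  )
}

#' @rdname tidy.latentsna_mcmc
#' @export
glance.latentsna_mcmc <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    n_subjects = length(x$subject_ids),
    n_nodes = length(x$node_ids),
    n_draws = length(x$traces$tau2),
    tau2 = x$summary$tau2_mean,
    sigma2 = x$summary$sigma2_mean,
    mean_rhat = mean(x$rhat),
    max_rhat = max(x$rhat)
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard PSRF across parallel chains of equal length. When all chains
#' are constant and equal (zero total variance) the statistic is defined
#' as 1.
#'
#' @param chains List of at least two equal-length numeric vectors
#'   (length >= 10).
#' @return The scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    stop("need at least two chains")
  }
  len <- lengths(chains)
  if (length(unique(len)) != 1 || len[1] < 10) {
    stop("chains must have equal length >= 10")
  }
  m <- length(chains); n <- len[1]
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w + b == 0) return(1)
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}

# Split-chain R-hat from a single trace: the trace is cut into k equal
# segments which are treated as chains.
split_rhat <- function(trace, k = 2) {
  n <- length(trace)
  seg <- floor(n / k)
  if (seg < 10) return(NA_real_)
  chains <- lapply(seq_len(k), function(i) trace[((i - 1) * seg + 1):(i * seg)])
  gelman_rubin(chains)
}

#' Fit the joint model with multiple restarts
#'
#' The joint posterior is multimodal: besides the exact global
#' sign-reflection mode, the sampler can settle in locally stable but
#' inferior configurations of the latent positions. The fitting protocol
#' therefore runs `config$n_inits` independent chains from jittered
#' starting points (seeds `seed`, `seed + 1`, ...) and keeps the chain with
#' the highest mean retained joint log posterior (ties broken by lower
#' chain index). Cross-chain Gelman-Rubin diagnostics are computed over
#' the restarts after aligning each chain's sign orientation to the chosen
#' chain.
#'
#' @inheritParams run_mcmc
#' @return The selected `latentsna_mcmc` fit, with extra elements
#'   `init_criteria` (mean log posterior per restart), `chosen_init`, and
#'   `cross_chain_rhat` (per-node R-hat across restarts, when
#'   `n_inits >= 2`).
#' @export
latentsna <- function(connectomes, behavior, config = mcmc_config(),
                      priors = prior_spec()) {
  k <- config$n_inits
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    fits[[i]] <- run_mcmc(connectomes, behavior, cfg_i, priors)
  }
  crit <- vapply(fits, function(f) mean(f$traces$logpost), 0)
  best_i <- which.max(crit)           # which.max takes the first of ties
  best <- fits[[best_i]]
  best$init_criteria <- crit
  best$chosen_init <- best_i
  if (k >= 2) {
    ref <- best$node_covariances
    chains <- lapply(fits, function(f) {
      s <- if (sum(f$node_covariances * ref) < 0) -1 else 1
      list(tau2 = f$traces$tau2, sigma2 = f$traces$sigma2,
           cross = s * f$traces$node_covariances)
    })
    v <- length(ref)
    cross_rhat <- vapply(seq_len(v), function(x) {
      gelman_rubin(lapply(chains, function(ch) ch$cross[, x]))
    }, 0)
    names(cross_rhat) <- names(ref)
    best$cross_chain_rhat <- c(
      tau2 = gelman_rubin(lapply(chains, `[[`, "tau2")),
      sigma2 = gelman_rubin(lapply(chains, `[[`, "sigma2")),
      cross_rhat
    )
  }
  best
}

#' Predicted behavior scores from a fitted model
#'
#' The prediction for subject j on indicator p is the posterior mean of
#' `e_p + kappa_j` over retained draws. For subjects whose behavior was
#' masked before fitting this is the transductive prediction.
#'
#' @param object A `latentsna_mcmc` fit.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `indicator`, `predicted`.
#' @export
predict.latentsna_mcmc <- function(object, ...) {
  p <- length(object$e_mean)
  tidyr::expand_grid(subject_id = object$subject_ids,
                     indicator = object$indicator_names) |>
    dplyr::mutate(predicted = rep(object$kappa_mean, each = p) +
                    rep(object$e_mean, times = length(object$subject_ids)))
}
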