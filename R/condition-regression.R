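#' Dummy regression of prediction accuracy on fMRI condition
#'
#' Ordinary least squares of per-indicator, per-repeat prediction accuracy
#' on condition indicator variables, with a chosen reference condition.
#' With dummies only, the intercept is the mean accuracy under the
#' reference and each coefficient is the difference between that
#' condition's mean accuracy and the reference mean. Observations are
#' pooled over indicators and repeats within the category.
#'
#' @param accuracy_table Long-format tibble with columns `condition`,
#'   `category`, `indicator`, `repeat_index`, `accuracy` (as produced by
#'   [crossval()] / [compare_conditions()]).
#' @param category Which behavioral category to analyse.
#' @param reference Reference condition (default `"Rest1"`).
#' @return An object of class `condition_regression`: `reference`,
#'   `beta0`, `betas` (named vector of condition contrasts), `r2`,
#'   `n_obs`, and the underlying `lm` fit.
#' @export
fit_condition_regression <- function(accuracy_table, category = NULL,
                                     reference = "Rest1") {
  tab <- tibble::as_tibble(accuracy_table)
  if (!is.null(category)) {
    if (!category %in% tab$category) stop("category not present: ", category)
    tab <- tab[tab$category == category, ]
  }
  tab <- tab[!is.na(tab$accuracy), ]
  conds <- unique(tab$condition)
  if (length(conds) < 2) stop("need at least two conditions")
  if (!reference %in% conds) stop("reference condition not present: ", reference)
  tab$condition <- stats::relevel(factor(tab$condition), ref = reference)
  fit <- stats::lm(accuracy ~ condition, data = tab)
  cf <- stats::coef(fit)
  betas <- cf[-1]
  names(betas) <- sub("^condition", "", names(betas))
  tss <- sum((tab$accuracy - mean(tab$accuracy))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(reference = reference, beta0 = unname(cf[1]),
                 betas = betas, r2 = r2, n_obs = nrow(tab),
                 category = category, lm_fit = fit),
            class = "condition_regression")
}

#' @export
print.condition_regression <- function(x, ...) {
  cat(sprintf("<condition_regression> reference '%s': beta0 %.3f, R2 %.3f (n = %d)\n",
              x$reference, x$beta0, x$r2, x$n_obs))
  print(round(x$betas, 4))
  invisible(x)
}

#' @export
tidy.condition_regression <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("(Intercept: ", x$reference, ")"), names(x$betas)),
    estimate = c(x$beta0, unname(x$betas))
  )
}

#' @export
glance.condition_regression <- function(x, ...) {
  tibble::tibble(reference = x$reference, r.squared = x$r2, nobs = x$n_obs)
}

#' Regression of absolute node covariance on functional-system labels
#'
#' OLS of |covariance| on system dummy indicators; coefficients equal
#' per-system mean differences from the reference system (the first
#' system label alphabetically). Used to check which functional systems
#' carry the strongest brain-behavior associations.
#'
#' @param node_covariances Named numeric vector of per-node covariances
#'   (names = node ids), or a tibble with `node_id` and `covariance`.
#' @param atlas Atlas tibble with `node_id` and `system` (see
#'   [synthetic_atlas()]).
#' @return An object of class `system_regression` with `reference`,
#'   `intercept` (reference system mean |covariance|), `betas`, `r2`.
#' @export
network_covariance_regression <- function(node_covariances, atlas) {
  if (is.data.frame(node_covariances)) {
    covs <- stats::setNames(node_covariances$covariance,
                            node_covariances$node_id)
  } else {
    covs <- node_covariances
    if (is.null(names(covs))) names(covs) <- seq_along(covs)
  }
  atlas <- tibble::as_tibble(atlas)
  sys <- stats::setNames(as.character(atlas$system), as.character(atlas$node_id))
  missing_nodes <- setdiff(names(covs), names(sys))
  if (length(missing_nodes) > 0) {
    stop("nodes missing from atlas: ", paste(missing_nodes, collapse = ", "))
  }
  dat <- tibble::tibble(
    abs_cov = abs(unname(covs)),
    system = factor(sys[names(covs)])
  )
  ref <- sort(levels(dat$system))[1]
  dat$system <- stats::relevel(dat$system, ref = ref)
  fit <- stats::lm(abs_cov ~ system, data = dat)
  cf <- stats::coef(fit)
  betas <- cf[-1]
  names(betas) <- sub("^system", "", names(betas))
  tss <- sum((dat$abs_cov - mean(dat$abs_cov))^2)
  structure(list(reference = ref, intercept = unname(cf[1]), betas = betas,
                 r2 = if (tss == 0) 0 else 1 - sum(stats::resid(fit)^2) / tss,
                 n_obs = nrow(dat), lm_fit = fit),
            class = "system_regression")
}

#' @export
print.system_regression <- function(x, ...) {
  cat(sprintf("<system_regression> reference '%s': mean |cov| %.4f, R2 %.3f\n",
              x$reference, x$intercept, x$r2))
  print(round(x$betas, 4))
  invisible(x)
}

#' @export
tidy.system_regression <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("(Intercept: ", x$reference, ")"), names(x$betas)),
    estimate = c(x$intercept, unname(x$betas))
  )
}
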