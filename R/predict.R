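#' Random train/test split of subjects
#'
#' Draws a split with `round(fraction * N)` training subjects (half-up
#' rounding) and the remainder as the test sample; deterministic for a
#' fixed seed.
#'
#' @param subject_ids Character vector of subject ids (N >= 10).
#' @param fraction Training fraction, in (0, 1); default 0.9.
#' @param seed RNG seed.
#' @return A list of class `split_plan` with `train_ids`, `test_ids`,
#'   `fraction`, `seed`.
#' @export
make_split <- function(subject_ids, fraction = 0.9, seed = 1) {
  subject_ids <- as.character(subject_ids)
  n <- length(subject_ids)
  if (n < 10) stop("need at least 10 subjects to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  n_train <- floor(fraction * n + 0.5)
  set.seed(seed)
  train <- sort(sample(subject_ids, n_train))
  structure(list(train_ids = train,
                 test_ids = setdiff(subject_ids, train),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$fraction, x$seed))
  invisible(x)
}

#' Prediction accuracy as a correlation
#'
#' The sample Pearson correlation between predicted and observed scores,
#' the accuracy measure used throughout the comparative pipeline. Returns
#' `NA` (the undefined-accuracy flag) when fewer than 3 pairs are complete
#' or either vector is constant; such records are excluded from averages.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return A correlation in `[-1, 1]`, or `NA`.
#' @export
accuracy <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  ok <- stats::complete.cases(predicted, observed)
  if (sum(ok) < 3) return(NA_real_)
  p <- predicted[ok]; o <- observed[ok]
  if (stats::sd(p) == 0 || stats::sd(o) == 0) return(NA_real_)
  stats::cor(p, o)
}

#' Transductive fit and prediction for one split
#'
#' Implements the prediction protocol: behavior of the test subjects is
#' masked to missing, the model is fitted to the connectomes of *all*
#' subjects together with the training subjects' behavior (transductive
#' fitting), and the masked scores are predicted by the posterior mean of
#' `e_p + kappa_j`. With `config$n_inits > 1` the fit is restarted from
#' jittered initializations and the restart with the best selection
#' criterion is kept.
#'
#' @param connectomes A [connectome_set] covering all subjects.
#' @param behavior Complete behavior tibble (test rows are masked
#'   internally).
#' @param plan A [make_split()] plan over the same subjects.
#' @param config An [mcmc_config()]; `n_inits` restarts are run with seeds
#'   `seed`, `seed + 1`, ...
#' @param priors A [prior_spec()].
#' @param selection How to score restarts: `"test"` reproduces the
#'   protocol of choosing the model by fit in the test sample (mean
#'   predictive correlation over indicators); `"logpost"` uses the mean
#'   retained joint log posterior and never touches test behavior.
#' @return An object of class `latentsna_prediction`: a list with
#'   `predictions` (tibble: subject_id, indicator, predicted, observed),
#'   `accuracy` (tibble per indicator), `fit` (the chosen
#'   `latentsna_mcmc`), `init_criteria` and `plan`.
#' @export
fit_predict <- function(connectomes, behavior, plan,
                        config = mcmc_config(), priors = prior_spec(),
                        selection = c("test", "logpost")) {
  selection <- match.arg(selection)
  check_alignment(connectomes, behavior)
  all_ids <- connectomes$subject_ids
  if (!setequal(c(plan$train_ids, plan$test_ids), all_ids)) {
    stop("split plan does not match the subjects of the data")
  }
  masked <- mask_behavior(behavior, plan$test_ids)
  b_obs <- behavior_matrix(behavior)
  test_rows <- all_ids %in% plan$test_ids

  fits <- vector("list", config$n_inits)
  crit <- numeric(config$n_inits)
  for (i in seq_len(config$n_inits)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    fits[[i]] <- run_mcmc(connectomes, masked, cfg_i, priors)
    crit[i] <- switch(selection,
      test = {
        pred <- outer(fits[[i]]$kappa_mean[test_rows], fits[[i]]$e_mean, `+`)
        accs <- vapply(seq_len(ncol(b_obs)), function(p) {
          accuracy(pred[, p], b_obs[test_rows, p])
        }, 0)
        mean(accs, na.rm = TRUE)
      },
      logpost = mean(fits[[i]]$traces$logpost)
    )
  }
  chosen <- select_best_init(fits, crit)
  fit <- fits[[chosen]]

  pred_mat <- outer(fit$kappa_mean, fit$e_mean, `+`)
  colnames(pred_mat) <- fit$indicator_names
  predictions <- tidyr::expand_grid(subject_id = all_ids,
                                    indicator = fit$indicator_names) |>
    dplyr::mutate(
      predicted = as.vector(t(pred_mat)),
      observed = as.vector(t(b_obs)),
      role = ifelse(.data$subject_id %in% plan$test_ids, "test", "train")
    )
  acc <- predictions |>
    dplyr::filter(.data$role == "test") |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(accuracy = accuracy(.data$predicted, .data$observed),
                     .groups = "drop")
  structure(list(predictions = predictions, accuracy = acc, fit = fit,
                 init_criteria = crit, chosen_init = chosen, plan = plan,
                 selection = selection),
            class = "latentsna_prediction")
}

#' @export
print.latentsna_prediction <- function(x, ...) {
  cat(sprintf("<latentsna_prediction> %d test subjects, mean accuracy %.3f\n",
              length(x$plan$test_ids), mean(x$accuracy$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Select the best restart
#'
#' Returns the index of the run maximizing the selection criterion, ties
#' broken by the lower run index.
#'
#' @param fits Non-empty list of fitted runs.
#' @param criteria Numeric vector of selection criteria, one per fit.
#' @return The chosen index.
#' @export
select_best_init <- function(fits, criteria) {
  if (length(fits) == 0) stop("no fits to select from")
  stopifnot(length(criteria) == length(fits))
  which.max(criteria)    # first index wins ties
}

#' Repeated-split cross-validation of predictive accuracy
#'
#' Runs `n_repeats` independent random train/test splits (split seeds
#' `base seed + repeat index`), fits transductively on each, and records
#' the per-indicator test accuracy, yielding the long-format accuracy
#' table that downstream condition comparisons consume. Per-repeat node
#' covariances are kept for fold-averaged biomarker detection.
#'
#' @inheritParams fit_predict
#' @param n_repeats Number of independent splits (default 5).
#' @param fraction Training fraction (default 0.9).
#' @param category Label for the behavioral category of this table.
#' @return An object of class `latentsna_cv`: `accuracy` (tibble with
#'   condition, category, indicator, repeat, accuracy), `covariances`
#'   (tibble with repeat, node_id, covariance) and `fits` metadata.
#' @export
crossval <- function(connectomes, behavior, n_repeats = 5,
                     config = mcmc_config(), priors = prior_spec(),
                     fraction = 0.9, category = "behavior",
                     selection = "test") {
  stopifnot(n_repeats >= 1)
  acc <- list(); covs <- list()
  for (r in seq_len(n_repeats)) {
    plan <- make_split(connectomes$subject_ids, fraction,
                       seed = config$seed + r)
    cfg_r <- config
    cfg_r$seed <- config$seed + 1000L * r
    fp <- fit_predict(connectomes, behavior, plan, cfg_r, priors,
                      selection = selection)
    acc[[r]] <- fp$accuracy |>
      dplyr::mutate(condition = connectomes$condition, category = category,
                    repeat_index = r, .before = 1)
    covs[[r]] <- tidy(fp$fit) |>
      dplyr::select("node_id", "covariance") |>
      dplyr::mutate(repeat_index = r, .before = 1)
  }
  structure(list(accuracy = dplyr::bind_rows(acc),
                 covariances = dplyr::bind_rows(covs),
                 condition = connectomes$condition, category = category,
                 n_repeats = n_repeats),
            class = "latentsna_cv")
}

#' @export
print.latentsna_cv <- function(x, ...) {
  cat(sprintf("<latentsna_cv> condition '%s', %d repeats, mean accuracy %.3f\n",
              x$condition, x$n_repeats,
              mean(x$accuracy$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.latentsna_cv <- function(x, ...) x$accuracy

#' @export
glance.latentsna_cv <- function(x, ...) {
  x$accuracy |>
    dplyr::group_by(.data$condition, .data$category, .data$indicator) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
                     .groups = "drop")
}

#' Cross-validate several fMRI conditions on shared behavior
#'
#' Applies [crossval()] to each condition with identical split seeds, so
#' that every condition is evaluated on the same train/test partitions,
#' and binds the results into one accuracy table.
#'
#' @param condition_sets Named list of [connectome_set] objects over the
#'   same subjects.
#' @inheritParams crossval
#' @return A list of class `condition_comparison` with `accuracy` (bound
#'   tibble), `covariances`, and per-condition `cv` objects.
#' @export
compare_conditions <- function(condition_sets, behavior, n_repeats = 5,
                               config = mcmc_config(), priors = prior_spec(),
                               fraction = 0.9, category = "behavior",
                               selection = "test") {
  stopifnot(length(condition_sets) >= 1)
  cvs <- lapply(condition_sets, crossval, behavior = behavior,
                n_repeats = n_repeats, config = config, priors = priors,
                fraction = fraction, category = category,
                selection = selection)
  structure(list(
    accuracy = dplyr::bind_rows(lapply(cvs, `[[`, "accuracy")),
    covariances = dplyr::bind_rows(lapply(cvs, function(x) {
      dplyr::mutate(x$covariances, condition = x$condition, .before = 1)
    })),
    cv = cvs
  ), class = "condition_comparison")
}

#' @export
tidy.condition_comparison <- function(x, ...) x$accuracy
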