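#' Edge feature matrix for CPM-style models
#'
#' Vectorizes every subject's connectivity matrix ([vectorize_edges()]:
#' row-wise upper triangle including the diagonal) into an N x E feature
#' matrix, E = (V^2 + V)/2.
#'
#' @param connectomes A [connectome_set].
#' @return Numeric matrix with subjects as rows; `index_map` attribute
#'   maps columns to node pairs.
#' @export
edge_features <- function(connectomes) {
  stopifnot(inherits(connectomes, "connectome_set"))
  n <- n_subjects(connectomes)
  first <- vectorize_edges(connectomes$values[1, , ])
  out <- matrix(0, n, length(first))
  out[1, ] <- first
  if (n > 1) {
    for (j in 2:n) out[j, ] <- vectorize_edges(connectomes$values[j, , ])
  }
  rownames(out) <- connectomes$subject_ids
  attr(out, "index_map") <- attr(first, "index_map")
  out
}

#' Train a connectome-based predictive model (CPM)
#'
#' Screens each edge by the p-value of its Pearson correlation with the
#' outcome on the training set (p from the t-distribution transform of
#' the correlation), splits surviving edges by correlation sign, computes
#' per-subject positive- and negative-network strength sums, and fits a
#' linear model of the outcome on the strengths. The default fits two
#' predictors (positive and negative strength); when one set is empty, a
#' single-strength fit is used; when both are empty the model predicts
#' the training mean and is flagged. Constant features (e.g., a constant
#' diagonal) are dropped from screening with a warning.
#'
#' @param features N x E feature matrix (see [edge_features()]).
#' @param y Numeric outcome of length N.
#' @param p_threshold Edge-screening p-value threshold (default 0.001).
#' @param mode `"two_strength"` (default) or `"combined"` (single
#'   predictor pos_strength - neg_strength).
#' @return An object of class `cpm_model` with `positive_edges`,
#'   `negative_edges` (column indices), `coefficients`, `mode`, `flag`.
#' @export
cpm_train <- function(features, y, p_threshold = 0.001,
                      mode = c("two_strength", "combined")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(features), length(y) == nrow(features))
  if (nrow(features) < 10) stop("need at least 10 training subjects")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must lie in (0, 1]")
  }
  n <- nrow(features)
  sds <- apply(features, 2, stats::sd)
  usable <- sds > 0
  if (any(!usable)) {
    warning(sum(!usable), " constant feature(s) dropped from edge screening")
  }
  r <- rep(0, ncol(features))
  r[usable] <- suppressWarnings(as.vector(stats::cor(features[, usable,
                                                              drop = FALSE], y)))
  r[is.na(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  selected <- usable & pval < p_threshold & r != 0
  pos <- which(selected & r > 0)
  neg <- which(selected & r < 0)

  pos_strength <- if (length(pos)) rowSums(features[, pos, drop = FALSE]) else rep(0, n)
  neg_strength <- if (length(neg)) rowSums(features[, neg, drop = FALSE]) else rep(0, n)
  flag <- length(pos) + length(neg) == 0

  coefs <- if (flag) {
    c(intercept = mean(y))
  } else if (mode == "combined") {
    f <- stats::lm(y ~ I(pos_strength - neg_strength))
    stats::setNames(stats::coef(f), c("intercept", "combined"))
  } else if (length(pos) && length(neg)) {
    f <- stats::lm(y ~ pos_strength + neg_strength)
    stats::setNames(stats::coef(f), c("intercept", "positive", "negative"))
  } else if (length(pos)) {
    f <- stats::lm(y ~ pos_strength)
    stats::setNames(stats::coef(f), c("intercept", "positive"))
  } else {
    f <- stats::lm(y ~ neg_strength)
    stats::setNames(stats::coef(f), c("intercept", "negative"))
  }
  coefs[is.na(coefs)] <- 0
  structure(list(positive_edges = pos, negative_edges = neg,
                 coefficients = coefs, p_threshold = p_threshold,
                 mode = mode, flag = flag, n_features = ncol(features),
                 index_map = attr(features, "index_map")),
            class = "cpm_model")
}

#' Selected CPM edges as an edge list
#'
#' @param x A [cpm_train()] model. When the training features carried an
#'   `index_map` attribute (as produced by [edge_features()]), edges are
#'   reported as node pairs; otherwise as feature column indices.
#' @param ... Unused.
#' @return Tibble with `node_x`, `node_y` (or `feature`), `sign`.
#' @export
tidy.cpm_model <- function(x, ...) {
  idx <- c(x$positive_edges, x$negative_edges)
  sign <- rep(c("positive", "negative"),
              c(length(x$positive_edges), length(x$negative_edges)))
  if (!is.null(x$index_map)) {
    tibble::tibble(node_x = x$index_map[idx, "x"],
                   node_y = x$index_map[idx, "y"], sign = sign)
  } else {
    tibble::tibble(feature = idx, sign = sign)
  }
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf("<cpm_model> %d positive / %d negative edges (p < %g)%s\n",
              length(x$positive_edges), length(x$negative_edges),
              x$p_threshold, if (x$flag) " [no edges survived]" else ""))
  invisible(x)
}

#' Predict from a trained CPM model
#'
#' Applies the strength sums and the linear fit; deterministic.
#'
#' @param object A [cpm_train()] model.
#' @param features Feature matrix with the same number of columns as the
#'   training features.
#' @param ... Unused.
#' @return Numeric predictions, one per row.
#' @export
predict.cpm_model <- function(object, features, ...) {
  stopifnot(is.matrix(features))
  if (ncol(features) != object$n_features) {
    stop("feature length mismatch: expected ", object$n_features,
         " columns, got ", ncol(features))
  }
  n <- nrow(features)
  if (object$flag) return(rep(unname(object$coefficients["intercept"]), n))
  ps <- if (length(object$positive_edges)) {
    rowSums(features[, object$positive_edges, drop = FALSE])
  } else rep(0, n)
  ns <- if (length(object$negative_edges)) {
    rowSums(features[, object$negative_edges, drop = FALSE])
  } else rep(0, n)
  cf <- object$coefficients
  if (object$mode == "combined") {
    unname(cf["intercept"] + cf["combined"] * (ps - ns))
  } else {
    out <- rep(unname(cf["intercept"]), n)
    if ("positive" %in% names(cf)) out <- out + cf["positive"] * ps
    if ("negative" %in% names(cf)) out <- out + cf["negative"] * ns
    unname(out)
  }
}

#' Ridge (L2-penalized) regression baseline
#'
#' Fits an L2-penalized linear regression of the outcome on the edge
#' features with the penalty chosen by internal cross-validation on the
#' training set only, then predicts the held-out subjects.
#'
#' @param features_train,features_test Feature matrices.
#' @param y_train Training outcome.
#' @param lambda Optional penalty grid passed to glmnet.
#' @param nfolds Internal CV folds (default 5).
#' @param seed Seed for the internal fold assignment.
#' @return List with `predictions` for the test rows and `lambda` chosen.
#' @export
ridge_baseline <- function(features_train, y_train, features_test,
                           lambda = NULL, nfolds = 5, seed = 1) {
  stopifnot(is.matrix(features_train), is.matrix(features_test),
            ncol(features_train) == ncol(features_test))
  keep <- apply(features_train, 2, stats::sd) > 0
  if (sum(keep) < 2) stop("degenerate features: fewer than 2 varying columns")
  set.seed(seed)
  cv <- glmnet::cv.glmnet(features_train[, keep, drop = FALSE], y_train,
                          alpha = 0, lambda = lambda, nfolds = nfolds)
  pred <- as.vector(predict(cv, features_test[, keep, drop = FALSE],
                            s = "lambda.min"))
  list(predictions = pred, lambda = cv$lambda.min)
}

#' Cross-validated CPM accuracy on the package's split protocol
#'
#' Runs the CPM baseline over the same repeated 90/10 splits used by
#' [crossval()] (identical split seeds given the same base seed), so the
#' two methods are compared on identical train/test partitions. Each
#' indicator is predicted separately.
#'
#' @param connectomes A [connectome_set].
#' @param behavior Behavior tibble.
#' @param n_repeats Number of splits (default 5).
#' @param p_threshold Edge-screening threshold (default 0.001).
#' @param fraction Training fraction (default 0.9).
#' @param seed Base seed; split r uses `seed + r` (matching [crossval()]
#'   when the same seed is supplied via `mcmc_config`).
#' @param category Category label for the accuracy table.
#' @param mode CPM strength mode, see [cpm_train()].
#' @return Accuracy tibble (condition, category, indicator, repeat_index,
#'   accuracy).
#' @export
cpm_crossval <- function(connectomes, behavior, n_repeats = 5,
                         p_threshold = 0.001, fraction = 0.9, seed = 1,
                         category = "behavior", mode = "two_strength") {
  feats <- edge_features(connectomes)
  b <- behavior_matrix(behavior)
  out <- list()
  for (r in seq_len(n_repeats)) {
    plan <- make_split(connectomes$subject_ids, fraction, seed = seed + r)
    tr <- connectomes$subject_ids %in% plan$train_ids
    for (p in seq_len(ncol(b))) {
      ok <- tr & !is.na(b[, p])
      # the V zero-diagonal features are structurally constant; the
      # screening warning is expected here
      model <- suppressWarnings(
        cpm_train(feats[ok, , drop = FALSE], b[ok, p],
                  p_threshold = p_threshold, mode = mode))
      pred <- predict(model, feats[!tr, , drop = FALSE])
      out[[length(out) + 1]] <- tibble::tibble(
        condition = connectomes$condition, category = category,
        indicator = colnames(b)[p], repeat_index = r,
        accuracy = accuracy(pred, b[!tr, p])
      )
    }
  }
  dplyr::bind_rows(out)
}
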