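#' Create a connectome set
#'
#' A `connectome_set` holds a stack of N symmetric V x V functional
#' connectivity matrices (Fisher-z units) for one scanning condition.
#' Diagonals carry no information under the model and are stored as zero.
#'
#' @param values Numeric array of dimension N x V x V, each slice symmetric.
#' @param subject_ids Character vector of length N (default `"S001"`, ...).
#' @param node_ids Vector of length V of node labels (default `1:V`).
#' @param condition Single string naming the scanning condition.
#' @param tol Symmetry tolerance.
#'
#' @return An object of class `connectome_set`.
#' @export
connectome_set <- function(values, subject_ids = NULL, node_ids = NULL,
                           condition = "unknown", tol = 1e-6) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  n <- dim(values)[1]
  v <- dim(values)[2]
  if (dim(values)[3] != v) stop("connectome slices must be square")
  if (v < 3) stop("need at least 3 nodes")
  if (!all(is.finite(values))) stop("non-finite connectivity values")
  for (j in seq_len(n)) {
    m <- values[j, , ]
    if (max(abs(m - t(m))) > tol) {
      stop("connectome for subject ", j, " is not symmetric within tolerance")
    }
    diag(m) <- 0
    values[j, , ] <- (m + t(m)) / 2
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  if (is.null(node_ids)) node_ids <- seq_len(v)
  stopifnot(length(subject_ids) == n, length(node_ids) == v)
  structure(
    list(values = values, subject_ids = as.character(subject_ids),
         node_ids = node_ids, condition = as.character(condition)[1]),
    class = "connectome_set"
  )
}

#' @export
print.connectome_set <- function(x, ...) {
  cat(sprintf("<connectome_set> condition '%s': %d subjects x %d nodes\n",
              x$condition, n_subjects(x), n_nodes(x)))
  invisible(x)
}

#' @export
dim.connectome_set <- function(x) dim(x$values)

n_subjects <- function(x) dim(x$values)[1]
n_nodes <- function(x) dim(x$values)[2]

#' Convert a connectome set to a long edge tibble
#'
#' Each unordered node pair (x < y) appears once per subject.
#'
#' @param x A [connectome_set].
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `node_x`, `node_y`, `value`,
#'   `condition`.
#' @export
tidy.connectome_set <- function(x, ...) {
  v <- n_nodes(x)
  ut <- which(upper.tri(matrix(0, v, v)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  purrr::map_dfr(seq_len(n_subjects(x)), function(j) {
    m <- x$values[j, , ]
    tibble::tibble(
      subject_id = x$subject_ids[j],
      node_x = ut[, 1], node_y = ut[, 2],
      value = m[ut], condition = x$condition
    )
  })
}

#' Build a connectome set from a long edge tibble
#'
#' The inverse of [tidy.connectome_set()]: expects one row per subject and
#' unordered node pair with 1-based node indices, `node_x < node_y`.
#'
#' @param data Data frame with columns `subject_id`, `node_x`, `node_y`,
#'   `value`.
#' @param n_nodes Number of nodes V; inferred from the largest index if
#'   missing.
#' @param condition Condition label.
#' @return A [connectome_set].
#' @export
as_connectome_set <- function(data, n_nodes = NULL, condition = "unknown") {
  stopifnot(all(c("subject_id", "node_x", "node_y", "value") %in% names(data)))
  if (any(data$node_x >= data$node_y)) {
    stop("edge list must store unordered pairs once with node_x < node_y")
  }
  v <- if (is.null(n_nodes)) max(data$node_y) else n_nodes
  ids <- unique(as.character(data$subject_id))
  arr <- array(0, dim = c(length(ids), v, v))
  for (j in seq_along(ids)) {
    d <- data[as.character(data$subject_id) == ids[j], ]
    m <- matrix(0, v, v)
    m[cbind(d$node_x, d$node_y)] <- d$value
    arr[j, , ] <- m + t(m)
  }
  connectome_set(arr, subject_ids = ids, condition = condition)
}

#' Entrywise average of connectome sets across conditions
#'
#' Produces the "Average" condition: the entrywise mean of each subject's
#' connectivity matrices across conditions. Subjects and nodes must align.
#'
#' @param sets A list of [connectome_set] objects with identical subjects
#'   and nodes.
#' @param condition Label for the averaged condition.
#' @return A [connectome_set].
#' @export
average_connectomes <- function(sets, condition = "Average") {
  stopifnot(length(sets) >= 1)
  ref <- sets[[1]]
  for (s in sets) {
    if (!identical(dim(s$values), dim(ref$values)) ||
        !identical(s$subject_ids, ref$subject_ids)) {
      stop("connectome sets must share subjects and dimensions")
    }
  }
  vals <- Reduce(`+`, lapply(sets, `[[`, "values")) / length(sets)
  connectome_set(vals, subject_ids = ref$subject_ids,
                 node_ids = ref$node_ids, condition = condition)
}

#' Vectorize the upper triangle of a symmetric matrix (with diagonal)
#'
#' Flattens a V x V symmetric matrix into a vector of length (V^2 + V)/2 by
#' row-wise concatenation of the upper triangle including the diagonal, the
#' edge-feature representation used by CPM-style models.
#'
#' @param m Symmetric numeric matrix.
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length `(V^2 + V)/2` with an `index_map`
#'   attribute: a two-column matrix of the (x, y) pair behind each position.
#' @export
vectorize_edges <- function(m, tol = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) stop("matrix is not symmetric within tolerance")
  v <- nrow(m)
  x <- rep(seq_len(v), times = v:1)
  y <- unlist(lapply(seq_len(v), function(i) i:v))
  out <- m[cbind(x, y)]
  attr(out, "index_map") <- cbind(x = x, y = y)
  out
}

#' Rebuild a symmetric matrix from an edge feature vector
#'
#' Inverse of [vectorize_edges()].
#'
#' @param vec Vector of length `(V^2 + V)/2`.
#' @return A symmetric V x V matrix.
#' @export
unflatten_edges <- function(vec) {
  e <- length(vec)
  v <- (sqrt(8 * e + 1) - 1) / 2
  if (abs(v - round(v)) > 1e-8) stop("length is not (V^2+V)/2 for integer V")
  v <- round(v)
  x <- rep(seq_len(v), times = v:1)
  y <- unlist(lapply(seq_len(v), function(i) i:v))
  m <- matrix(0, v, v)
  m[cbind(x, y)] <- vec
  m[cbind(y, x)] <- vec
  m
}

#' Fisher-z connectivity matrix from a multivariate time series
#'
#' Computes pairwise Pearson correlations between node time series and
#' applies the Fisher z-transformation (atanh). The diagonal is set to 0 by
#' convention (its Fisher-z value is infinite and carries no information).
#'
#' @param ts Numeric T x V matrix, one column per node.
#' @param node_ids Optional node labels used in error messages.
#' @return A symmetric V x V Fisher-z matrix with zero diagonal.
#' @export
connectivity_from_timeseries <- function(ts, node_ids = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points")
  if (is.null(node_ids)) node_ids <- colnames(ts) %||% seq_len(ncol(ts))
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series for node(s): ",
         paste(node_ids[sds == 0], collapse = ", "))
  }
  r <- stats::cor(ts)
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  diag(z) <- 0
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-mean connectome
#'
#' Entrywise mean connectivity matrix across subjects of a set.
#'
#' @param x A [connectome_set].
#' @return A symmetric V x V matrix.
#' @export
group_mean_connectome <- function(x) {
  stopifnot(inherits(x, "connectome_set"))
  apply(x$values, c(2, 3), mean)
}
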