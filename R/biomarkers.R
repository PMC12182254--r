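#' The ten functional-system labels
#'
#' Canonical system names used for the 268-node parcellation's
#' atlas-level grouping of nodes.
#' @export
functional_systems <- c(
  "Medial Frontal", "Frontoparietal", "Default Mode", "Motor",
  "Visual I", "Visual II", "Visual Association", "Limbic",
  "Basal Ganglia", "Cerebellum"
)

#' Generate a synthetic node-to-system atlas
#'
#' Produces an atlas table assigning each of `V` nodes to one of
#' `n_systems` functional systems (balanced round-robin assignment after a
#' seeded shuffle) with synthetic 3-D coordinates on a sphere. This is a
#' stand-in fixture for a real parcellation atlas.
#'
#' @param V Number of nodes.
#' @param n_systems Number of systems (default 10, labelled with the
#'   canonical system names when `n_systems <= 10`).
#' @param seed RNG seed for the shuffle.
#' @return Tibble with `node_id`, `system`, `x`, `y`, `z`.
#' @export
synthetic_atlas <- function(V, n_systems = 10, seed = 1) {
  stopifnot(V >= 1, n_systems >= 1)
  labels <- if (n_systems <= length(functional_systems)) {
    functional_systems[seq_len(n_systems)]
  } else {
    paste0("System", seq_len(n_systems))
  }
  set.seed(seed)
  assignment <- sample(rep_len(labels, V))
  theta <- stats::runif(V, 0, 2 * pi)
  phi <- acos(stats::runif(V, -1, 1))
  tibble::tibble(
    node_id = seq_len(V),
    system = assignment,
    x = round(70 * sin(phi) * cos(theta), 1),
    y = round(70 * sin(phi) * sin(theta), 1),
    z = round(70 * cos(phi), 1)
  )
}

#' Average node covariances across cross-validation folds
#'
#' Entrywise mean of the per-fold covariance vectors, the fold-averaged
#' biomarker strength.
#'
#' @param fold_vectors List of equal-length numeric vectors, or the
#'   `covariances` tibble of a [crossval()] result (columns
#'   `repeat_index`, `node_id`, `covariance`).
#' @return A named numeric vector of length V.
#' @export
average_covariances <- function(fold_vectors) {
  if (is.data.frame(fold_vectors)) {
    out <- fold_vectors |>
      dplyr::group_by(.data$node_id) |>
      dplyr::summarise(covariance = mean(.data$covariance), .groups = "drop")
    return(stats::setNames(out$covariance, out$node_id))
  }
  if (!is.list(fold_vectors) || length(fold_vectors) == 0) {
    stop("need a non-empty list of fold vectors")
  }
  if (length(unique(lengths(fold_vectors))) != 1) {
    stop("fold vectors must have equal length")
  }
  Reduce(`+`, fold_vectors) / length(fold_vectors)
}

#' Select top positive and negative biomarker nodes
#'
#' Picks up to `k_pos` nodes with the largest strictly positive
#' covariances and up to `k_neg` nodes with the smallest strictly negative
#' covariances (ties broken by lower node index; zero belongs to neither
#' list). With the default 10 + 10 this is the "top 20 brain nodes"
#' selection rule.
#'
#' @param covariances Numeric vector of per-node covariances (names taken
#'   as node ids; defaults to 1..V).
#' @param k_pos,k_neg Maximum nodes per sign (default 10 each).
#' @return An object of class `biomarker_selection`: tibble `nodes` with
#'   `node_id`, `covariance`, `sign` (positive sorted descending, then
#'   negative sorted ascending by covariance).
#' @export
select_top_nodes <- function(covariances, k_pos = 10, k_neg = 10) {
  v <- length(covariances)
  stopifnot(v >= 1, k_pos >= 0, k_neg >= 0)
  ids <- names(covariances) %||% as.character(seq_len(v))
  covs <- unname(covariances)
  pos_i <- which(covs > 0)
  neg_i <- which(covs < 0)
  pos_i <- pos_i[order(-covs[pos_i], pos_i)]
  neg_i <- neg_i[order(covs[neg_i], neg_i)]
  pos_i <- utils::head(pos_i, k_pos)
  neg_i <- utils::head(neg_i, k_neg)
  nodes <- tibble::tibble(
    node_id = ids[c(pos_i, neg_i)],
    covariance = covs[c(pos_i, neg_i)],
    sign = rep(c("positive", "negative"), c(length(pos_i), length(neg_i)))
  )
  structure(list(nodes = nodes, k_pos = k_pos, k_neg = k_neg),
            class = "biomarker_selection")
}

#' @export
print.biomarker_selection <- function(x, ...) {
  cat(sprintf("<biomarker_selection> %d positive + %d negative nodes\n",
              sum(x$nodes$sign == "positive"), sum(x$nodes$sign == "negative")))
  invisible(x)
}

#' @export
tidy.biomarker_selection <- function(x, ...) x$nodes

#' Count selected biomarker nodes per functional system
#'
#' Maps each selected node to its functional system and counts nodes per
#' system. Every system of the atlas appears in the output (zero counts
#' included), so the table can feed fixed-axis spider/radar plots.
#'
#' @param selection A [select_top_nodes()] result.
#' @param atlas Atlas tibble with `node_id` and `system`.
#' @return Tibble with `system` and `count`, class `system_counts`;
#'   counts sum to the selection size.
#' @export
count_by_system <- function(selection, atlas) {
  stopifnot(inherits(selection, "biomarker_selection"))
  atlas <- tibble::as_tibble(atlas)
  sys <- stats::setNames(as.character(atlas$system), as.character(atlas$node_id))
  unmapped <- setdiff(as.character(selection$nodes$node_id), names(sys))
  if (length(unmapped) > 0) {
    stop("selected nodes missing from atlas: ", paste(unmapped, collapse = ", "))
  }
  all_systems <- sort(unique(as.character(atlas$system)))
  hit <- table(factor(sys[as.character(selection$nodes$node_id)],
                      levels = all_systems))
  out <- tibble::tibble(system = all_systems, count = as.integer(hit))
  class(out) <- c("system_counts", class(out))
  out
}

#' Edge highlights among top covariance nodes
#'
#' Selects the `k` nodes with the largest positive and the `k` nodes with
#' the smallest negative covariance, then returns the edges among each
#' signed group, with edge weights taken from the group-mean connectome.
#' This is the data behind circle-plot visualizations of top
#' brain-behavior edges. (Descriptions of this display alternately call
#' its elements nodes or edges; the operation selects node groups and
#' reports the within-group edges.)
#'
#' @param covariances Numeric vector of per-node covariances.
#' @param group_mean_connectome Symmetric V x V matrix (e.g., the mean
#'   connectivity across subjects).
#' @param k Nodes per sign (default 5).
#' @param atlas Optional atlas tibble; when given, node coordinates are
#'   attached.
#' @return A list of class `edge_highlight`: `nodes` (tibble with sign and
#'   covariance, plus coordinates if an atlas was given), `edges` (tibble
#'   with node_x, node_y, sign, weight) and `flag` (TRUE when fewer than
#'   `k` nodes of a sign were available).
#' @export
top_edges <- function(covariances, group_mean_connectome, k = 5,
                      atlas = NULL) {
  v <- length(covariances)
  stopifnot(nrow(group_mean_connectome) == v, ncol(group_mean_connectome) == v)
  sel <- select_top_nodes(covariances, k_pos = k, k_neg = k)
  nodes <- sel$nodes
  flag <- any(table(factor(nodes$sign, c("positive", "negative"))) < k)
  ids <- names(covariances) %||% as.character(seq_len(v))
  edges <- purrr::map_dfr(c("positive", "negative"), function(sg) {
    grp <- match(nodes$node_id[nodes$sign == sg], ids)
    if (length(grp) < 2) return(NULL)
    pairs <- utils::combn(sort(grp), 2)
    tibble::tibble(
      node_x = ids[pairs[1, ]], node_y = ids[pairs[2, ]], sign = sg,
      weight = group_mean_connectome[cbind(pairs[1, ], pairs[2, ])]
    )
  })
  if (!is.null(atlas)) {
    nodes <- dplyr::left_join(
      nodes, dplyr::mutate(tibble::as_tibble(atlas),
                           node_id = as.character(.data$node_id)),
      by = "node_id")
  }
  structure(list(nodes = nodes, edges = edges, k = k, flag = flag),
            class = "edge_highlight")
}

#' @export
print.edge_highlight <- function(x, ...) {
  cat(sprintf("<edge_highlight> %d nodes, %d within-group edges%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$flag) " (fewer than k nodes of one sign)" else ""))
  invisible(x)
}
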