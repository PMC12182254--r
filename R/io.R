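#' Write a connectome set as matrix files plus a manifest
#'
#' One whitespace-delimited V x V numeric text file per subject, plus a
#' tab-separated manifest mapping `subject_id` to the file name. The
#' manifest order defines the subject order on reading.
#'
#' @param connectomes A [connectome_set].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_connectomes <- function(connectomes, dir) {
  stopifnot(inherits(connectomes, "connectome_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s.txt", connectomes$subject_ids)
  for (j in seq_len(n_subjects(connectomes))) {
    utils::write.table(connectomes$values[j, , ],
                       file.path(dir, files[j]),
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  readr::write_tsv(tibble::tibble(subject_id = connectomes$subject_ids,
                                  file = files), manifest)
  invisible(manifest)
}

#' Read a connectome set from a manifest of matrix files
#'
#' @param manifest Path to a tab-separated manifest with columns
#'   `subject_id` and `file` (paths relative to the manifest's directory).
#' @param condition Condition label for the set.
#' @param tol Symmetry tolerance (default 1e-6).
#' @return A [connectome_set]; subjects in manifest order.
#' @export
read_connectomes <- function(manifest, condition = "unknown", tol = 1e-6) {
  man <- readr::read_tsv(manifest, show_col_types = FALSE)
  stopifnot(all(c("subject_id", "file") %in% names(man)))
  base <- dirname(manifest)
  mats <- vector("list", nrow(man))
  for (j in seq_len(nrow(man))) {
    path <- file.path(base, man$file[j])
    if (!file.exists(path)) stop("missing connectome file: ", path)
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m)) {
      stop("file ", man$file[j], ": matrix is not square (",
           nrow(m), " x ", ncol(m), ")")
    }
    if (any(is.na(m))) stop("file ", man$file[j], ": missing values")
    if (max(abs(m - t(m))) > tol) {
      stop("file ", man$file[j], ": matrix is not symmetric within ", tol)
    }
    mats[[j]] <- m
  }
  v <- nrow(mats[[1]])
  arr <- array(0, dim = c(nrow(man), v, v))
  for (j in seq_len(nrow(man))) {
    if (nrow(mats[[j]]) != v) {
      stop("file ", man$file[j], ": dimension mismatch with first matrix")
    }
    arr[j, , ] <- mats[[j]]
  }
  connectome_set(arr, subject_ids = man$subject_id, condition = condition,
                 tol = tol)
}

#' Read/write a connectome set as a stacked edge list
#'
#' Tab-separated columns `subject_id`, `node_x`, `node_y`, `value`;
#' 1-based node indices, each unordered pair stored once with
#' `node_x < node_y`.
#'
#' @param connectomes A [connectome_set].
#' @param path File path.
#' @return `write_connectome_edges` returns the path invisibly;
#'   `read_connectome_edges` a [connectome_set].
#' @export
write_connectome_edges <- function(connectomes, path) {
  readr::write_tsv(tidy(connectomes)[c("subject_id", "node_x", "node_y",
                                       "value")], path)
  invisible(path)
}

#' @rdname write_connectome_edges
#' @param condition Condition label.
#' @param n_nodes Number of nodes (inferred from the data if missing).
#' @export
read_connectome_edges <- function(path, condition = "unknown",
                                  n_nodes = NULL) {
  as_connectome_set(readr::read_tsv(path, show_col_types = FALSE),
                    n_nodes = n_nodes, condition = condition)
}

#' Read and write behavior tables
#'
#' Delimited text with the subject id in the first column and one named
#' indicator per remaining column; an empty cell is a missing value.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return A behavior tibble.
#' @export
read_behavior <- function(path, delim = "\t") {
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           na = c("", "NA"))
  names(out)[1] <- "subject_id"
  out$subject_id <- as.character(out$subject_id)
  out
}

#' @rdname read_behavior
#' @param behavior Behavior tibble.
#' @export
write_behavior <- function(behavior, path, delim = "\t") {
  readr::write_delim(behavior, path, delim = delim, na = "")
  invisible(path)
}

#' Read a node-to-system atlas table
#'
#' Delimited text with columns `node_id`, `system` and optional `x`, `y`,
#' `z` coordinates; 1-based node ids matching the connectome node order.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return An atlas tibble.
#' @export
read_atlas <- function(path, delim = "\t") {
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (!all(c("node_id", "system") %in% names(out))) {
    stop("atlas file must have node_id and system columns")
  }
  if (anyDuplicated(out$node_id)) stop("atlas maps some node more than once")
  out
}

#' Write a result table as tab-separated text
#'
#' Generic writer used for accuracy tables, covariance tables, selections,
#' per-system counts and coefficient tables.
#'
#' @param x A data frame.
#' @param path File path.
#' @export
write_result_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Load a flat key-value run configuration
#'
#' YAML-compatible flat key: value text. Recognized keys include paths
#' (`behavior`, `atlas`, one `connectomes_<condition>` manifest per
#' condition), MCMC settings (`n_burn`, `n_samples`, `thin`, `n_inits`,
#' `seed`), the split (`fraction`, `n_repeats`) and thresholds
#' (`cpm_p_threshold`, `k_pos`, `k_neg`, `reference_condition`).
#' Unspecified settings default to the standard protocol values (0.9
#' split, p 0.001, 10 + 10 nodes, 5000 burn, 15000 samples, 10 inits,
#' 5 repeats).
#'
#' @param path Path to the config file.
#' @return A list of class `run_config` with `paths`, `mcmc`
#'   ([mcmc_config()]) and `settings`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read run configurations")
  }
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  path_keys <- c("behavior", "atlas",
                 grep("^connectomes_", names(raw), value = TRUE))
  paths <- list()
  for (k in intersect(path_keys, names(raw))) {
    p <- raw[[k]]
    if (!file.exists(p)) p <- file.path(base, raw[[k]])
    if (!file.exists(p)) stop("configured file does not exist: ", raw[[k]])
    paths[[k]] <- p
  }
  num <- function(key, default) as.numeric(raw[[key]] %||% default)
  mcmc <- mcmc_config(
    n_burn = num("n_burn", 5000), n_samples = num("n_samples", 15000),
    thin = num("thin", 1), n_inits = num("n_inits", 10),
    seed = num("seed", 1)
  )
  settings <- list(
    fraction = num("fraction", 0.9), n_repeats = num("n_repeats", 5),
    cpm_p_threshold = num("cpm_p_threshold", 0.001),
    k_pos = num("k_pos", 10), k_neg = num("k_neg", 10),
    reference_condition = raw$reference_condition %||% "Rest1",
    category = raw$category %||% "behavior"
  )
  structure(list(paths = paths, mcmc = mcmc, settings = settings),
            class = "run_config")
}
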