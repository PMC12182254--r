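#' Extract the indicator matrix from a behavior tibble
#'
#' Behavior tables are tibbles with a `subject_id` column followed by one
#' numeric column per indicator; `NA` marks a missing response. Subject
#' order must match the paired connectome set.
#'
#' @param behavior Data frame with `subject_id` and indicator columns.
#' @return Numeric N x P matrix with indicator names as colnames and
#'   subject ids as rownames.
#' @export
behavior_matrix <- function(behavior) {
  stopifnot("subject_id" %in% names(behavior))
  b <- as.matrix(behavior[setdiff(names(behavior), c("subject_id", "category"))])
  storage.mode(b) <- "double"
  rownames(b) <- as.character(behavior$subject_id)
  if (ncol(b) < 1) stop("behavior table has no indicator columns")
  b
}

#' Mask behavior rows as missing
#'
#' Sets all indicator values to `NA` for the given subjects. Used before a
#' transductive fit so that test subjects contribute connectivity but no
#' behavior.
#'
#' @param behavior Behavior tibble (see [behavior_matrix()]).
#' @param subject_ids Subjects whose rows are masked.
#' @return The behavior tibble with masked rows.
#' @export
mask_behavior <- function(behavior, subject_ids) {
  cols <- setdiff(names(behavior), c("subject_id", "category"))
  rows <- behavior$subject_id %in% subject_ids
  behavior[rows, cols] <- NA_real_
  behavior
}

check_alignment <- function(connectomes, behavior) {
  if (!identical(connectomes$subject_ids, as.character(behavior$subject_id))) {
    stop("subject order of behavior table must match the connectome set")
  }
  invisible(TRUE)
}
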