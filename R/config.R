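#' Configuration for the MCAR test
#'
#' Collects every tuning parameter of [pklm_test()]. Apart from
#' `size_resp_set` (where 2, i.e. binary classification per projection, works
#' well across examples) the guidance is "higher is better" for accuracy at
#' the cost of compute; the permutation count only discretizes the attainable
#' p-values, so it can stay low while the projection count stays high.
#'
#' @param num_proj number of projection pairs N.
#' @param nperm number of global row permutations L; the smallest attainable
#'   p-value is `1 / (nperm + 1)`.
#' @param num_trees_per_proj trees per probability forest.
#' @param min_node_size minimum terminal node size per tree.
#' @param size_resp_set cap on collapsed classes per projection (>= 2).
#' @param eps log-odds clip bound; `NULL` means `1 / (2 * num_trees_per_proj)`.
#' @param min_rows minimum complete-case rows per projection.
#' @param min_class_size minimum rows per collapsed class.
#' @param max_attempts rejection-sampling budget per projection pair.
#' @param partial also compute per-variable partial p-values.
#' @param partial_filter `"B"` excludes variable k from the label-building set
#'   only; `"AB"` excludes it from both sets of the pair.
#' @param na_strings strings read as missing by [read_incomplete_csv()].
#' @return a list of class `pklm_config`.
#' @export
pklm_config <- function(num_proj = 100L, nperm = 30L,
                        num_trees_per_proj = 200L, min_node_size = 10L,
                        size_resp_set = 2L, eps = NULL,
                        min_rows = 10L, min_class_size = 2L,
                        max_attempts = 300L,
                        partial = FALSE, partial_filter = c("B", "AB"),
                        na_strings = c("NA", "", "NaN")) {
  partial_filter <- match.arg(partial_filter)
  stopifnot(num_proj >= 1L, nperm >= 1L, num_trees_per_proj >= 1L,
            min_node_size >= 1L, size_resp_set >= 2L)
  if (is.null(eps)) eps <- 1 / (2 * num_trees_per_proj)
  stopifnot(eps > 0, eps < 0.5)
  structure(list(num_proj = as.integer(num_proj), nperm = as.integer(nperm),
                 num_trees_per_proj = as.integer(num_trees_per_proj),
                 min_node_size = as.integer(min_node_size),
                 size_resp_set = as.integer(size_resp_set), eps = eps,
                 min_rows = as.integer(min_rows),
                 min_class_size = as.integer(min_class_size),
                 max_attempts = as.integer(max_attempts),
                 partial = isTRUE(partial), partial_filter = partial_filter,
                 na_strings = na_strings),
            class = "pklm_config")
}
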