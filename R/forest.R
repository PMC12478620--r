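#' Out-of-bag class probabilities from a probability forest
#'
#' Fits a Malley-style probability forest (bagged probability trees: each tree
#' grown on a bootstrap sample, class-frequency leaves) on a fully observed
#' feature submatrix and returns, for every row, the class-probability
#' estimate averaged over the trees in which the row was out-of-bag. All
#' features are candidate splits in every tree (mtry = number of columns), so
#' the only feature subsampling in the overall procedure comes from the random
#' projections themselves.
#'
#' Rows that were in-bag in every tree have no out-of-bag estimate; they are
#' flagged as uncovered rather than given a made-up probability. With the
#' default tree counts this event is rare (each row is out-of-bag per tree
#' with probability about exp(-1)).
#'
#' @param x_sub data.frame of classifier inputs, no missing cells (guaranteed
#'   when rows come from [complete_rows_on()]). Categorical columns may be
#'   factors; they are handled by the forest's ordered-split encoding.
#' @param labels integer class labels 1..K, each class with >= 2 rows.
#' @param num_trees number of trees.
#' @param min_node_size minimum terminal node size.
#' @param seed integer seed passed to the forest; with one thread the fit is
#'   bit-reproducible.
#' @return an object of class `oob_probabilities`: list with `probs`
#'   (n x K matrix, rows on the probability simplex for covered rows),
#'   `covered` (logical), `class_order` (1..K, matching `probs` columns).
#' @export
fit_oob_probabilities <- function(x_sub, labels, num_trees = 200L,
                                  min_node_size = 10L, seed = NULL) {
  if (num_trees < 1L) stop("num_trees must be >= 1")
  labels <- as.integer(labels)
  k <- max(labels)
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  if (!is.data.frame(x_sub)) x_sub <- as.data.frame(x_sub)
  if (anyNA(x_sub)) stop("classifier input contains missing cells")
  stopifnot(nrow(x_sub) == length(labels))

  fit <- ranger::ranger(
    y = factor(labels, levels = seq_len(k)),
    x = x_sub,
    probability = TRUE,
    num.trees = num_trees,
    mtry = ncol(x_sub),
    min.node.size = min_node_size,
    seed = seed,
    num.threads = 1L
  )
  probs <- fit$predictions[, as.character(seq_len(k)), drop = FALSE]
  covered <- stats::complete.cases(probs)
  if (!all(covered)) {
    message(sprintf("%d row(s) never out-of-bag; excluded from the statistic",
                    sum(!covered)))
  }
  structure(list(probs = unname(probs), covered = covered,
                 class_order = seq_len(k)),
            class = "oob_probabilities")
}
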