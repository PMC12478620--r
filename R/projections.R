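#' Constraints for projection-pair sampling
#'
#' @param size_resp_set maximum number of collapsed classes per projection;
#'   2 reduces every projection to a binary classification problem.
#' @param min_rows minimum size of the complete-case set O(A).
#' @param min_class_size minimum number of rows per collapsed class.
#' @param max_attempts rejection-sampling budget before giving up.
#' @return a named list of constraints.
#' @export
projection_constraints <- function(size_resp_set = 2L, min_rows = 10L,
                                   min_class_size = 2L, max_attempts = 300L) {
  stopifnot(size_resp_set >= 2L, min_rows >= 1L, min_class_size >= 1L,
            max_attempts >= 1L)
  list(size_resp_set = as.integer(size_resp_set),
       min_rows = as.integer(min_rows),
       min_class_size = as.integer(min_class_size),
       max_attempts = as.integer(max_attempts))
}

# sample() without the length-1 surprise
resample <- function(x, k) x[sample.int(length(x), k)]

#' Sample one projection pair (A, B)
#'
#' Draws a feature set A (classifier input) and a disjoint label-building set
#' B by the two-stage uniform scheme: |A| uniform on 1..p-1, then A uniform
#' without replacement; |B| uniform on 1..p-|A|, then B uniform without
#' replacement from the complement of A. The pair is accepted iff the
#' complete-case set O(A) has at least `min_rows` rows and the collapsed
#' labels on B give between 2 and `size_resp_set` classes, each with at least
#' `min_class_size` members; otherwise both sets are redrawn, up to
#' `max_attempts` times.
#'
#' Uses the R random stream; seed with [set.seed()] for reproducibility.
#'
#' @param m a [missingness_matrix()].
#' @param constraints see [projection_constraints()].
#' @return an object of class `projection_pair`: list with `A`, `B`, `rows`
#'   (= O(A)), `labels`, `n_classes`, `class_patterns`.
#' @export
sample_projection_pair <- function(m, constraints = projection_constraints()) {
  p <- ncol(m)
  if (p < 2L) stop("need at least 2 columns")
  for (attempt in seq_len(constraints$max_attempts)) {
    na <- sample.int(p - 1L, 1L)
    A <- sort(resample(seq_len(p), na))
    comp <- setdiff(seq_len(p), A)
    nb <- sample.int(length(comp), 1L)
    B <- sort(resample(comp, nb))
    rows <- complete_rows_on(m, A)
    if (length(rows) < constraints$min_rows) next
    lab <- collapse_labels(m, rows, B)
    if (lab$n_classes < 2L || lab$n_classes > constraints$size_resp_set) next
    if (min(tabulate(lab$labels, lab$n_classes)) < constraints$min_class_size) next
    return(structure(list(A = A, B = B, rows = rows,
                          labels = lab$labels, n_classes = lab$n_classes,
                          class_patterns = lab$class_patterns),
                     class = "projection_pair"))
  }
  stop("no valid projection found after ", constraints$max_attempts,
       " attempts; the missingness structure may have a single pattern, ",
       "making the MCAR test undefined")
}

#' Sample a set of projection pairs
#'
#' N i.i.d. draws from [sample_projection_pair()]; duplicates are allowed
#' (sampling is with replacement over the projection space).
#'
#' @inheritParams sample_projection_pair
#' @param N number of pairs.
#' @return list of `projection_pair` objects.
#' @export
sample_projection_set <- function(m, N, constraints = projection_constraints()) {
  stopifnot(N >= 1L)
  lapply(seq_len(N), function(i) sample_projection_pair(m, constraints))
}
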