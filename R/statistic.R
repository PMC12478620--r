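#' Clipped log-odds
#'
#' log(q / (1 - q)) with q the probability clipped to `[eps, 1 - eps]`.
#' Out-of-bag frequencies can be exactly 0 or 1, so the clip bound keeps every
#' term finite; the default used throughout the package is
#' `1 / (2 * num_trees)`, the resolution of an out-of-bag frequency, which
#' bounds each log-odds by about log(2 * num_trees) without moving interior
#' values.
#'
#' @param p probability (vectorized), in `[0, 1]`.
#' @param eps clip bound, in (0, 0.5).
#' @return log-odds of the clipped probability.
#' @export
log_odds <- function(p, eps = 1e-9) {
  stopifnot(eps > 0, eps < 0.5)
  q <- pmin(pmax(p, eps), 1 - eps)
  log(q / (1 - q))
}

#' Per-class symmetrized log-odds statistic
#'
#' For a class g, the mean log-odds of the estimated class-g probability over
#' rows labelled g, minus the same mean over all other rows. The statistic
#' converges (as sample size and classifier accuracy grow) to the symmetrized
#' Kullback-Leibler divergence between the class-g distribution and the
#' mixture of the remaining classes; the class-prior terms in the log-odds
#' difference cancel. Only rows with an out-of-bag estimate enter the sums.
#'
#' @param oob an [fit_oob_probabilities()] result.
#' @param labels integer labels for the same rows; entries outside
#'   `1..n_classes` (e.g. 0 for "pattern not among the original classes"
#'   under permutation) count toward the complement of every class.
#' @param g class index.
#' @param eps clip bound for [log_odds()].
#' @return the statistic, or `NA_real_` if the class or its complement is
#'   empty among covered rows (degenerate class, skipped by the caller).
#' @export
per_class_statistic <- function(oob, labels, g, eps = 1e-9) {
  class_stat_from_lo(log_odds(oob$probs[, g], eps), oob$covered, labels, g)
}

# shared arithmetic core: lo is the clipped log-odds of class g's probability
class_stat_from_lo <- function(lo, covered, labels, g) {
  in_g <- covered & labels == g
  out_g <- covered & labels != g
  if (!any(in_g) || !any(out_g)) return(NA_real_)
  mean(lo[in_g]) - mean(lo[out_g])
}

# projection statistic from a precomputed log-odds matrix (one column per class)
proj_stat_from_lo <- function(lo_mat, covered, labels, n_classes) {
  vals <- vapply(seq_len(n_classes),
                 function(g) class_stat_from_lo(lo_mat[, g], covered, labels, g),
                 numeric(1L))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Projection-level statistic
#'
#' Mean of [per_class_statistic()] over all non-degenerate classes of one
#' projection pair (equal weight per class).
#'
#' @inheritParams per_class_statistic
#' @param n_classes number of classes of the projection.
#' @return the mean, or `NA_real_` if every class is degenerate.
#' @export
projection_statistic <- function(oob, labels, n_classes, eps = 1e-9) {
  proj_stat_from_lo(log_odds(oob$probs[, seq_len(n_classes), drop = FALSE], eps),
                    oob$covered, labels, n_classes)
}

#' Pool projection statistics
#'
#' Arithmetic mean over projections: the pooled statistic for the observed
#' labels, or the pooled permuted statistic when fed one permutation's values.
#'
#' @param values numeric vector, non-empty.
#' @return the mean.
#' @export
aggregate_statistic <- function(values) {
  if (!length(values)) stop("no projection statistics to aggregate")
  mean(values)
}
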