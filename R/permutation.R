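#' Global row permutations
#'
#' Draws L independent uniform permutations of 1..n. The same list must be
#' applied to the missingness matrix for every projection: permuting labels
#' independently per projection destroys the correspondence between
#' projections across permutations and does not hold the level.
#'
#' @param n number of rows.
#' @param L number of permutations.
#' @return list of L integer permutation vectors.
#' @export
sample_row_permutations <- function(n, L) {
  stopifnot(L >= 1L)
  lapply(seq_len(L), function(l) sample.int(n))
}

#' Projection statistic under a row permutation of the missingness matrix
#'
#' Re-evaluates one projection's statistic after globally permuting the rows
#' of the missingness matrix, without refitting the forest. The complete-case
#' set O(A) stays fixed (forest predictions exist only for rows whose A-part
#' is actually observed); only the labels change: row i of O(A) receives the
#' collapsed pattern of row `sigma[i]` of the original matrix restricted to
#' B, matched against the projection's original class patterns. Rows whose
#' permuted pattern is not among the original classes fall into the
#' complement of every class; the forest has no probability column for them,
#' so they can only appear on the mixture side of the statistic. Classes
#' emptied by the permutation are skipped.
#'
#' @param oob the [fit_oob_probabilities()] result fit on the original labels.
#' @param pair the `projection_pair` the forest was fit for.
#' @param m the original [missingness_matrix()].
#' @param sigma an integer permutation of 1..n.
#' @param eps clip bound for [log_odds()].
#' @return the permuted statistic, or `NA_real_` if the projection is
#'   degenerate for this permutation (every class empty).
#' @export
permuted_projection_statistic <- function(oob, pair, m, sigma, eps = 1e-9) {
  perm_lab <- permuted_labels(pair, m, sigma)
  projection_statistic(oob, perm_lab, pair$n_classes, eps)
}

# labels of O(A) under row permutation sigma; 0 = pattern outside the
# original class set
permuted_labels <- function(pair, m, sigma) {
  class_keys <- pattern_keys(pair$class_patterns)
  sub <- unclass(m)[sigma[pair$rows], pair$B, drop = FALSE]
  match(pattern_keys(sub), class_keys, nomatch = 0L)
}

#' Permutation p-value
#'
#' The add-one permutation form Z = (1 + #\{l : pooled permuted statistic >=
#' pooled observed statistic\}) / (L + 1). Ties count as exceedances, which is
#' conservative and preserves finite-sample validity.
#'
#' @param u_hat pooled observed statistic.
#' @param u_perm_pool length-L vector of pooled permuted statistics.
#' @return p-value on the grid \{(1 + k) / (L + 1)\}.
#' @export
perm_pvalue <- function(u_hat, u_perm_pool) {
  L <- length(u_perm_pool)
  (1 + sum(u_perm_pool >= u_hat)) / (L + 1)
}

#' Test the missing-completely-at-random hypothesis
#'
#' Runs the full projected KL test: encode the missingness matrix, sample N
#' projection pairs, fit a probability forest per pair on the complete cases
#' of the feature projection with collapsed missingness-pattern labels,
#' compute the symmetrized out-of-bag log-odds statistic per pair, pool over
#' pairs, and compare against L global row permutations of the missingness
#' matrix to obtain a finite-sample valid p-value. A small p-value is
#' evidence that the distribution of observed values differs across
#' missingness patterns, i.e. against MCAR.
#'
#' The permuted pool for each permutation averages over the projections that
#' are non-degenerate for it; a permutation degenerate on every projection is
#' redrawn once and, if still degenerate, counted as an exceedance
#' (conservative).
#'
#' Reproducibility: one user seed drives three independent child streams
#' (projection sampling, forest fitting, permutations), so changing `nperm`
#' leaves the sampled projections unchanged.
#'
#' @param x an [incomplete_matrix()], or a matrix/data.frame with `NA`s which
#'   is ingested first.
#' @param config a [pklm_config()].
#' @param seed integer seed; `NULL` leaves the R random stream as is.
#' @return an object of class `pklm_test` with components `u_hat`,
#'   `u_perm_pool`, `pvalue`, `u_obs` (per projection), `u_perm`
#'   (projections x permutations, `NA` = degenerate cell), `pairs`,
#'   `partials` (if requested), `n_degenerate_cells`, `config`, `seed`.
#' @examples
#' \donttest{
#' set.seed(7)
#' x <- matrix(rnorm(400), 100, 4)
#' x[sample(length(x), 40)] <- NA
#' res <- pklm_test(x, pklm_config(num_proj = 15, nperm = 20,
#'                                 num_trees_per_proj = 50), seed = 1)
#' res$pvalue
#' }
#' @export
pklm_test <- function(x, config = pklm_config(), seed = NULL) {
  if (!inherits(x, "incomplete_matrix")) x <- incomplete_matrix(x)
  m <- x$m
  n <- nrow(m)
  N <- config$num_proj
  L <- config$nperm
  eps <- config$eps
  constraints <- projection_constraints(config$size_resp_set, config$min_rows,
                                        config$min_class_size,
                                        config$max_attempts)
  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, 3L)

  set.seed(child[1L])
  pairs <- sample_projection_set(m, N, constraints)

  set.seed(child[2L])
  forest_seeds <- sample.int(.Machine$integer.max - 1L, N)
  oobs <- vector("list", N)
  u_obs <- numeric(N)
  for (i in seq_len(N)) {
    pr <- pairs[[i]]
    oobs[[i]] <- fit_oob_probabilities(
      x$values[pr$rows, pr$A, drop = FALSE], pr$labels,
      num_trees = config$num_trees_per_proj,
      min_node_size = config$min_node_size, seed = forest_seeds[i])
    u_obs[i] <- projection_statistic(oobs[[i]], pr$labels, pr$n_classes, eps)
  }
  ok <- is.finite(u_obs)
  if (!all(ok)) {
    warning(sprintf("%d projection(s) degenerate on the observed labels; dropped",
                    sum(!ok)))
    pairs <- pairs[ok]; oobs <- oobs[ok]; u_obs <- u_obs[ok]
    N <- length(pairs)
    if (N == 0L) stop("every projection degenerate; test undefined")
  }

  # L working permutations plus a reserve for fully degenerate columns
  set.seed(child[3L])
  sigmas <- sample_row_permutations(n, 2L * L)
  reserve <- sigmas[(L + 1L):(2L * L)]
  sigmas <- sigmas[seq_len(L)]

  # per-pair precomputation: clipped log-odds and B-pattern keys of all n rows
  lo_mats <- lapply(seq_len(N), function(i) {
    log_odds(oobs[[i]]$probs[, seq_len(pairs[[i]]$n_classes), drop = FALSE], eps)
  })
  keys_all <- lapply(pairs, function(pr) pattern_keys(unclass(m)[, pr$B, drop = FALSE]))
  class_keys <- lapply(pairs, function(pr) pattern_keys(pr$class_patterns))
  perm_stat <- function(i, sigma) {
    pr <- pairs[[i]]
    labs <- match(keys_all[[i]][sigma[pr$rows]], class_keys[[i]], nomatch = 0L)
    proj_stat_from_lo(lo_mats[[i]], oobs[[i]]$covered, labs, pr$n_classes)
  }

  u_perm <- matrix(NA_real_, N, L)
  for (i in seq_len(N)) {
    for (l in seq_len(L)) {
      u_perm[i, l] <- perm_stat(i, sigmas[[l]])
    }
  }
  n_degenerate <- sum(is.na(u_perm))
  if (n_degenerate > 0.1 * length(u_perm)) {
    warning(sprintf("%.1f%% of (projection, permutation) cells degenerate",
                    100 * n_degenerate / length(u_perm)))
  }

  u_hat <- aggregate_statistic(u_obs)
  u_perm_pool <- numeric(L)
  for (l in seq_len(L)) {
    vals <- u_perm[, l]
    if (all(is.na(vals))) {
      # redraw once from the reserve stream, then give up conservatively
      redo <- vapply(seq_len(N), function(i) perm_stat(i, reserve[[l]]),
                     numeric(1L))
      if (all(is.na(redo))) {
        u_perm_pool[l] <- Inf  # counted as >= u_hat
      } else {
        sigmas[[l]] <- reserve[[l]]
        u_perm[, l] <- redo
        u_perm_pool[l] <- mean(redo, na.rm = TRUE)
      }
    } else {
      u_perm_pool[l] <- mean(vals, na.rm = TRUE)
    }
  }

  res <- structure(list(u_hat = u_hat, u_perm_pool = u_perm_pool,
                        pvalue = perm_pvalue(u_hat, u_perm_pool),
                        u_obs = u_obs, u_perm = u_perm, pairs = pairs,
                        partials = NULL, n_degenerate_cells = n_degenerate,
                        n_proj_used = N, n = n, p = ncol(m),
                        config = config, seed = seed),
                   class = "pklm_test")
  if (config$partial) {
    res$partials <- partial_pvalues(res)
  }
  res
}

#' Per-variable partial p-values
#'
#' Localizes an MCAR violation: for each variable k, the test is re-pooled
#' over only those projection pairs whose label-building set B does not
#' contain k (optionally excluding k from A as well). If the violation is
#' driven by the missingness of variable j alone, no projection in the
#' k = j subset ever uses j's patterns as labels, so the partial p-value for
#' j tends to be large while the others stay small. The permuted statistics
#' are reused; no refitting happens.
#'
#' @param result a completed [pklm_test()] result.
#' @param variables integer variable indices; default all columns.
#' @param filter `"B"` or `"AB"`; default taken from the result's config.
#' @return a data.frame with one row per variable: `variable`, `u_hat`
#'   (pooled statistic over the qualifying pairs), `pvalue`, `n_pairs_used`;
#'   `u_hat` and `pvalue` are `NA` (undefined) when no pair qualifies.
#' @export
partial_pvalues <- function(result, variables = NULL, filter = NULL) {
  stopifnot(inherits(result, "pklm_test"))
  if (is.null(filter)) filter <- result$config$partial_filter
  filter <- match.arg(filter, c("B", "AB"))
  if (is.null(variables)) variables <- seq_len(result$p)
  L <- length(result$u_perm_pool)
  out <- data.frame(variable = as.integer(variables), u_hat = NA_real_,
                    pvalue = NA_real_, n_pairs_used = 0L)
  for (r in seq_along(variables)) {
    k <- variables[r]
    idx <- which(vapply(result$pairs, function(pr) {
      excl <- if (filter == "AB") c(pr$A, pr$B) else pr$B
      !(k %in% excl)
    }, logical(1L)))
    out$n_pairs_used[r] <- length(idx)
    if (!length(idx)) next
    u_hat_k <- mean(result$u_obs[idx])
    pool_k <- vapply(seq_len(L), function(l) {
      vals <- result$u_perm[idx, l]
      if (all(is.na(vals))) Inf else mean(vals, na.rm = TRUE)
    }, numeric(1L))
    out$u_hat[r] <- u_hat_k
    out$pvalue[r] <- perm_pvalue(u_hat_k, pool_k)
  }
  out
}

#' @export
print.pklm_test <- function(x, ...) {
  cat("Projected KL test of MCAR\n")
  cat(sprintf("  pooled statistic U = %.4f\n", x$u_hat))
  cat(sprintf("  p-value = %.4f  (N = %d projections, L = %d permutations)\n",
              x$pvalue, x$n_proj_used, length(x$u_perm_pool)))
  if (x$n_degenerate_cells > 0) {
    cat(sprintf("  degenerate (projection, permutation) cells: %d\n",
                x$n_degenerate_cells))
  }
  if (!is.null(x$partials)) {
    cat("  partial p-values:\n")
    print(x$partials, row.names = FALSE)
  }
  invisible(x)
}
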