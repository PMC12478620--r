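#' Generate complete data from the simulation suite
#'
#' Eight multivariate distributions used for level and power studies of the
#' MCAR test. `Sigma_rho` below denotes the p x p matrix with unit diagonal
#' and constant off-diagonal `rho`.
#'
#' \describe{
#'   \item{1}{independent standard normal (identity covariance)}
#'   \item{2}{multivariate normal, covariance `Sigma_rho`}
#'   \item{3}{multivariate t, identity scale, `t_df` degrees of freedom}
#'   \item{4}{multivariate t, scale `Sigma_rho`, `t_df` degrees of freedom}
#'   \item{5}{independent uniform(0, 1) marginals}
#'   \item{6}{case-5 draws mixed by the Cholesky factor of `Sigma_rho`}
#'   \item{7}{componentwise power `Z^power_exponent` of standard normals}
#'   \item{8}{independent Weibull(`weibull_shape`, `weibull_scale`) marginals}
#' }
#'
#' The multivariate t is generated as a Gaussian vector scaled by
#' `sqrt(t_df / chisq(t_df))`. Uses the R random stream; seed with
#' [set.seed()].
#'
#' @param case integer 1..8.
#' @param n rows.
#' @param p columns.
#' @param rho off-diagonal correlation for cases 2, 4, 6 (must keep
#'   `Sigma_rho` positive definite, i.e. `rho > -1/(p-1)`).
#' @param t_df degrees of freedom, cases 3-4.
#' @param power_exponent exponent, case 7.
#' @param weibull_shape,weibull_scale Weibull parameters, case 8.
#' @return an n x p numeric matrix.
#' @export
generate_data <- function(case, n, p, rho = 0.7, t_df = 4,
                          power_exponent = 3, weibull_shape = 1,
                          weibull_scale = 1) {
  stopifnot(case %in% 1:8, n >= 1L, p >= 2L)
  sigma_rho <- function() {
    s <- matrix(rho, p, p); diag(s) <- 1
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("correlation matrix not positive definite for rho = ", rho)
    }
    s
  }
  z <- function() matrix(stats::rnorm(n * p), n, p)
  switch(case,
    z(),                                     # 1
    z() %*% chol(sigma_rho()),               # 2
    z() * sqrt(t_df / stats::rchisq(n, t_df)),                     # 3
    (z() %*% chol(sigma_rho())) * sqrt(t_df / stats::rchisq(n, t_df)),  # 4
    matrix(stats::runif(n * p), n, p),       # 5
    matrix(stats::runif(n * p), n, p) %*% chol(sigma_rho()),       # 6
    z()^power_exponent,                      # 7
    matrix(stats::rweibull(n * p, shape = weibull_shape,
                           scale = weibull_scale), n, p)           # 8
  )
}

na_from_mask <- function(x, m) {
  xna <- x
  xna[m == 1L] <- NA
  im <- incomplete_matrix(as.data.frame(xna))
  list(x = im, m = im$m)
}

#' MCAR amputation
#'
#' Each cell is set missing independently with probability `cell_prob`; rows
#' that come out fully missing are redrawn, since a fully missing observation
#' is never part of the observed dataset.
#'
#' @param x complete numeric matrix.
#' @param cell_prob per-cell missingness probability, in (0, 1).
#' @return list with `x` (an [incomplete_matrix()]) and `m` (the
#'   [missingness_matrix()]).
#' @export
ampute_mcar <- function(x, cell_prob = 0.1) {
  stopifnot(cell_prob > 0, cell_prob < 1)
  n <- nrow(x); p <- ncol(x)
  m <- matrix(stats::rbinom(n * p, 1L, cell_prob), n, p)
  bad <- which(rowSums(m) == p)
  while (length(bad)) {
    m[bad, ] <- stats::rbinom(length(bad) * p, 1L, cell_prob)
    bad <- bad[rowSums(m[bad, , drop = FALSE]) == p]
  }
  na_from_mask(x, m)
}

#' MAR amputation with a fully observed driver column
#'
#' Two-stage mechanism. Stage 1 builds a missingness matrix that is still
#' MCAR: column 1 is all zeros (variable 1 stays fully observed) and every
#' cell of the remaining p - 1 columns is missing with the probability q
#' solving `(1 - q)^(p-1) = r_complete / n`, so that on average `r_complete`
#' rows are fully observed. Stage 2 makes it MAR by pairing mask rows with
#' data rows depending on the driver column: mask rows are split into the
#' complete group (all zeros) and the missing group; each data row whose
#' first-column value exceeds the first-column mean takes a mask row from the
#' complete group with probability 1/6 (and from the missing group with
#' probability 5/6), and vice versa below the mean; when a group runs out,
#' the remaining group is used. Rows above the mean are thus five times more
#' likely to be incomplete.
#'
#' @param x complete numeric matrix.
#' @param r_complete expected number of fully observed rows, in (0, n).
#' @return list with `x` (an [incomplete_matrix()]) and `m` (the
#'   [missingness_matrix()]).
#' @export
ampute_mar_liyu <- function(x, r_complete) {
  n <- nrow(x); p <- ncol(x)
  stopifnot(r_complete > 0, r_complete < n, p >= 2L)
  q <- 1 - (r_complete / n)^(1 / (p - 1))
  m <- cbind(0L, matrix(stats::rbinom(n * (p - 1L), 1L, q), n, p - 1L))

  complete_rows <- which(rowSums(m) == 0L)
  missing_rows <- setdiff(seq_len(n), complete_rows)
  thr <- mean(x[, 1L])
  assigned <- integer(n)
  ci <- 1L; mi <- 1L
  for (i in seq_len(n)) {
    p_complete <- if (x[i, 1L] > thr) 1 / 6 else 5 / 6
    take_complete <- stats::runif(1L) < p_complete
    if (take_complete && ci > length(complete_rows)) take_complete <- FALSE
    if (!take_complete && mi > length(missing_rows)) take_complete <- TRUE
    if (take_complete) {
      assigned[i] <- complete_rows[ci]; ci <- ci + 1L
    } else {
      assigned[i] <- missing_rows[mi]; mi <- mi + 1L
    }
  }
  na_from_mask(x, m[assigned, , drop = FALSE])
}

#' Amputation with one MAR variable and the rest MCAR
#'
#' Variable 1 is set missing for row i exactly when the mean of row i over
#' the remaining variables exceeds `threshold`; variables 2..p receive
#' independent MCAR missingness at `cell_prob`. Variable 1's missingness is a
#' deterministic function of observed values, hence MAR; the joint mechanism
#' violates MCAR through variable 1 alone, the setting in which partial
#' p-values should single it out.
#'
#' @param x complete numeric matrix, p >= 3.
#' @param threshold cut on the row mean of variables 2..p; `Inf` leaves
#'   variable 1 fully observed.
#' @param cell_prob MCAR cell probability for variables 2..p.
#' @return list with `x` (an [incomplete_matrix()]) and `m` (the
#'   [missingness_matrix()]).
#' @export
ampute_mar_partial <- function(x, threshold = 0, cell_prob = 0.1) {
  n <- nrow(x); p <- ncol(x)
  stopifnot(p >= 3L, cell_prob > 0, cell_prob < 1)
  m1 <- as.integer(rowMeans(x[, -1L, drop = FALSE]) > threshold)
  rest <- matrix(stats::rbinom(n * (p - 1L), 1L, cell_prob), n, p - 1L)
  bad <- which(m1 == 1L & rowSums(rest) == p - 1L)
  while (length(bad)) {
    rest[bad, ] <- stats::rbinom(length(bad) * (p - 1L), 1L, cell_prob)
    bad <- bad[rowSums(rest[bad, , drop = FALSE]) == p - 1L]
  }
  na_from_mask(x, cbind(m1, rest))
}

#' Level / power experiment
#'
#' Repeats generate -> ampute -> test `n_reps` times with child seeds derived
#' from `seed`, and reports all p-values plus the fraction at or below
#' `alpha`. Under an MCAR mechanism the rejection rate estimates the type-I
#' error (at most `alpha` up to Monte-Carlo noise, by the validity of the
#' permutation p-value); under a MAR mechanism it estimates power.
#'
#' @param case,n,p,... passed to [generate_data()].
#' @param mechanism `"mcar"`, `"mar_liyu"` or `"mar_partial"`.
#' @param mech_args list of arguments for the amputation function
#'   (e.g. `list(cell_prob = 0.1)` or `list(r_complete = 130)`).
#' @param config a [pklm_config()].
#' @param n_reps replicates.
#' @param alpha nominal level.
#' @param seed integer master seed.
#' @return list with `rejection_rate`, `pvalues` (length `n_reps`, `NA` where
#'   a replicate errored), `errors` (messages per failed replicate), `alpha`.
#' @export
run_experiment <- function(case, n, p, mechanism = c("mcar", "mar_liyu",
                                                     "mar_partial"),
                           mech_args = list(), config = pklm_config(),
                           n_reps = 100L, alpha = 0.05, seed = 1L, ...) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_reps >= 1L)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n_reps)
  amp <- switch(mechanism, mcar = ampute_mcar, mar_liyu = ampute_mar_liyu,
                mar_partial = ampute_mar_partial)
  pvalues <- rep(NA_real_, n_reps)
  errors <- character(0L)
  results <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(child[r])
    xc <- generate_data(case, n, p, ...)
    dat <- do.call(amp, c(list(xc), mech_args))
    res <- tryCatch(pklm_test(dat$x, config, seed = child[r]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, conditionMessage(res))
    } else {
      pvalues[r] <- res$pvalue
      results[[r]] <- res
    }
  }
  list(rejection_rate = mean(pvalues <= alpha, na.rm = TRUE),
       pvalues = pvalues, results = results, errors = errors, alpha = alpha)
}
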