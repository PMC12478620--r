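#' Read an incomplete dataset from delimited text
#'
#' Reads a CSV/TSV file into an [incomplete_matrix()]. Cells matching one of
#' `na_strings` are treated as missing; any other non-numeric content makes a
#' column categorical (so a literal `"NA"` stays a category if `"NA"` is
#' removed from `na_strings`).
#'
#' @param path file path.
#' @param na_strings character vector of missing-value markers.
#' @param sep field separator; `","` for CSV, `"\t"` for TSV.
#' @param header does the first line carry column names?
#' @return an [incomplete_matrix()].
#' @export
read_incomplete_csv <- function(path, na_strings = c("NA", "", "NaN"),
                                sep = ",", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = header, sep = sep,
                          na.strings = na_strings,
                          stringsAsFactors = FALSE,
                          colClasses = NA, fill = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("zero or one usable column in ", path)
  incomplete_matrix(df)
}

#' Write a JSON report of a test result
#'
#' Serializes the pooled statistic, the permuted pool, the p-value, partial
#' p-values if present, the per-projection statistics, degenerate-cell
#' counts, the full configuration and the seed, so that the report alone
#' documents the run. Projection pairs themselves are summarized (A, B,
#' number of rows and classes), not dumped.
#'
#' @param result a [pklm_test()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "pklm_test"))
  rep <- list(
    u_hat = result$u_hat,
    pvalue = result$pvalue,
    n_projections = result$n_proj_used,
    n_permutations = length(result$u_perm_pool),
    u_perm_pool = result$u_perm_pool,
    u_obs = result$u_obs,
    n_degenerate_cells = result$n_degenerate_cells,
    n = result$n, p = result$p,
    projections = lapply(result$pairs, function(pr) {
      list(A = pr$A, B = pr$B, n_rows = length(pr$rows),
           n_classes = pr$n_classes)
    }),
    partials = result$partials,
    config = unclass(result$config),
    seed = result$seed,
    package_version = as.character(utils::packageVersion("pklm"))
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path a report written by [write_report()].
#' @return the report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
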