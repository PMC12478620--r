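#' Construct an incomplete data matrix
#'
#' Wraps a rectangular dataset with missing entries into the container used by
#' [pklm_test()]. Columns may be numeric or categorical; categorical columns
#' are stored as factors and later integer-encoded for the classifier. Rows
#' that are entirely missing and columns that are entirely missing carry no
#' usable information for the test and are dropped with a warning.
#'
#' @param x a matrix or data.frame; missing cells must be `NA`.
#' @return an object of class `incomplete_matrix` with components
#'   \describe{
#'     \item{values}{data.frame of cell values (`NA` = missing), categorical
#'       columns as factors}
#'     \item{kinds}{character vector, `"numeric"` or `"categorical"` per column}
#'     \item{m}{the n x p binary missingness matrix (1 = missing)}
#'     \item{dropped_rows, dropped_cols}{indices removed at ingest}
#'   }
#' @examples
#' x <- data.frame(a = c(1, NA, 3), b = c("u", "v", NA))
#' im <- incomplete_matrix(x)
#' im$m
#' @export
incomplete_matrix <- function(x) {
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(x))
  if (ncol(x) < 2L) stop("need at least 2 columns")
  if (nrow(x) < 1L) stop("need at least 1 row")

  # drop fully-missing rows/columns first (they drive nothing)
  row_all_na <- apply(x, 1L, function(r) all(is.na(r)))
  dropped_rows <- which(row_all_na)
  if (length(dropped_rows)) {
    warning(sprintf("dropping %d fully missing row(s): %s",
                    length(dropped_rows),
                    paste(utils::head(dropped_rows, 10L), collapse = ", ")))
    x <- x[!row_all_na, , drop = FALSE]
  }
  col_all_na <- vapply(x, function(cc) all(is.na(cc)), logical(1L))
  dropped_cols <- which(col_all_na)
  if (length(dropped_cols)) {
    warning(sprintf("dropping %d fully missing column(s): %s",
                    length(dropped_cols),
                    paste(names(x)[dropped_cols], collapse = ", ")))
    x <- x[, !col_all_na, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("fewer than 2 usable columns after ingest")
  if (nrow(x) < 1L) stop("no usable rows after ingest")

  kinds <- vapply(x, function(cc) {
    if (is.numeric(cc)) "numeric" else "categorical"
  }, character(1L))
  for (j in which(kinds == "categorical")) x[[j]] <- factor(x[[j]])

  const_obs <- vapply(x, function(cc) {
    v <- cc[!is.na(cc)]
    length(v) > 0L && length(unique(v)) == 1L
  }, logical(1L))
  if (any(const_obs)) {
    message(sprintf("column(s) constant on observed values (kept): %s",
                    paste(names(x)[const_obs], collapse = ", ")))
  }

  m <- missingness_matrix(ifelse(is.na(as.matrix(x)), 1L, 0L))
  rownames(x) <- NULL
  structure(list(values = x, kinds = kinds, m = m,
                 dropped_rows = dropped_rows, dropped_cols = dropped_cols),
            class = "incomplete_matrix")
}

#' @export
print.incomplete_matrix <- function(x, ...) {
  cat(sprintf("incomplete_matrix: %d rows x %d columns (%d numeric, %d categorical)\n",
              nrow(x$values), ncol(x$values),
              sum(x$kinds == "numeric"), sum(x$kinds == "categorical")))
  cat(sprintf("  missing cells: %d (%.1f%%), distinct patterns: %d\n",
              sum(x$m), 100 * mean(x$m), nrow(encode_patterns(x$m)$patterns)))
  invisible(x)
}

#' Validate a binary missingness matrix
#'
#' @param m an n x p matrix of 0/1 (or logical) entries, 1 = missing. Every
#'   row must have at least one observed cell.
#' @return the validated integer matrix with class `missingness_matrix`.
#' @export
missingness_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("missingness matrix must be binary")
  full <- which(rowSums(m) == ncol(m))
  if (length(full)) {
    stop(sprintf("fully missing row(s) present: %s",
                 paste(utils::head(full, 10L), collapse = ", ")))
  }
  dimnames(m) <- NULL
  class(m) <- c("missingness_matrix", class(m))
  m
}

pattern_keys <- function(m) {
  # compact string key per row; m may have a single column
  if (ncol(m) == 1L) as.character(m[, 1L]) else do.call(paste0, asplit(m, 2L))
}

#' Enumerate missingness-pattern groups
#'
#' Divides the n observations into groups sharing an identical missingness
#' pattern (a distinct row of the missingness matrix). Patterns are ordered by
#' first occurrence, so the result is deterministic.
#'
#' @param m a [missingness_matrix()].
#' @return a list with `patterns` (G x p binary matrix of distinct patterns),
#'   `assignment` (length-n group index per row) and `counts` (rows per group).
#' @examples
#' m <- missingness_matrix(rbind(c(0, 0), c(0, 1), c(0, 1)))
#' encode_patterns(m)
#' @export
encode_patterns <- function(m) {
  keys <- pattern_keys(m)
  first <- !duplicated(keys)
  uk <- keys[first]
  assignment <- match(keys, uk)
  structure(list(patterns = unclass(m)[first, , drop = FALSE],
                 assignment = assignment,
                 counts = tabulate(assignment, nbins = length(uk))),
            class = "pattern_groups")
}

#' Rows fully observed on a projection
#'
#' Returns O(A), the indices of observations whose projection onto the column
#' set `A` contains no missing value, in row order. An empty `A` observes
#' everything.
#'
#' @param m a [missingness_matrix()].
#' @param A integer vector of column indices (1-based); may be empty.
#' @return integer vector of row indices.
#' @export
complete_rows_on <- function(m, A) {
  p <- ncol(m)
  A <- as.integer(A)
  if (length(A) && (any(A < 1L) || any(A > p))) {
    stop("projection indices out of range 1..", p)
  }
  if (!length(A)) return(seq_len(nrow(m)))
  which(rowSums(m[, A, drop = FALSE]) == 0L)
}

#' Collapse missingness patterns on a label-building projection
#'
#' For the rows in `rows`, assigns a class label given by the distinct pattern
#' of the missingness matrix restricted to the columns `B`. Two rows share a
#' label iff they agree on the missingness of every column of B. Labels are
#' numbered 1, 2, ... in order of first occurrence.
#'
#' @param m a [missingness_matrix()].
#' @param rows non-empty integer vector of row indices (typically `O(A)`).
#' @param B non-empty integer vector of column indices, disjoint from the
#'   projection that produced `rows` (the caller enforces disjointness).
#' @return a list with `labels` (class index per element of `rows`),
#'   `n_classes`, and `class_patterns` (n_classes x |B| binary matrix).
#' @export
collapse_labels <- function(m, rows, B) {
  stopifnot(length(rows) > 0L, length(B) > 0L)
  B <- as.integer(B)
  if (any(B < 1L) || any(B > ncol(m))) stop("label projection indices out of range")
  sub <- unclass(m)[rows, B, drop = FALSE]
  keys <- pattern_keys(sub)
  first <- !duplicated(keys)
  uk <- keys[first]
  list(labels = match(keys, uk),
       n_classes = length(uk),
       class_patterns = sub[first, , drop = FALSE])
}
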