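# hand-built out-of-bag probability container
make_oob <- function(probs, covered = rep(TRUE, nrow(probs))) {
  structure(list(probs = probs, covered = covered,
                 class_order = seq_len(ncol(probs))),
            class = "oob_probabilities")
}

# random binary missingness matrix with no fully missing row
rand_miss <- function(n, p, prob = 0.2) {
  m <- matrix(rbinom(n * p, 1L, prob), n, p)
  bad <- which(rowSums(m) == p)
  while (length(bad)) {
    m[bad, ] <- rbinom(length(bad) * p, 1L, prob)
    bad <- bad[rowSums(m[bad, , drop = FALSE]) == p]
  }
  missingness_matrix(m)
}

# missingness matrix containing every pattern except all-missing, each
# `reps` times; with p = 4 and reps = 4 every two-stage projection draw is
# admissible under size_resp_set = 8
all_pattern_miss <- function(p = 4L, reps = 4L) {
  pats <- as.matrix(expand.grid(rep(list(0:1), p)))
  pats <- pats[rowSums(pats) < p, , drop = FALSE]
  missingness_matrix(pats[rep(seq_len(nrow(pats)), each = reps), ])
}
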