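test_that("row permutations are bijections and reproducible", {
  set.seed(301); a <- sample_row_permutations(3L, 2L)
  set.seed(301); b <- sample_row_permutations(3L, 2L)
  expect_identical(a, b)
  expect_length(a, 2L)
  for (s in a) expect_setequal(s, 1:3)
})

test_that("the permutation p-value counts exceedances with the add-one form", {
  expect_equal(perm_pvalue(2.0, c(0.1, -0.3, 2.5, 0.0)), 0.4)
  expect_equal(perm_pvalue(5, rep(1, 10)), 1 / 11)
  expect_equal(perm_pvalue(1, rep(1, 10)), 1)  # ties count as exceedances
})

test_that("the identity permutation reproduces the observed projection statistic exactly", {
  set.seed(302)
  m <- rand_miss(60, 4)
  x <- as.data.frame(matrix(rnorm(240), 60, 4))
  pr <- sample_projection_pair(m, projection_constraints(min_rows = 10L))
  oob <- fit_oob_probabilities(x[pr$rows, pr$A, drop = FALSE], pr$labels,
                               num_trees = 50L, seed = 1L)
  u_obs <- projection_statistic(oob, pr$labels, pr$n_classes, eps = 0.01)
  u_id <- permuted_projection_statistic(oob, pr, m, seq_len(60), eps = 0.01)
  expect_identical(u_id, u_obs)
})

test_that("swapping the two class blocks flips the sign of a binary statistic", {
  oob <- make_oob(cbind(c(0.8, 0.6, 0.3, 0.2), c(0.2, 0.4, 0.7, 0.8)))
  labels <- c(1L, 1L, 2L, 2L)
  swapped <- c(2L, 2L, 1L, 1L)
  expect_equal(projection_statistic(oob, swapped, 2L),
               -projection_statistic(oob, labels, 2L), tolerance = 1e-12)
})

test_that("a permutation importing an unseen pattern routes those rows to the complement of every class", {
  m <- missingness_matrix(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0),
                                c(0, 1, 0), c(1, 1, 0), c(1, 0, 1)))
  # O(A={1}) = rows 1:4; classes on B = {2,3}: "00" and "10"
  pr <- structure(list(A = 1L, B = 2:3, rows = 1:4,
                       labels = c(1L, 1L, 2L, 2L), n_classes = 2L,
                       class_patterns = rbind(c(0L, 0L), c(1L, 0L))),
                  class = "projection_pair")
  oob <- make_oob(cbind(c(0.8, 0.6, 0.3, 0.2), c(0.2, 0.4, 0.7, 0.8)))
  # sigma sends row 4 to row 6, whose B-pattern "01" is unseen
  sigma <- c(1L, 2L, 3L, 6L, 5L, 4L)
  u <- permuted_projection_statistic(oob, pr, m, sigma, eps = 1e-9)
  # class 1 = rows 1,2; class 2 = row 3; row 4 is "other" (complement only)
  u1 <- mean(log_odds(c(0.8, 0.6))) - mean(log_odds(c(0.3, 0.2)))
  u2 <- log_odds(0.7) - mean(log_odds(c(0.2, 0.4, 0.8)))
  expect_equal(u, mean(c(u1, u2)), tolerance = 1e-12)
})

test_that("a permutation emptying every class flags the projection degenerate", {
  # rows 5-6 share the class-1 pattern "00" on B, so sigma below labels all
  # of O(A) as class 1: class 1 has no complement, class 2 no members
  m <- missingness_matrix(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0),
                                c(0, 1, 0), c(1, 0, 0), c(1, 0, 0)))
  pr <- structure(list(A = 1L, B = 2:3, rows = 1:4,
                       labels = c(1L, 1L, 2L, 2L), n_classes = 2L,
                       class_patterns = rbind(c(0L, 0L), c(1L, 0L))),
                  class = "projection_pair")
  oob <- make_oob(cbind(c(0.8, 0.6, 0.3, 0.2), c(0.2, 0.4, 0.7, 0.8)))
  sigma <- c(1L, 2L, 5L, 6L, 3L, 4L)
  expect_true(is.na(permuted_projection_statistic(oob, pr, m, sigma)))
})

test_that("the full test is reproducible, lands on the p-value grid and echoes its config", {
  set.seed(303)
  x <- matrix(rnorm(400), 100, 4)
  x[sample(length(x), 50)] <- NA
  cfg <- pklm_config(num_proj = 10L, nperm = 15L, num_trees_per_proj = 40L)
  r1 <- suppressMessages(pklm_test(x, cfg, seed = 77L))
  r2 <- suppressMessages(pklm_test(x, cfg, seed = 77L))
  expect_identical(r1, r2)
  L <- 15L
  expect_true(r1$pvalue %in% ((1 + 0:L) / (L + 1)))
  expect_equal(r1$u_hat, mean(r1$u_obs))
  for (l in seq_len(L)) {
    expect_equal(r1$u_perm_pool[l], mean(r1$u_perm[, l], na.rm = TRUE))
  }
  expect_equal(r1$config$num_proj, 10L)
  expect_equal(r1$seed, 77L)
})

test_that("changing the permutation count leaves the sampled projections unchanged", {
  set.seed(304)
  x <- matrix(rnorm(400), 100, 4)
  x[sample(length(x), 50)] <- NA
  r1 <- suppressMessages(pklm_test(x, pklm_config(num_proj = 8L, nperm = 5L,
                                                  num_trees_per_proj = 30L),
                                   seed = 5L))
  r2 <- suppressMessages(pklm_test(x, pklm_config(num_proj = 8L, nperm = 12L,
                                                  num_trees_per_proj = 30L),
                                   seed = 5L))
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$u_obs, r2$u_obs)
})

test_that("complete data has no testable missingness structure", {
  x <- matrix(rnorm(100), 25, 4)
  expect_error(suppressMessages(
    pklm_test(x, pklm_config(num_proj = 2L, nperm = 2L, max_attempts = 30L))),
    "no valid projection")
})

test_that("partial p-values degenerate correctly when a variable is always or never a label", {
  # 2-column data: the only admissible pair is A = {1}, B = {2}, so the
  # partial test excluding variable 1 equals the global test, and the one
  # excluding variable 2 is undefined
  set.seed(305)
  x <- data.frame(a = rnorm(60), b = rnorm(60))
  x$b[sample(60, 30)] <- NA
  cfg <- pklm_config(num_proj = 5L, nperm = 10L, num_trees_per_proj = 40L,
                     partial = TRUE)
  res <- suppressMessages(pklm_test(x, cfg, seed = 6L))
  pt <- res$partials
  expect_equal(pt$n_pairs_used[pt$variable == 1L], 5L)
  expect_equal(pt$u_hat[pt$variable == 1L], res$u_hat)
  expect_equal(pt$pvalue[pt$variable == 1L], res$pvalue)
  expect_equal(pt$n_pairs_used[pt$variable == 2L], 0L)
  expect_true(is.na(pt$pvalue[pt$variable == 2L]))
})
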