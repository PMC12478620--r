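test_that("log-odds matches closed forms and clips at the boundary", {
  expect_equal(log_odds(0.5), 0)
  expect_equal(log_odds(0.8), log(4), tolerance = 1e-12)
  expect_equal(log_odds(0, eps = 1e-3), log(1e-3 / 0.999), tolerance = 1e-12)
  expect_equal(log_odds(0, eps = 1e-3), -6.906754779, tolerance = 1e-8)
  expect_equal(log_odds(1, eps = 1e-3), -log_odds(0, eps = 1e-3))
})

test_that("the per-class statistic reproduces the hand-computed value", {
  oob <- make_oob(cbind(c(0.8, 0.6, 0.3, 0.2), c(0.2, 0.4, 0.7, 0.8)))
  labels <- c(1L, 1L, 2L, 2L)
  expect_equal(per_class_statistic(oob, labels, 1L), 2.012675845,
               tolerance = 1e-8)
})

test_that("the two per-class statistics of a binary projection coincide", {
  # log(p/(1-p)) = -log((1-p)/p): both classes carry the same information
  oob <- make_oob(cbind(c(0.8, 0.6, 0.3, 0.2), c(0.2, 0.4, 0.7, 0.8)))
  labels <- c(1L, 1L, 2L, 2L)
  u1 <- per_class_statistic(oob, labels, 1L)
  u2 <- per_class_statistic(oob, labels, 2L)
  expect_equal(u1, u2, tolerance = 1e-12)
  expect_equal(projection_statistic(oob, labels, 2L), u1, tolerance = 1e-12)

  set.seed(201)
  for (rep in 1:10) {
    p1 <- runif(12, 0.01, 0.99)
    oob <- make_oob(cbind(p1, 1 - p1))
    labels <- sample(rep(1:2, 6))
    expect_equal(per_class_statistic(oob, labels, 1L),
                 per_class_statistic(oob, labels, 2L), tolerance = 1e-12)
  }
})

test_that("an uninformative classifier gives a zero statistic", {
  oob <- make_oob(matrix(0.5, 8, 2))
  expect_equal(projection_statistic(oob, rep(1:2, 4), 2L), 0)
})

test_that("the three-class projection statistic averages the hand-computed class values", {
  P <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2), c(0.2, 0.6, 0.2),
             c(0.3, 0.5, 0.2), c(0.1, 0.2, 0.7), c(0.25, 0.25, 0.5))
  labels <- c(1L, 1L, 2L, 2L, 3L, 3L)
  oob <- make_oob(P)
  expect_equal(per_class_statistic(oob, labels, 1L), 1.806006202, tolerance = 1e-8)
  expect_equal(per_class_statistic(oob, labels, 2L), 1.382357272, tolerance = 1e-8)
  expect_equal(per_class_statistic(oob, labels, 3L), 2.012675845, tolerance = 1e-8)
  expect_equal(projection_statistic(oob, labels, 3L), 1.733679773, tolerance = 1e-8)
})

test_that("degenerate classes are skipped, not imputed", {
  P <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2), c(0.2, 0.6, 0.2),
             c(0.3, 0.5, 0.2))
  oob <- make_oob(P)
  labels <- c(1L, 1L, 2L, 2L)  # class 3 empty
  expect_true(is.na(per_class_statistic(oob, labels, 3L)))
  expect_equal(projection_statistic(oob, labels, 3L),
               mean(c(per_class_statistic(oob, labels, 1L),
                      per_class_statistic(oob, labels, 2L))))
  # single non-degenerate class: its value alone
  lab_one <- c(1L, 1L, 1L, 2L)
  oob1 <- make_oob(P[, 1:2])
  expect_equal(projection_statistic(oob1, c(1L, 1L, 1L, 0L), 2L),
               per_class_statistic(oob1, c(1L, 1L, 1L, 0L), 1L))
})

test_that("uncovered rows are excluded from both sides of the statistic", {
  oob <- make_oob(cbind(c(0.8, 0.6, 0.3, 0.2), c(0.2, 0.4, 0.7, 0.8)),
                  covered = c(TRUE, FALSE, TRUE, TRUE))
  labels <- c(1L, 1L, 2L, 2L)
  expect_equal(per_class_statistic(oob, labels, 1L),
               log(4) - mean(log(c(3 / 7, 1 / 4))), tolerance = 1e-12)
})

test_that("pooling is the plain mean and errors on empty input", {
  expect_equal(aggregate_statistic(2), 2)
  expect_equal(aggregate_statistic(c(1, 3)), 2)
  expect_error(aggregate_statistic(numeric(0)), "no projection")
})

test_that("the statistic estimates the symmetrized KL divergence with the true posterior", {
  # two equal-weight Gaussian classes N(0,1) vs N(delta,1): symmetrized KL
  # = delta^2, and the oracle posterior is the density ratio
  set.seed(210)
  delta <- 0.6
  n <- 5000L
  xs <- c(rnorm(n), rnorm(n, delta))
  p1 <- dnorm(xs, 0) / (dnorm(xs, 0) + dnorm(xs, delta))
  oob <- make_oob(cbind(p1, 1 - p1))
  u <- projection_statistic(oob, rep(1:2, each = n), 2L, eps = 1e-12)
  expect_equal(u, delta^2, tolerance = 0.05)
})

test_that("the statistic centers at zero under exchangeable labels", {
  set.seed(211)
  vals <- replicate(200, {
    p1 <- runif(40, 0.05, 0.95)
    oob <- make_oob(cbind(p1, 1 - p1))
    projection_statistic(oob, sample(rep(1:2, 20)), 2L)
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(200))
})
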