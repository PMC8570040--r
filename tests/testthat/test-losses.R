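test_that("epsilon is the inverse of the relative-weight map", {
  expect_equal(epsilon_from_alpha(0), 0)
  expect_equal(epsilon_from_alpha(0.5), 1 / 3)  # solves e/(1-e) = 0.5
  expect_equal(epsilon_from_alpha(1), 0.5)
  # round-trip: alpha -> epsilon -> epsilon/(1-epsilon) recovers alpha
  for (a in c(0.1, 0.25, 2, 10)) {
    e <- epsilon_from_alpha(a)
    expect_equal(e / (1 - e), a, tolerance = 1e-12)
  }
  expect_error(epsilon_from_alpha(-0.1), "domain")
})

test_that("smooth_labels mixes one-hot targets with the uniform distribution", {
  y <- c(0L, 2L, 1L)
  expect_equal(smooth_labels(y, 3, 0),
               rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)))
  expect_equal(smooth_labels(y, 3, 1), matrix(1 / 3, 3, 3))
  expect_equal(smooth_labels(2L, 4, 0.25),
               matrix(c(0.0625, 0.0625, 0.8125, 0.0625), 1))
  expect_true(all(abs(rowSums(smooth_labels(y, 3, 0.37)) - 1) < 1e-12))
  expect_error(smooth_labels(y, 3, 1.2), "domain")
})

test_that("cross-entropy has its closed-form values and obeys Gibbs", {
  p <- smooth_labels(c(0L, 1L), 4, 0)
  q <- matrix(0.25, 2, 4)
  expect_equal(cross_entropy(p, q), log(4), tolerance = 1e-12)
  expect_equal(cross_entropy(p, q, reduction = "sum"), 2 * log(4),
               tolerance = 1e-12)
  expect_lt(cross_entropy(p, p), 1e-10)  # perfect prediction, floored logs
  expect_error(cross_entropy(p, q[, 1:3]), "shape")

  set.seed(1)
  for (r in 1:50) {
    a <- random_simplex(4, 3)
    b <- random_simplex(4, 3)
    entropy_a <- -mean(rowSums(a * log(pmax(a, 1e-12))))
    expect_gte(cross_entropy(a, b) + 1e-12, entropy_a)
  }
})

test_that("the smoothing regularizer is the uniform cross-entropy", {
  q <- matrix(0.25, 3, 4)
  expect_equal(lsr_term(q), log(4), tolerance = 1e-12)
  # minimized exactly at the uniform prediction (convexity, 2-class grid)
  grid <- seq(0.05, 0.95, by = 0.05)
  vals <- sapply(grid, function(p) lsr_term(matrix(c(p, 1 - p), 1)))
  expect_equal(grid[which.min(vals)], 0.5)
  # confident predictions are penalized hard
  expect_gt(lsr_term(matrix(c(1 - 1e-9, 1e-9), 1)), lsr_term(matrix(0.5, 1, 2)))
})

test_that("the two forms of the smoothed cross-entropy agree", {
  set.seed(2)
  for (r in 1:20) {
    M <- sample(2:5, 1); n <- sample(1:8, 1)
    y <- sample(0:(M - 1), n, replace = TRUE)
    q <- random_simplex(n, M)
    a <- runif(1, 0, 3)
    expect_equal(smoothed_cross_entropy(y, q, a, form = "epsilon"),
                 smoothed_cross_entropy(y, q, a, form = "alpha"),
                 tolerance = 1e-10)
  }
  # zero smoothing reduces to the plain cross-entropy
  y <- c(0L, 1L); q <- random_simplex(2, 2)
  expect_identical(smoothed_cross_entropy(y, q, 0),
                   cross_entropy(smooth_labels(y, 2, 0), q))
  # any target against a uniform prediction gives log M
  expect_equal(smoothed_cross_entropy(0L, matrix(0.5, 1, 2),
                                      smoothing_config(0.5)),
               log(2), tolerance = 1e-12)
})

test_that("center loss matches closed forms and a brute-force oracle", {
  bank <- center_bank(2, 2)
  feats <- rbind(c(3, 4), c(0, 0))
  expect_equal(center_loss(feats, c(0L, 1L), bank, reduction = "sum"), 12.5)
  # features sitting on their centers
  bank2 <- center_bank(2, 2, centers = rbind(c(1, 2), c(-1, 0)))
  expect_equal(center_loss(rbind(c(1, 2), c(-1, 0)), c(0L, 1L), bank2), 0)

  set.seed(3)
  for (r in 1:10) {
    n <- sample(2:10, 1); d <- sample(1:6, 1); M <- sample(2:4, 1)
    f <- matrix(rnorm(n * d), n, d)
    y <- sample(0:(M - 1), n, replace = TRUE)
    b <- center_bank(M, d, centers = matrix(rnorm(M * d), M, d))
    brute <- 0
    for (i in seq_len(n))
      for (k in seq_len(d))
        brute <- brute + 0.5 * (f[i, k] - b$centers[y[i] + 1, k])^2
    expect_equal(center_loss(f, y, b, reduction = "sum"), brute,
                 tolerance = 1e-12)
  }
  expect_error(center_loss(matrix(0, 2, 3), c(0L, 1L), center_bank(2, 2)),
               "shape")
})

test_that("center updates are damped means and ignore absent classes", {
  b <- center_bank(3, 2, center_step = 0)
  b2 <- update_centers(b, rbind(c(1, 1)), 0L)
  expect_identical(b2$centers, b$centers)   # zero step

  b <- center_bank(2, 2, center_step = 1,
                   centers = rbind(c(2, 2), c(5, 5)))
  b2 <- update_centers(b, rbind(c(0, 0)), 0L)
  expect_equal(b2$centers[1, ], c(1, 1))    # midpoint of center and sample
  expect_equal(b2$centers[2, ], c(5, 5))    # class 1 absent, untouched

  # fixed-point iteration converges to the within-batch class means
  set.seed(4)
  f <- matrix(rnorm(20 * 3), 20, 3)
  y <- rep(c(0L, 1L), 10)
  b <- center_bank(2, 3, center_step = 0.5)
  for (it in 1:200) b <- update_centers(b, f, y)
  expect_equal(b$centers[1, ], colMeans(f[y == 0L, ]), tolerance = 1e-8)
  expect_equal(b$centers[2, ], colMeans(f[y == 1L, ]), tolerance = 1e-8)
})

test_that("the combined loss is additive in its weighted terms", {
  set.seed(5)
  n <- 6; M <- 3; d <- 4
  y <- sample(0:(M - 1), n, replace = TRUE)
  q <- random_simplex(n, M)
  f <- matrix(rnorm(n * d), n, d)
  b <- center_bank(M, d, centers = matrix(rnorm(M * d), M, d))

  expect_equal(combined_loss(y, q, f, b, loss_weights(0, 0)),
               cross_entropy(smooth_labels(y, M, 0), q), tolerance = 1e-14)

  for (w in list(loss_weights(0.5, 0.5), loss_weights(0.25, 1))) {
    lhs <- combined_loss(y, q, f, b, w) - combined_loss(y, q, f, b, loss_weights(0, 0))
    rhs <- w$alpha_lsr * lsr_term(q) + w$alpha_ct * center_loss(f, y, b)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("the center-loss gradient w.r.t. features matches finite differences", {
  set.seed(6)
  n <- 4; M <- 2; d <- 3
  y <- c(0L, 1L, 1L, 0L)
  q <- random_simplex(n, M)
  f <- matrix(rnorm(n * d), n, d)
  b <- center_bank(M, d, centers = matrix(rnorm(M * d), M, d))
  w <- loss_weights(0.3, 0.7)
  h <- 1e-6
  for (i in 1:n) for (k in 1:d) {
    analytic <- w$alpha_ct * (f[i, k] - b$centers[y[i] + 1, k]) / n
    fp <- f; fp[i, k] <- fp[i, k] + h
    fm <- f; fm[i, k] <- fm[i, k] - h
    fd <- (combined_loss(y, q, fp, b, w) - combined_loss(y, q, fm, b, w)) / (2 * h)
    expect_equal(fd, analytic, tolerance = 1e-4)
  }
})
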