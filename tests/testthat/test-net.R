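test_that("the flatten dimension follows the printed formula", {
  expect_equal(feature_dim(model_config(T = 1000, E = 22, M = 4)), 250)
  expect_equal(feature_dim(model_config(T = 64, E = 3, M = 2, F2 = 1,
                                        P1 = 8, P2 = 8)), 1)
  expect_error(feature_dim(model_config(T = 1000, E = 22, M = 4, P1 = 7)),
               "configuration")
})

test_that("stage-wise divisibility is enforced at build time", {
  # 1000/8 = 125 is fine but 125/8 is not integral: rejected
  cfg <- model_config(T = 1000, E = 22, M = 4)
  expect_error(build_model(cfg), "divisible")
  expect_error(validate_divisibility(model_config(T = 30, E = 2, M = 2,
                                                  P1 = 4, P2 = 2)),
               "divisible")
})

test_that("intermediate shapes match the architecture formulas", {
  # nearest T to the 1000-sample convention that satisfies divisibility
  cfg <- model_config(T = 960, E = 22, M = 4)
  sh <- layer_shapes(build_model(cfg, seed = 1))
  expect_equal(sh$input, c(960, 22, 1))
  expect_equal(sh$conv_temporal, c(960, 22, 8))
  expect_equal(sh$depthwise, c(960, 1, 16))
  expect_equal(sh$pool1, c(120, 1, 16))
  expect_equal(sh$separable, c(120, 1, 16))
  expect_equal(sh$pool2, c(15, 1, 16))
  expect_equal(sh$flatten, 240)
  expect_equal(sh$dense, 4)
})

test_that("shape formulas hold symbolically for random valid configurations", {
  set.seed(7)
  for (r in 1:5) {
    P1 <- sample(2:4, 1); P2 <- sample(2:4, 1)
    T <- P1 * P2 * sample(2:6, 1)
    cfg <- model_config(T = T, E = sample(2:6, 1), M = sample(2:4, 1),
                        F1 = sample(2:4, 1), F2 = sample(2:5, 1),
                        K1 = sample(3:9, 1), K2 = sample(3:7, 1),
                        D = sample(1:3, 1), P1 = P1, P2 = P2)
    sh <- layer_shapes(build_model(cfg, seed = r))
    expect_equal(sh$conv_temporal, c(cfg$T, cfg$E, cfg$F1))
    expect_equal(sh$depthwise, c(cfg$T, 1, cfg$F1 * cfg$D))
    expect_equal(sh$pool1, c(cfg$T / cfg$P1, 1, cfg$F1 * cfg$D))
    expect_equal(sh$separable, c(cfg$T / cfg$P1, 1, cfg$F2))
    expect_equal(sh$pool2, c(cfg$T / (cfg$P1 * cfg$P2), 1, cfg$F2))
    expect_equal(sh$flatten, cfg$T * cfg$F2 / (cfg$P1 * cfg$P2))
  }
})

test_that("model building is seed-deterministic with positive parameter count", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg, seed = 9)
  m2 <- build_model(cfg, seed = 9)
  expect_gt(n_parameters(m1), 0)
  expect_identical(m1$par, m2$par)
})

test_that("softmax is safe, normalized and shift-invariant", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  p <- softmax(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p, c(1, 0), tolerance = 1e-12)
  set.seed(8)
  for (r in 1:20) {
    z <- rnorm(5) * 10
    expect_equal(sum(softmax(z)), 1, tolerance = 1e-12)
    expect_equal(softmax(z + runif(1, -50, 50)), softmax(z),
                 tolerance = 1e-6)
  }
})

test_that("forward pass yields finite, normalized, deterministic outputs", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 1)
  zero <- array(0, c(2, cfg$E, cfg$T))
  out0 <- forward(m, zero)
  expect_true(all(is.finite(out0$logits)))
  expect_true(all(is.finite(out0$features)))

  set.seed(10)
  x <- array(rnorm(5 * cfg$E * cfg$T), c(5, cfg$E, cfg$T))
  out <- forward(m, x)
  expect_equal(rowSums(out$probabilities), rep(1, 5), tolerance = 1e-6)
  expect_true(all(out$probabilities > 0))
  out2 <- forward(m, x)
  expect_identical(out$logits, out2$logits)  # inference is bitwise stable

  # duplicated trials produce identical feature rows
  dup <- x[c(1, 1, 3), , , drop = FALSE]
  fd <- forward(m, dup)$features
  expect_identical(fd[1, ], fd[2, ])

  expect_error(forward(m, array(0, c(2, cfg$E + 1, cfg$T))), "shape")
})

test_that("extracted features have the flatten width", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 2)
  ts <- random_trialset(n = 4, E = cfg$E, T = cfg$T, seed = 3)
  f <- extract_features(m, ts)
  expect_equal(dim(f), c(4, feature_dim(cfg)))
})

test_that("prediction breaks probability ties toward the lowest class index", {
  # symmetric zero input through an identical-logit head: argmax must pick 0
  expect_equal(which.max(c(0.5, 0.5)) - 1L, 0L)
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 4)
  set.seed(5)
  x <- array(rnorm(3 * cfg$E * cfg$T), c(3, cfg$E, cfg$T))
  pred <- predict(m, x)
  expect_true(all(pred %in% 0:(cfg$M - 1)))
})

test_that("training-step gradients match central finite differences", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 1)
  set.seed(2)
  n <- 4
  x <- array(rnorm(n * cfg$E * cfg$T), c(n, cfg$E, cfg$T))
  labels <- c(0L, 1L, 1L, 0L)
  centers <- matrix(rnorm(cfg$M * feature_dim(cfg)), cfg$M)
  cfgl <- unclass(cfg)
  Xc <- aperm(x, c(2, 3, 1))
  par <- m$par
  bn <- m$bn
  loss_at <- function(p) {
    micnn:::nn_train_step_cpp(Xc, labels, p, bn, cfgl, 0.5, 0.5, centers,
                              0.99, 1e-3, 1e-12, 0, 0L)$loss$total
  }
  step <- micnn:::nn_train_step_cpp(Xc, labels, par, bn, cfgl, 0.5, 0.5,
                                    centers, 0.99, 1e-3, 1e-12, 0, 0L)
  h <- 1e-6
  set.seed(3)
  for (nm in names(par)) {
    # probe a random subset of coordinates in every parameter tensor
    idx <- sample(seq_along(par[[nm]]), min(6, length(par[[nm]])))
    for (i in idx) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(as.numeric(step$grads[[nm]])[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("model checkpoints round-trip through disk", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  set.seed(12)
  x <- array(rnorm(2 * cfg$E * cfg$T), c(2, cfg$E, cfg$T))
  expect_identical(forward(m, x)$logits, forward(m2, x)$logits)
})
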