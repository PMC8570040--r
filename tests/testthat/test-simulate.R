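test_that("spatial patterns are seeded, distinct, and non-empty per class", {
  p1 <- make_spatial_patterns(2, 8, seed = 1)
  p2 <- make_spatial_patterns(2, 8, seed = 1)
  expect_identical(p1, p2)

  p <- make_spatial_patterns(4, 22, seed = 3)
  expect_equal(dim(p), c(4, 22))
  expect_equal(nrow(unique(p)), 4)          # pairwise distinct rows
  expect_true(all(rowSums(p >= 0.5) >= 1))  # every class affects a channel

  # with one channel there is a single non-empty mask: two classes impossible
  expect_error(make_spatial_patterns(2, 1, seed = 1), "configuration")
})

test_that("trial synthesis follows the ERD formula in its degenerate cases", {
  pat <- make_spatial_patterns(2, 4, seed = 2)
  cfg <- sim_config(n_classes = 2, trials_per_class = 1, n_channels = 4,
                    n_samples = 200, rhythm_amp = 0, pink_noise_amp = 0,
                    white_noise_amp = 0)
  set.seed(1)
  expect_equal(synthesize_trial(0L, pat, cfg), matrix(0, 4, 200))
  expect_error(synthesize_trial(5L, pat, cfg), "class_id")
})

test_that("full attenuation silences mu-band power down to the noise floor", {
  # one affected and one unaffected channel; with rho = 1 the affected
  # channel keeps only noise in the mu band
  pat <- matrix(c(1, 0), 1, 2)
  cfg <- sim_config(n_classes = 2, trials_per_class = 1, n_channels = 2,
                    n_samples = 500, rho = 1)
  set.seed(4)
  aff <- una <- numeric(20)
  for (r in 1:20) {
    trial <- synthesize_trial(0L, rbind(pat, 0), cfg)
    aff[r] <- band_power(trial[1, ], c(8, 12), 250)
    una[r] <- band_power(trial[2, ], c(8, 12), 250)
  }
  expect_lt(mean(aff), 0.1 * mean(una))
})

test_that("mu-band power on affected channels decreases monotonically in rho", {
  pat <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  pw <- sapply(c(0, 0.4, 0.8), function(r) {
    cfg <- sim_config(n_classes = 2, trials_per_class = 1, n_channels = 4,
                      n_samples = 250, rho = r)
    set.seed(9)
    mean(replicate(50, band_power(synthesize_trial(0L, pat, cfg)[1, ],
                                  c(8, 12), 250)))
  })
  expect_true(all(diff(pw) < 0))
})

test_that("with rho = 0 the signal distribution is class-independent", {
  cfg <- sim_config(n_classes = 2, trials_per_class = 40, n_channels = 4,
                    n_samples = 250, rho = 0, seed = 21)
  ts <- generate_dataset(cfg)
  mu_power <- apply(ts$signals, 1, function(tr) band_power(tr[1, ], c(8, 12), 250))
  m0 <- mean(mu_power[ts$labels == 0])
  m1 <- mean(mu_power[ts$labels == 1])
  expect_lt(abs(m0 - m1) / ((m0 + m1) / 2), 0.25)
})

test_that("dataset generation is balanced, sized, and bitwise reproducible", {
  cfg <- sim_config(n_classes = 4, trials_per_class = 72, n_channels = 4,
                    n_samples = 50, seed = 5)
  ts <- generate_dataset(cfg)
  expect_equal(dim(ts$signals)[1], 288)     # 4 classes x 72 trials
  expect_equal(as.vector(table(ts$labels)), rep(72, 4))

  ts2 <- generate_dataset(cfg)
  expect_identical(ts$signals, ts2$signals)
  expect_identical(ts$labels, ts2$labels)
})

test_that("label noise flips exactly the requested fraction of labels", {
  base_cfg <- sim_config(n_classes = 2, trials_per_class = 50, n_channels = 3,
                         n_samples = 40, seed = 8, label_noise_frac = 0)
  noisy_cfg <- base_cfg
  noisy_cfg$label_noise_frac <- 0.1
  clean <- generate_dataset(base_cfg)
  noisy <- generate_dataset(noisy_cfg)
  expect_identical(clean$signals, noisy$signals)  # only labels are corrupted
  expect_equal(sum(clean$labels != noisy$labels), 10)
})

test_that("band_power integrates the periodogram correctly", {
  fs <- 250; T <- 500
  t <- (0:(T - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  expect_gt(band_power(x, c(8, 12), fs) / band_power(x, c(20, 30), fs), 10)
  expect_equal(band_power(numeric(100), c(8, 12), fs), 0)
  expect_error(band_power(x, c(8, 200), fs), "range")
  expect_error(band_power(x, c(12, 8), fs), "range")

  # flat spectrum: equal-width bands carry equal power on average
  set.seed(2)
  p1 <- p2 <- numeric(200)
  for (r in 1:200) {
    w <- rnorm(T)
    p1[r] <- band_power(w, c(8, 12), fs)
    p2[r] <- band_power(w, c(20, 24), fs)
  }
  expect_lt(abs(mean(p1) / mean(p2) - 1), 0.25)
})

test_that("simulator configuration rejects invalid parameters", {
  expect_error(sim_config(rho = 1.5), "rho")
  expect_error(sim_config(label_noise_frac = -0.1), "label_noise_frac")
  expect_error(sim_config(mu_freq = 200, sampling_rate = 250), "Nyquist")
  expect_error(sim_config(rhythm_amp = -1), "non-negative")
  expect_error(sim_config(n_classes = 1), "n_classes")
})
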