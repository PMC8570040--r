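# shared fixtures: everything is generated in code, nothing is stored on disk

# a minimal but structurally complete network configuration
tiny_cfg <- function() {
  model_config(T = 16, E = 3, M = 2, F1 = 2, F2 = 3, K1 = 5, K2 = 3,
               D = 2, P1 = 2, P2 = 2)
}

# random labeled trial set with balanced classes
random_trialset <- function(n = 6, E = 3, T = 16, M = 2, seed = 1,
                            sampling_rate = 250) {
  set.seed(seed)
  eeg_trialset(array(rnorm(n * E * T), c(n, E, T)),
               labels = rep(seq_len(M) - 1L, length.out = n),
               sampling_rate = sampling_rate,
               class_names = paste0("class", seq_len(M) - 1L))
}

# random rows on the probability simplex
random_simplex <- function(n, M) {
  x <- matrix(rexp(n * M), n, M)
  x / rowSums(x)
}

# small separable synthetic pair used by the cheaper training tests
small_sep_pair <- function(rho = 0.8, noise = 0) {
  cfg <- sim_config(n_classes = 2, trials_per_class = 30, n_channels = 4,
                    n_samples = 128, rho = rho, label_noise_frac = noise,
                    seed = 11)
  tr <- generate_dataset(cfg)
  cfg$seed <- 12L
  cfg$trials_per_class <- 15L
  te <- generate_dataset(cfg)
  list(train = tr, test = te,
       model = model_config(T = 128, E = 4, M = 2, F1 = 4, F2 = 4, K1 = 9,
                            K2 = 5, D = 2, P1 = 4, P2 = 4))
}
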