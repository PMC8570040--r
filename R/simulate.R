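#' Synthetic motor-imagery session configuration
#'
#' Parameters for the synthetic MI EEG generator. Trials are band-limited
#' mu/beta oscillations over 1/f (pink) background noise; class identity
#' enters through event-related desynchronization (ERD): multiplicative
#' attenuation of the rhythm amplitude on a class-specific channel subset.
#' The attenuation strength `rho` is the single separability dial — `rho = 0`
#' makes the classes statistically identical, `rho = 1` silences the rhythm
#' completely on affected channels.
#'
#' Default amplitudes follow typical scalp EEG scales: a ~10 microvolt
#' sensorimotor rhythm over ~5 microvolt (RMS) pink background plus 2
#' microvolt wideband sensor noise.
#'
#' @param n_classes number of MI classes `M` (>= 2).
#' @param trials_per_class trials generated per class.
#' @param n_channels electrode count `E`.
#' @param n_samples samples per trial `T`.
#' @param sampling_rate Hz; 250 by default (the common MI recording rate).
#' @param mu_freq,beta_freq rhythm frequencies in Hz (defaults 10 and 20,
#'   inside the mu 8–12 Hz and beta 12.5–30 Hz bands that carry the MI
#'   signal). Must be below the Nyquist frequency.
#' @param rhythm_amp rhythm amplitude in microvolts.
#' @param rho ERD attenuation in `[0, 1]` applied on class-affected channels.
#' @param pink_noise_amp RMS amplitude of the 1/f background, microvolts.
#' @param white_noise_amp standard deviation of the white sensor noise,
#'   microvolts.
#' @param label_noise_frac fraction of labels reassigned uniformly to a
#'   different class after generation (default 0).
#' @param seed integer seed controlling trial noise, phases and ordering.
#' @param pattern_seed integer seed for the class-to-channel patterns. Kept
#'   separate from `seed` so that train and test sessions generated with
#'   different `seed` values share the same class definitions.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_classes = 2L, trials_per_class = 72L,
                       n_channels = 8L, n_samples = 1000L,
                       sampling_rate = 250, mu_freq = 10, beta_freq = 20,
                       rhythm_amp = 10, rho = 0.8,
                       pink_noise_amp = 5, white_noise_amp = 2,
                       label_noise_frac = 0, seed = 1L,
                       pattern_seed = 1000L) {
  if (!is_count(n_classes, 2L)) stopf("`n_classes` must be an integer >= 2")
  if (!is_count(trials_per_class)) stopf("`trials_per_class` must be a positive integer")
  if (!is_count(n_channels)) stopf("`n_channels` must be a positive integer")
  if (!is_count(n_samples)) stopf("`n_samples` must be a positive integer")
  if (sampling_rate <= 0) stopf("`sampling_rate` must be positive")
  if (rho < 0 || rho > 1) stopf("`rho` must lie in [0, 1]")
  if (label_noise_frac < 0 || label_noise_frac > 1)
    stopf("`label_noise_frac` must lie in [0, 1]")
  if (rhythm_amp < 0 || pink_noise_amp < 0 || white_noise_amp < 0)
    stopf("amplitudes must be non-negative")
  if (mu_freq >= sampling_rate / 2 || beta_freq >= sampling_rate / 2)
    stopf("rhythm frequencies must be below the Nyquist frequency %g Hz",
          sampling_rate / 2)
  structure(list(n_classes = as.integer(n_classes),
                 trials_per_class = as.integer(trials_per_class),
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 sampling_rate = sampling_rate, mu_freq = mu_freq,
                 beta_freq = beta_freq, rhythm_amp = rhythm_amp, rho = rho,
                 pink_noise_amp = pink_noise_amp,
                 white_noise_amp = white_noise_amp,
                 label_noise_frac = label_noise_frac,
                 seed = as.integer(seed),
                 pattern_seed = as.integer(pattern_seed)),
            class = "sim_config")
}

#' Class-to-channel ERD patterns
#'
#' Draws, deterministically for a given seed, one binary channel mask per
#' class: entry `[j, e] = 1` marks channel `e` as attenuated during imagery
#' of class `j`. Rows are pairwise distinct and every class affects at least
#' one channel, so any two classes are separable through band power on some
#' channel.
#'
#' @param M number of classes (>= 2).
#' @param E number of channels (>= 1).
#' @param seed integer seed.
#' @return `M x E` matrix with entries in `{0, 1}`.
#' @export
make_spatial_patterns <- function(M, E, seed) {
  if (!is_count(M, 2L)) stopf("`M` must be an integer >= 2")
  if (!is_count(E)) stopf("`E` must be a positive integer")
  if (M > 2^E - 1)
    stopf("configuration error: cannot draw %d distinct non-empty patterns over %d channels", M, E)
  with_seed(seed, {
    pat <- matrix(0, M, E)
    seen <- character(0)
    for (j in seq_len(M)) {
      for (tries in seq_len(10000L)) {
        row <- as.numeric(runif(E) < 0.5)
        key <- paste(row, collapse = "")
        if (sum(row) >= 1 && !(key %in% seen)) {
          pat[j, ] <- row
          seen <- c(seen, key)
          break
        }
        if (tries == 10000L)
          stopf("configuration error: failed to draw %d distinct patterns", M)
      }
    }
    pat
  })
}

# pink (1/f) noise of length T via inverse-FFT spectral shaping, scaled to a
# given RMS amplitude; consumes the ambient RNG
pink_noise <- function(T, amp) {
  if (amp <= 0 || T < 2) return(numeric(T))
  half <- floor(T / 2)
  spec <- complex(length.out = T)
  k <- seq_len(half)
  mag <- 1 / sqrt(k)                    # power ~ 1/f
  phase <- runif(half, 0, 2 * pi)
  spec[k + 1L] <- mag * exp(1i * phase)
  # hermitian symmetry for a real signal
  idx <- T - k + 1L
  keep <- idx > half + 1L
  spec[idx[keep]] <- Conj(spec[k + 1L][keep])
  if (T %% 2 == 0) spec[half + 1L] <- Re(spec[half + 1L])
  x <- Re(fft(spec, inverse = TRUE)) / T
  s <- sd(x)
  if (s > 0) x <- x / s * amp
  x
}

#' Synthesize one motor-imagery trial
#'
#' Channel `e` of a class-`j` trial is
#' `(1 - rho * pattern[j, e]) * rhythm_amp * (sin(2 pi f_mu t + phi_e) +
#' 0.5 sin(2 pi f_beta t + psi_e))` plus pink and white noise, with fresh
#' random phases per trial and channel. Consumes the ambient RNG; seed at the
#' dataset level via [generate_dataset()].
#'
#' @param class_id 0-based class index in `[0, M)`.
#' @param patterns `M x E` matrix from [make_spatial_patterns()].
#' @param cfg a [sim_config()].
#' @return Numeric matrix `E x T`, microvolts.
#' @export
synthesize_trial <- function(class_id, patterns, cfg) {
  M <- nrow(patterns); E <- ncol(patterns); T <- cfg$n_samples
  if (class_id < 0 || class_id >= M) stopf("`class_id` must lie in [0, %d)", M)
  tt <- (seq_len(T) - 1) / cfg$sampling_rate
  out <- matrix(0, E, T)
  for (e in seq_len(E)) {
    gain <- (1 - cfg$rho * patterns[class_id + 1L, e]) * cfg$rhythm_amp
    phi <- runif(1, 0, 2 * pi)
    psi <- runif(1, 0, 2 * pi)
    rhythm <- sin(2 * pi * cfg$mu_freq * tt + phi) +
      0.5 * sin(2 * pi * cfg$beta_freq * tt + psi)
    out[e, ] <- gain * rhythm +
      pink_noise(T, cfg$pink_noise_amp) +
      rnorm(T, 0, cfg$white_noise_amp)
  }
  out
}

#' Generate a synthetic motor-imagery session
#'
#' Produces a balanced, randomly ordered trial set of
#' `n_classes * trials_per_class` trials, fully determined by `cfg$seed`
#' (class patterns by `cfg$pattern_seed`). If `label_noise_frac > 0`, that
#' fraction of labels (rounded) is reassigned, after generation, uniformly to
#' a different class — the signals still carry the original class, only the
#' label lies.
#'
#' @param cfg a [sim_config()].
#' @return An [eeg_trialset].
#' @examples
#' ts <- generate_dataset(sim_config(n_classes = 2, trials_per_class = 5,
#'                                   n_channels = 4, n_samples = 100))
#' ts
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  M <- cfg$n_classes
  patterns <- make_spatial_patterns(M, cfg$n_channels, cfg$pattern_seed)
  n <- M * cfg$trials_per_class
  with_seed(cfg$seed, {
    labels <- rep(seq_len(M) - 1L, each = cfg$trials_per_class)
    ord <- sample.int(n)
    labels <- labels[ord]
    sig <- array(0, c(n, cfg$n_channels, cfg$n_samples))
    for (i in seq_len(n))
      sig[i, , ] <- synthesize_trial(labels[i], patterns, cfg)
    k <- round(cfg$label_noise_frac * n)
    if (k > 0) {
      flip <- sample.int(n, k)
      for (i in flip) {
        others <- setdiff(seq_len(M) - 1L, labels[i])
        labels[i] <- others[sample.int(length(others), 1L)]
      }
    }
    eeg_trialset(sig, labels, cfg$sampling_rate,
                 class_names = paste0("class", seq_len(M) - 1L))
  })
}

#' Band power of a single-channel signal
#'
#' Integrates the one-sided periodogram over a frequency band — the
#' validation statistic behind the generator: ERD shows up as reduced
#' mu/beta band power on affected channels.
#'
#' @param x numeric vector, one channel of one trial.
#' @param band numeric length-2, `(low, high)` in Hz with
#'   `0 <= low < high <= sampling_rate / 2`.
#' @param sampling_rate Hz.
#' @return Non-negative scalar power.
#' @export
band_power <- function(x, band, sampling_rate) {
  if (length(band) != 2 || band[1] < 0 || band[2] <= band[1] ||
      band[2] > sampling_rate / 2)
    stopf("range error: band must satisfy 0 <= low < high <= %g",
          sampling_rate / 2)
  n <- length(x)
  xf <- fft(x)
  half <- floor(n / 2)
  freqs <- (0:half) * sampling_rate / n
  psd <- (Mod(xf[1:(half + 1L)])^2) / (n * sampling_rate)
  scale <- rep(2, half + 1L)
  scale[1] <- 1
  if (n %% 2 == 0) scale[half + 1L] <- 1
  psd <- psd * scale
  df <- sampling_rate / n
  sel <- freqs >= band[1] & freqs <= band[2]
  sum(psd[sel]) * df
}
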