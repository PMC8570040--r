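#' Network architecture configuration
#'
#' Hyperparameters of the compact EEG CNN: a temporal convolution (`F1`
#' filters, kernel `K1`, length-preserving padding), a depthwise spatial
#' convolution across all `E` electrodes with depth multiplier `D`, and a
#' separable convolution (`F2` filters, kernel `K2`), each followed by batch
#' normalization, with ELU activations and average pooling (`P1`, `P2`) in
#' the second and third blocks, then flatten, dense and softmax.
#'
#' The defaults (`F1 = 8`, `F2 = 16`, `K1 = 32`, `K2 = 16`, `D = 2`,
#' `P1 = P2 = 8`) are the standard settings for 250 Hz MI recordings; the
#' short `K1` (32 samples = 128 ms at 250 Hz) focuses the temporal filters on
#' content above ~8 Hz where the mu/beta MI signal lives. Building a model
#' additionally requires `T` divisible by `P1` and `T/P1` by `P2` so that all
#' pooled lengths are integral ([validate_divisibility()]).
#'
#' @param T samples per trial.
#' @param E electrode count.
#' @param M class count.
#' @param F1 temporal filter count.
#' @param F2 separable filter count.
#' @param K1 temporal kernel length.
#' @param K2 separable kernel length.
#' @param D depth multiplier of the depthwise convolution.
#' @param P1,P2 average-pooling lengths.
#' @return A `model_config` object.
#' @export
model_config <- function(T, E, M, F1 = 8L, F2 = 16L, K1 = 32L, K2 = 16L,
                         D = 2L, P1 = 8L, P2 = 8L) {
  for (nm in c("T", "E", "M", "F1", "F2", "K1", "K2", "D", "P1", "P2")) {
    v <- get(nm)
    if (!is_count(v)) stopf("`%s` must be a positive integer", nm)
  }
  if (M < 2) stopf("`M` must be >= 2")
  structure(list(T = as.integer(T), E = as.integer(E), M = as.integer(M),
                 F1 = as.integer(F1), F2 = as.integer(F2),
                 K1 = as.integer(K1), K2 = as.integer(K2), D = as.integer(D),
                 P1 = as.integer(P1), P2 = as.integer(P2)),
            class = "model_config")
}

#' Penultimate feature dimension
#'
#' Evaluates the flatten-layer formula `T * F2 / (P1 * P2)` and errors if the
#' result is not an integer.
#'
#' @param cfg a [model_config()].
#' @return Integer feature dimension.
#' @examples
#' feature_dim(model_config(T = 1000, E = 22, M = 4))  # 250
#' @export
feature_dim <- function(cfg) {
  num <- cfg$T * cfg$F2
  den <- cfg$P1 * cfg$P2
  if (num %% den != 0)
    stopf("configuration error: T*F2/(P1*P2) = %d/%d is not an integer",
          num, den)
  as.integer(num / den)
}

#' Check pooled-length divisibility
#'
#' A buildable configuration needs every intermediate length to be integral:
#' `T` divisible by `P1` and `T / P1` divisible by `P2`. (This is stricter
#' than [feature_dim()] being integral.)
#'
#' @param cfg a [model_config()].
#' @return `cfg`, invisibly, if valid; otherwise a configuration error.
#' @export
validate_divisibility <- function(cfg) {
  if (cfg$T %% cfg$P1 != 0)
    stopf("configuration error: T = %d is not divisible by P1 = %d",
          cfg$T, cfg$P1)
  if ((cfg$T %/% cfg$P1) %% cfg$P2 != 0)
    stopf("configuration error: T/P1 = %d is not divisible by P2 = %d",
          cfg$T %/% cfg$P1, cfg$P2)
  invisible(cfg)
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_params <- function(cfg) {
  C1 <- cfg$F1 * cfg$D
  d <- feature_dim(cfg)
  list(
    W1 = glorot(cfg$K1, cfg$F1, cfg$K1, cfg$K1 * cfg$F1),
    Wd = glorot(cfg$E, C1, cfg$E, cfg$E * cfg$D),
    Ws = glorot(cfg$K2, C1, cfg$K2, cfg$K2),
    Wp = glorot(C1, cfg$F2, C1, cfg$F2),
    Wfc = glorot(d, cfg$M, d, cfg$M),
    bfc = numeric(cfg$M),
    g1 = rep(1, cfg$F1), b1 = numeric(cfg$F1),
    g2 = rep(1, C1), b2 = numeric(C1),
    g3 = rep(1, cfg$F2), b3 = numeric(cfg$F2))
}

init_bn <- function(cfg) {
  C1 <- cfg$F1 * cfg$D
  list(rm1 = numeric(cfg$F1), rv1 = rep(1, cfg$F1),
       rm2 = numeric(C1), rv2 = rep(1, C1),
       rm3 = numeric(cfg$F2), rv3 = rep(1, cfg$F2))
}

cfg_to_list <- function(cfg) unclass(cfg)

#' Build the CNN model
#'
#' Instantiates the network of [model_config()] with deterministic,
#' seed-controlled Glorot-uniform weight initialization; batch-norm scales
#' start at 1, shifts and running means at 0, running variances at 1.
#' Dropout and max-norm weight constraints are off by default (the printed
#' layer stack has neither) but can be switched on.
#'
#' @param cfg a [model_config()]; must pass [validate_divisibility()].
#' @param seed integer seed for the weight draw.
#' @param dropout optional dropout rate in `[0, 1)` applied after each
#'   pooling layer during training (default 0 = off).
#' @param max_norm optional maximum L2 norm for depthwise and dense weight
#'   columns, enforced after each optimizer step (default `NULL` = off).
#' @return An object of class `mi_cnn`.
#' @export
build_model <- function(cfg, seed = 1L, dropout = 0, max_norm = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  validate_divisibility(cfg)
  if (dropout < 0 || dropout >= 1) stopf("`dropout` must lie in [0, 1)")
  par <- with_seed(seed, init_params(cfg))
  structure(list(config = cfg, par = par, bn = init_bn(cfg),
                 dropout = dropout, max_norm = max_norm, seed = seed),
            class = "mi_cnn")
}

#' @export
print.mi_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<mi_cnn> T=%d E=%d M=%d | F1=%d D=%d F2=%d K1=%d K2=%d P1=%d P2=%d | %d features\n",
    cfg$T, cfg$E, cfg$M, cfg$F1, cfg$D, cfg$F2, cfg$K1, cfg$K2, cfg$P1,
    cfg$P2, feature_dim(cfg)))
  invisible(x)
}

# batch (n x E x T array) -> cube (E, T, n)
batch_to_cube <- function(batch) aperm(batch, c(2, 3, 1))

as_batch_array <- function(x) {
  if (inherits(x, "eeg_trialset")) x$signals
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stopf("shape error: expected an eeg_trialset or an n x E x T array")
}

# inference forward pass, chunked to bound the im2col workspace
infer_pass <- function(par, bn, cfg, batch, chunk = 64L) {
  n <- dim(batch)[1]
  d <- feature_dim(cfg)
  logits <- matrix(0, n, cfg$M)
  probs <- matrix(0, n, cfg$M)
  feats <- matrix(0, n, d)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    ids <- s:min(s + chunk - 1L, n)
    out <- nn_forward_cpp(batch_to_cube(batch[ids, , , drop = FALSE]),
                          par, bn, cfg_to_list(cfg), FALSE, 0.99, 1e-3, 0, 0L)
    logits[ids, ] <- out$logits
    probs[ids, ] <- out$probabilities
    feats[ids, ] <- out$features
  }
  list(logits = logits, probabilities = probs, features = feats)
}

#' Forward pass
#'
#' Runs a batch through the network in inference mode (batch norm uses
#' running statistics, dropout off) and returns logits, softmax class
#' probabilities and the penultimate (flatten-layer) feature vectors.
#'
#' @param model an [build_model()] object.
#' @param batch an [eeg_trialset] or an `n x E x T` numeric array.
#' @return List with `logits` (`n x M`), `probabilities` (`n x M`, rows on
#'   the simplex) and `features` (`n x feature_dim`).
#' @export
forward <- function(model, batch) {
  stopifnot(inherits(model, "mi_cnn"))
  x <- as_batch_array(batch)
  cfg <- model$config
  if (dim(x)[2] != cfg$E || dim(x)[3] != cfg$T)
    stopf("shape error: batch is %d x %d but model expects E=%d, T=%d",
          dim(x)[2], dim(x)[3], cfg$E, cfg$T)
  infer_pass(model$par, model$bn, cfg, x)
}

#' Extract penultimate features
#'
#' Inference-mode flatten-layer activations for every trial — the "deep
#' features" that the center loss regularizes and that the PCA/dispersion
#' analyses inspect.
#'
#' @param model an `mi_cnn`.
#' @param trialset an [eeg_trialset] (or `n x E x T` array).
#' @return `n x feature_dim(cfg)` matrix.
#' @export
extract_features <- function(model, trialset) {
  forward(model, trialset)$features
}

#' Predicted class labels
#'
#' Argmax over class probabilities; exact ties resolve to the lowest class
#' index.
#'
#' @param object an `mi_cnn`.
#' @param newdata an [eeg_trialset] or `n x E x T` array.
#' @param ... unused.
#' @return Integer vector of 0-based labels.
#' @export
predict.mi_cnn <- function(object, newdata, ...) {
  p <- forward(object, newdata)$probabilities
  apply(p, 1L, which.max) - 1L
}

#' Numerically safe softmax
#'
#' `exp(z - max(z)) / sum(exp(z - max(z)))` per row; immune to overflow for
#' large logits.
#'
#' @param z numeric vector of logits, or a matrix with one row per trial.
#' @return Probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) return(t(apply(z, 1L, softmax)))
  ez <- exp(z - max(z))
  ez / sum(ez)
}

#' Intermediate tensor shapes
#'
#' Reports the actual output shape of every stage for a model, in
#' `(time, space, channels)` convention, by pushing a zero trial through the
#' compiled pipeline: input `(T, E, 1)`, temporal conv `(T, E, F1)`,
#' depthwise `(T, 1, F1*D)`, pool `(T/P1, 1, F1*D)`, separable
#' `(T/P1, 1, F2)`, pool `(T/(P1*P2), 1, F2)`, flatten `T*F2/(P1*P2)`,
#' dense `M`.
#'
#' @param model an `mi_cnn`.
#' @return Named list of integer shape vectors.
#' @export
layer_shapes <- function(model) {
  cfg <- model$config
  x <- array(0, c(cfg$E, cfg$T, 1))
  out <- nn_forward_cpp(x, model$par, model$bn, cfg_to_list(cfg), FALSE,
                        0.99, 1e-3, 0, 0L)
  out$shapes
}

#' Count trainable parameters
#'
#' @param model an `mi_cnn`.
#' @return Integer parameter count (convolution, dense, and batch-norm
#'   scale/shift parameters).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$par, length, integer(1)))
}

#' Save / load a model checkpoint
#'
#' Serializes the configuration, weights and batch-norm running statistics.
#'
#' @param model an `mi_cnn`.
#' @param path file path (`.rds`).
#' @return `path` invisibly (save); the restored `mi_cnn` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mi_cnn"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(obj, class = "mi_cnn")
}
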