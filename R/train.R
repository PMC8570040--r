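#' Training configuration
#'
#' Mini-batch training settings for the combined objective. Defaults follow
#' the standard recipe for this architecture: Adam at learning rate 0.001,
#' batch size 64, 750 epochs, loss weights `alpha_lsr = alpha_ct = 0.5`.
#' Batch sizes below 2 are rejected because batch normalization needs batch
#' statistics; the last incomplete batch of an epoch is kept.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size mini-batch size (default 64, minimum 2).
#' @param epochs number of passes over the training set (default 750).
#' @param weights a [loss_weights()] (defaults 0.5 / 0.5).
#' @param seed integer seed covering weight initialization and shuffling.
#' @param center_update_mode `"per_batch"` (default; centers move after every
#'   optimizer step) or `"per_epoch"` (one damped update per epoch from
#'   full-training-set inference features).
#' @param center_step center update step size in `[0, 1]` (default 0.5).
#' @param shuffle reshuffle the training set every epoch (default `TRUE`).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         epochs = 750L, weights = loss_weights(),
                         seed = 1L,
                         center_update_mode = c("per_batch", "per_epoch"),
                         center_step = 0.5, shuffle = TRUE) {
  center_update_mode <- match.arg(center_update_mode)
  if (learning_rate <= 0) stopf("`learning_rate` must be positive")
  if (!is_count(batch_size, 2L))
    stopf("`batch_size` must be an integer >= 2 (batch normalization needs batch statistics)")
  if (!is_count(epochs)) stopf("`epochs` must be a positive integer")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weights = weights,
                 seed = as.integer(seed),
                 center_update_mode = center_update_mode,
                 center_step = center_step, shuffle = isTRUE(shuffle)),
            class = "train_config")
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(dim(par[[nm]]))) g <- as.numeric(g)
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(par = par, state = st)
}

apply_max_norm <- function(par, max_norm) {
  if (is.null(max_norm)) return(par)
  clip_cols <- function(W) {
    nrm <- sqrt(colSums(W^2))
    sc <- pmin(1, max_norm / pmax(nrm, 1e-12))
    sweep(W, 2, sc, "*")
  }
  par$Wd <- clip_cols(par$Wd)
  par$Wfc <- clip_cols(par$Wfc)
  par
}

check_compatible <- function(train_set, test_set, model_cfg) {
  for (s in list(train_set, test_set)) validate_trialset(s)
  dtr <- dim(train_set$signals); dte <- dim(test_set$signals)
  if (!all(dtr[2:3] == dte[2:3]))
    stopf("configuration error: train (%d x %d) and test (%d x %d) trial shapes differ",
          dtr[2], dtr[3], dte[2], dte[3])
  if (train_set$sampling_rate != test_set$sampling_rate)
    stopf("configuration error: sampling rates differ")
  if (dtr[2] != model_cfg$E || dtr[3] != model_cfg$T)
    stopf("configuration error: data are %d x %d but model expects E=%d, T=%d",
          dtr[2], dtr[3], model_cfg$E, model_cfg$T)
  if (length(train_set$class_names) != model_cfg$M)
    stopf("configuration error: %d classes in data but model expects M=%d",
          length(train_set$class_names), model_cfg$M)
}

epoch_metrics <- function(par, bn, cfg, batch, labels, bank, w) {
  out <- infer_pass(par, bn, cfg, batch)
  M <- cfg$M
  cl <- cross_entropy(onehot(labels, M), out$probabilities)
  lsr <- lsr_term(out$probabilities, M)
  ct <- center_loss(out$features, labels, bank)
  acc <- mean(apply(out$probabilities, 1L, which.max) - 1L == labels)
  list(cl = cl, lsr = lsr, ct = ct,
       total = cl + w$alpha_lsr * lsr + w$alpha_ct * ct, acc = acc)
}

#' Train the network with the combined objective
#'
#' Seeded mini-batch training: every step runs a forward pass in training
#' mode, computes the combined loss (cross-entropy + `alpha_lsr` *
#' label-smoothing regularizer + `alpha_ct` * center loss, mean-reduced),
#' takes an Adam gradient step, and then moves the class centers by their
#' damped update rule. After each epoch a learning-curve record is appended:
#' training losses and accuracy as the trial-weighted mean over that epoch's
#' training-mode batches (the convention of mainstream deep-learning
#' histories), test losses and accuracy from a full inference pass. The test
#' set is monitored only; no early stopping or model selection happens on it,
#' and the final-epoch model is returned.
#'
#' All randomness (weight initialization, shuffling) derives from
#' `train_cfg$seed`, and every kernel is deterministic, so identical
#' configurations reproduce identical histories bitwise.
#'
#' @param train_set,test_set [eeg_trialset] objects sharing `E`, `T`, `M`
#'   and sampling rate.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param dropout,max_norm opt-in regularizers passed to [build_model()].
#' @return An object of class `mi_fit`: list with `model` (`mi_cnn`),
#'   `centers` ([center_bank()]), `history` (tibble with one row per epoch:
#'   total and per-term train losses, test losses, accuracies) and
#'   `train_cfg`.
#' @export
train_model <- function(train_set, test_set, model_cfg, train_cfg,
                        dropout = 0, max_norm = NULL) {
  stopifnot(inherits(model_cfg, "model_config"),
            inherits(train_cfg, "train_config"))
  check_compatible(train_set, test_set, model_cfg)
  validate_divisibility(model_cfg)
  cfg <- model_cfg
  cfgl <- cfg_to_list(cfg)
  w <- train_cfg$weights
  n <- dim(train_set$signals)[1]
  d <- feature_dim(cfg)

  Xtr <- batch_to_cube(train_set$signals)   # E x T x n
  ytr <- train_set$labels

  with_seed(train_cfg$seed, {
    par <- init_params(cfg)
    bn <- init_bn(cfg)
    opt <- adam_init(par)
    bank <- center_bank(cfg$M, d, center_step = train_cfg$center_step)

    hist <- vector("list", train_cfg$epochs)
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- if (train_cfg$shuffle) sample.int(n) else seq_len(n)
      starts <- seq(1L, n, by = train_cfg$batch_size)
      # train metrics: trial-weighted epoch mean over training-mode batches
      acc_loss <- c(cl = 0, lsr = 0, ct = 0, total = 0)
      acc_hits <- 0L
      for (s in starts) {
        ids <- ord[s:min(s + train_cfg$batch_size - 1L, n)]
        ds <- if (dropout > 0) sample.int(.Machine$integer.max, 1L) else 0L
        step <- nn_train_step_cpp(
          Xtr[, , ids, drop = FALSE], ytr[ids], par, bn, cfgl,
          w$alpha_lsr, w$alpha_ct, bank$centers,
          0.99, 1e-3, 1e-12, dropout, ds)
        bn <- step$bn
        upd <- adam_step(par, step$grads, opt, train_cfg$learning_rate)
        par <- apply_max_norm(upd$par, max_norm)
        opt <- upd$state
        if (train_cfg$center_update_mode == "per_batch")
          bank <- update_centers(bank, step$features, ytr[ids])
        nb <- length(ids)
        acc_loss <- acc_loss + nb * c(step$loss$cl, step$loss$lsr,
                                      step$loss$ct, step$loss$total)
        acc_hits <- acc_hits +
          sum(apply(step$probabilities, 1L, which.max) - 1L == ytr[ids])
      }
      if (train_cfg$center_update_mode == "per_epoch") {
        feats <- infer_pass(par, bn, cfg, train_set$signals)$features
        bank <- update_centers(bank, feats, ytr)
      }
      mtr <- acc_loss / n
      mte <- epoch_metrics(par, bn, cfg, test_set$signals, test_set$labels,
                           bank, w)
      hist[[ep]] <- tibble::tibble(
        epoch = ep,
        train_loss = mtr[["total"]], train_cl = mtr[["cl"]],
        train_lsr = mtr[["lsr"]], train_ct = mtr[["ct"]],
        train_acc = acc_hits / n,
        test_loss = mte$total, test_cl = mte$cl, test_lsr = mte$lsr,
        test_ct = mte$ct, test_acc = mte$acc)
    }

    model <- structure(list(config = cfg, par = par, bn = bn,
                            dropout = dropout, max_norm = max_norm,
                            seed = train_cfg$seed),
                       class = "mi_cnn")
    history <- do.call(rbind, hist)
    class(history) <- c("train_history", class(history))
    structure(list(model = model, centers = bank, history = history,
                   train_cfg = train_cfg),
              class = "mi_fit")
  })
}

#' @export
print.mi_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<mi_fit> %d epochs | final train acc %.3f, test acc %.3f | test CE %.4f\n",
    nrow(x$history), h$train_acc, h$test_acc, h$test_cl))
  invisible(x)
}

#' @export
tidy.mi_fit <- function(x, ...) tibble::as_tibble(x$history)

#' @export
glance.mi_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history),
                 train_accuracy = h$train_acc, test_accuracy = h$test_acc,
                 train_loss = h$train_loss, test_loss = h$test_loss,
                 test_cross_entropy = h$test_cl,
                 alpha_lsr = x$train_cfg$weights$alpha_lsr,
                 alpha_ct = x$train_cfg$weights$alpha_ct)
}

#' Ablation over a loss weight
#'
#' Trains one model per grid value of `alpha_lsr` or `alpha_ct`, all other
#' settings (including the seed) held fixed, and tabulates final test
#' accuracy — the machinery behind loss-weight sensitivity tables. The
#' final-epoch standard cross-entropy on the test set is reported alongside,
#' as the generalization measure that stays comparable across different loss
#' weights.
#'
#' @param train_set,test_set [eeg_trialset] objects.
#' @param model_cfg a [model_config()].
#' @param base_cfg a [train_config()] supplying every non-varied setting.
#' @param param `"alpha_lsr"` or `"alpha_ct"`.
#' @param values numeric grid of weight values.
#' @param keep_fits also return the fitted models (attribute `"fits"`).
#' @return A tibble of class `mi_ablation` with columns `parameter`,
#'   `value`, `test_accuracy` (in `[0, 1]`), `test_cross_entropy` and
#'   `train_accuracy`.
#' @export
run_ablation <- function(train_set, test_set, model_cfg, base_cfg,
                         param = c("alpha_lsr", "alpha_ct"), values,
                         keep_fits = FALSE) {
  if (!param[1] %in% c("alpha_lsr", "alpha_ct"))
    stopf("configuration error: unknown ablation parameter '%s'", param[1])
  param <- match.arg(param)
  rows <- vector("list", length(values))
  fits <- if (keep_fits) vector("list", length(values))
  for (i in seq_along(values)) {
    w <- base_cfg$weights
    w[[param]] <- values[i]
    cfg_i <- base_cfg
    cfg_i$weights <- w
    fit <- train_model(train_set, test_set, model_cfg, cfg_i)
    h <- fit$history[nrow(fit$history), ]
    rows[[i]] <- tibble::tibble(parameter = param, value = values[i],
                                test_accuracy = h$test_acc,
                                test_cross_entropy = h$test_cl,
                                train_accuracy = h$train_acc)
    if (keep_fits) fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mi_ablation", class(out))
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' @export
tidy.mi_ablation <- function(x, ...) {
  out <- x
  attr(out, "fits") <- NULL
  class(out) <- setdiff(class(out), "mi_ablation")
  tibble::as_tibble(out)
}
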