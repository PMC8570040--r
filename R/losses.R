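#' Smoothing mass from the regularizer weight
#'
#' The smoothed objective can be parameterized either by the mixing mass
#' `epsilon` of the uniform noise distribution or by the relative weight
#' `alpha_lsr = epsilon / (1 - epsilon)` of the label-smoothing regularizer
#' against a unit-weight cross-entropy. This inverts that map:
#' `epsilon = alpha_lsr / (1 + alpha_lsr)`.
#'
#' @param alpha_lsr non-negative regularizer weight.
#' @return `epsilon` in `[0, 1)`.
#' @examples
#' epsilon_from_alpha(0.5)  # 1/3
#' @export
epsilon_from_alpha <- function(alpha_lsr) {
  if (any(alpha_lsr < 0)) stopf("domain error: `alpha_lsr` must be >= 0")
  alpha_lsr / (1 + alpha_lsr)
}

#' Smoothing configuration
#'
#' Bundles the regularizer weight with its derived smoothing mass. Users set
#' `alpha_lsr` only; `epsilon` is always derived, so the two
#' parameterizations of the smoothed objective cannot disagree.
#'
#' @param alpha_lsr non-negative regularizer weight.
#' @return List with `alpha_lsr` and `epsilon`.
#' @export
smoothing_config <- function(alpha_lsr = 0.5) {
  list(alpha_lsr = alpha_lsr, epsilon = epsilon_from_alpha(alpha_lsr))
}

#' Loss weights for the combined objective
#'
#' @param alpha_lsr weight of the label-smoothing regularizer (default 0.5).
#' @param alpha_ct weight of the center loss (default 0.5).
#' @return List with both weights.
#' @export
loss_weights <- function(alpha_lsr = 0.5, alpha_ct = 0.5) {
  if (alpha_lsr < 0 || alpha_ct < 0) stopf("loss weights must be >= 0")
  list(alpha_lsr = alpha_lsr, alpha_ct = alpha_ct)
}

#' Smoothed label distributions
#'
#' Mixes the one-hot target with the uniform distribution:
#' row `i` carries `(1 - epsilon) + epsilon / M` at the true class and
#' `epsilon / M` elsewhere.
#'
#' @param labels 0-based integer labels.
#' @param M number of classes.
#' @param epsilon smoothing mass in `[0, 1]`.
#' @return `n x M` matrix of row distributions.
#' @export
smooth_labels <- function(labels, M, epsilon) {
  if (epsilon < 0 || epsilon > 1) stopf("domain error: `epsilon` must lie in [0, 1]")
  labels <- as.integer(labels)
  if (length(labels) && (min(labels) < 0L || max(labels) >= M))
    stopf("labels must lie in [0, %d)", M)
  out <- matrix(epsilon / M, length(labels), M)
  out[cbind(seq_along(labels), labels + 1L)] <- (1 - epsilon) + epsilon / M
  out
}

onehot <- function(labels, M) smooth_labels(labels, M, 0)

.check_simplex <- function(x, name) {
  if (!is.matrix(x)) stopf("`%s` must be a matrix of row distributions", name)
  invisible(x)
}

.reduce <- function(x, reduction) {
  switch(reduction, mean = mean(x), sum = sum(x),
         stopf("unknown reduction '%s'", reduction))
}

#' Cross-entropy between row distributions
#'
#' `H(p, q) = -sum_y p_y log q_y` per trial, reduced by mean (default) or
#' sum over trials. Predicted probabilities are floored at `floor` before the
#' log so confident-but-wrong predictions stay finite.
#'
#' @param target `n x M` matrix of target distributions.
#' @param predicted `n x M` matrix of predicted distributions.
#' @param reduction `"mean"` or `"sum"` over trials.
#' @param floor lower clip for predicted probabilities (default `1e-12`).
#' @return Scalar loss.
#' @export
cross_entropy <- function(target, predicted, reduction = c("mean", "sum"),
                          floor = 1e-12) {
  reduction <- match.arg(reduction)
  .check_simplex(target, "target"); .check_simplex(predicted, "predicted")
  if (!all(dim(target) == dim(predicted)))
    stopf("shape error: target is %dx%d but predicted is %dx%d",
          nrow(target), ncol(target), nrow(predicted), ncol(predicted))
  per_trial <- -rowSums(target * log(pmax(predicted, floor)))
  .reduce(per_trial, reduction)
}

#' Label-smoothing regularizer
#'
#' The cross-entropy of each prediction against the uniform distribution
#' `u = 1/M`: `-(1/M) sum_y log q_y` per trial. Minimized exactly at the
#' uniform prediction, so it penalizes overconfidence.
#'
#' @param predicted `n x M` matrix of predicted distributions.
#' @param M number of classes (defaults to `ncol(predicted)`).
#' @inheritParams cross_entropy
#' @return Scalar loss.
#' @export
lsr_term <- function(predicted, M = ncol(predicted),
                     reduction = c("mean", "sum"), floor = 1e-12) {
  reduction <- match.arg(reduction)
  .check_simplex(predicted, "predicted")
  per_trial <- -rowSums(log(pmax(predicted, floor))) / M
  .reduce(per_trial, reduction)
}

#' Label-smoothed cross-entropy
#'
#' The classification loss under smoothed targets. Two algebraically equal
#' forms are exposed: `form = "epsilon"` computes the cross-entropy against
#' [smooth_labels()] targets with `epsilon = alpha_lsr / (1 + alpha_lsr)`;
#' `form = "alpha"` computes `(1 - epsilon) * (CE(onehot, q) + alpha_lsr *
#' lsr_term(q))`. Their agreement (to numerical tolerance) is a package
#' invariant.
#'
#' @param labels 0-based integer labels.
#' @param predicted `n x M` matrix of predicted distributions.
#' @param cfg a [smoothing_config()] (or a bare `alpha_lsr` number).
#' @param form which algebraic form to evaluate.
#' @inheritParams cross_entropy
#' @return Scalar loss.
#' @export
smoothed_cross_entropy <- function(labels, predicted, cfg = smoothing_config(),
                                   form = c("epsilon", "alpha"),
                                   reduction = c("mean", "sum"),
                                   floor = 1e-12) {
  form <- match.arg(form)
  reduction <- match.arg(reduction)
  if (is.numeric(cfg)) cfg <- smoothing_config(cfg)
  M <- ncol(predicted)
  if (form == "epsilon") {
    cross_entropy(smooth_labels(labels, M, cfg$epsilon), predicted,
                  reduction, floor)
  } else {
    (1 - cfg$epsilon) *
      (cross_entropy(onehot(labels, M), predicted, reduction, floor) +
         cfg$alpha_lsr * lsr_term(predicted, M, reduction, floor))
  }
}

#' Per-class feature centers
#'
#' Holds the `M x d` matrix of class centers for the center loss together
#' with the center step size used by [update_centers()]. Centers start at
#' zero and are model state, not trainable parameters: the loss gradient
#' flows into features only, and centers move solely through their update
#' rule.
#'
#' @param M number of classes.
#' @param d feature dimension.
#' @param center_step step size `alpha_c` in `[0, 1]` (default 0.5).
#' @param centers optional initial `M x d` matrix (default zeros).
#' @return A `center_bank` object.
#' @export
center_bank <- function(M, d, center_step = 0.5, centers = NULL) {
  if (is.null(centers)) centers <- matrix(0, M, d)
  if (!all(dim(centers) == c(M, d))) stopf("`centers` must be %d x %d", M, d)
  if (center_step < 0 || center_step > 1)
    stopf("`center_step` must lie in [0, 1]")
  structure(list(centers = centers, center_step = center_step),
            class = "center_bank")
}

#' Center loss
#'
#' Half the squared Euclidean distance between each feature vector and its
#' class center, `0.5 * sum_i ||x_i - c_{y_i}||^2`, reduced like the other
#' losses. Minimizing it shrinks intra-class variation of the penultimate
#' features.
#'
#' @param features `n x d` feature matrix (penultimate-layer activations).
#' @param labels 0-based integer labels.
#' @param bank a [center_bank()].
#' @inheritParams cross_entropy
#' @return Non-negative scalar.
#' @export
center_loss <- function(features, labels, bank, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (ncol(features) != ncol(bank$centers))
    stopf("shape error: features have width %d but centers width %d",
          ncol(features), ncol(bank$centers))
  labels <- as.integer(labels)
  if (length(labels) && (min(labels) < 0L || max(labels) >= nrow(bank$centers)))
    stopf("labels must lie in [0, %d)", nrow(bank$centers))
  diff <- features - bank$centers[labels + 1L, , drop = FALSE]
  per_trial <- 0.5 * rowSums(diff^2)
  .reduce(per_trial, reduction)
}

#' Update class centers from a batch
#'
#' For every class `j` with `n_j >= 1` members in the batch, the center moves
#' against the mean residual with a damped step:
#' `delta_j = sum_{i : y_i = j} (c_j - x_i) / (1 + n_j)` and
#' `c_j <- c_j - center_step * delta_j`. Classes absent from the batch are
#' untouched; iterating on a fixed batch converges to the within-batch class
#' means.
#'
#' @inheritParams center_loss
#' @return The updated [center_bank()].
#' @export
update_centers <- function(bank, features, labels) {
  if (ncol(features) != ncol(bank$centers))
    stopf("shape error: features have width %d but centers width %d",
          ncol(features), ncol(bank$centers))
  labels <- as.integer(labels)
  for (j in unique(labels)) {
    idx <- which(labels == j)
    cj <- bank$centers[j + 1L, ]
    resid <- matrix(cj, length(idx), ncol(features), byrow = TRUE) -
      features[idx, , drop = FALSE]
    delta <- colSums(resid) / (1 + length(idx))
    bank$centers[j + 1L, ] <- cj - bank$center_step * delta
  }
  bank
}

#' Combined training objective
#'
#' `L = CE(onehot, q) + alpha_lsr * lsr_term(q) + alpha_ct *
#' center_loss(features)`: the label-smoothed classification loss in its
#' additive form plus the weighted center loss. With both weights zero this
#' is exactly the standard cross-entropy.
#'
#' @param labels 0-based integer labels.
#' @param predicted `n x M` matrix of predicted distributions.
#' @param features `n x d` penultimate feature matrix.
#' @param bank a [center_bank()].
#' @param weights a [loss_weights()].
#' @inheritParams cross_entropy
#' @return Scalar loss.
#' @export
combined_loss <- function(labels, predicted, features, bank,
                          weights = loss_weights(),
                          reduction = c("mean", "sum"), floor = 1e-12) {
  reduction <- match.arg(reduction)
  M <- ncol(predicted)
  cross_entropy(onehot(labels, M), predicted, reduction, floor) +
    weights$alpha_lsr * lsr_term(predicted, M, reduction, floor) +
    weights$alpha_ct * center_loss(features, labels, bank, reduction)
}
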