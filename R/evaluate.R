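#' Classification accuracy
#'
#' Percentage of matching labels, `100 * matches / n`.
#'
#' @param predicted_labels,true_labels equal-length integer vectors.
#' @return Accuracy in percent.
#' @export
accuracy <- function(predicted_labels, true_labels) {
  if (length(predicted_labels) != length(true_labels))
    stopf("shape error: %d predictions for %d labels",
          length(predicted_labels), length(true_labels))
  if (length(true_labels) == 0L) stopf("domain error: empty label vectors")
  100 * mean(predicted_labels == true_labels)
}

#' Paired t-test between two accuracy vectors
#'
#' Classical paired t-test on the per-subject differences (`n - 1` degrees of
#' freedom, two-sided p) — the significance machinery for comparing two
#' methods evaluated on the same subjects.
#'
#' @param acc_a,acc_b equal-length numeric vectors (length >= 2), paired.
#' @return List with `statistic`, `p_value` and `df`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b))
    stopf("shape error: vectors of length %d and %d", length(acc_a),
          length(acc_b))
  if (length(acc_a) < 2) stopf("domain error: need at least 2 pairs")
  d <- acc_a - acc_b
  if (sd(d) == 0)
    stopf("degenerate input: all paired differences are identical")
  tt <- t.test(acc_a, acc_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Project features onto principal axes
#'
#' Covariance PCA on mean-centered (not standardized) features, returning
#' the scores on the top `k` components — used to render high-dimensional
#' penultimate features as 2-D maps. Component signs follow a deterministic
#' convention: each axis is flipped, if needed, so that its
#' largest-magnitude loading is positive.
#'
#' @param features `n x d` numeric matrix.
#' @param k target dimension (default 2).
#' @return `n x k` score matrix with attributes `explained_variance`
#'   (proportion per component) and `rotation` (`d x k` loadings).
#' @export
pca_project <- function(features, k = 2L) {
  features <- as.matrix(features)
  if (nrow(features) < k || ncol(features) < k)
    stopf("domain error: need at least %d rows and columns for a %d-D projection",
          k, k)
  pr <- prcomp(features, center = TRUE, scale. = FALSE)
  k <- as.integer(k)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  sco <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(rot[, j]))
    if (rot[i0, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- pr$sdev^2
  attr(sco, "explained_variance") <- ev[seq_len(k)] / sum(ev)
  attr(sco, "rotation") <- rot
  sco
}

#' Class-dispersion summary of a feature set
#'
#' Quantifies how discriminative a feature embedding is:
#' `intra_class_variance` is the mean over classes of the mean squared
#' distance of members to their class centroid (small = tight classes);
#' `inter_center_distance` is the mean pairwise Euclidean distance between
#' class centroids (large = well-separated classes). Computed on the raw
#' features, never on a PCA projection.
#'
#' @param features `n x d` numeric matrix.
#' @param labels 0-based integer labels; every class in `[0, M)` must have at
#'   least one member.
#' @param M optional class count; defaults to `max(labels) + 1`.
#' @return A `dispersion_summary` list with `intra_class_variance`,
#'   `inter_center_distance` and `n_classes`.
#' @export
class_dispersion <- function(features, labels, M = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stopf("shape error: %d feature rows for %d labels", nrow(features),
          length(labels))
  if (is.null(M)) M <- max(labels) + 1L
  classes <- seq_len(M) - 1L
  if (!all(classes %in% labels))
    stopf("domain error: class %d has no members",
          setdiff(classes, labels)[1])
  centroids <- matrix(0, M, ncol(features))
  intra <- numeric(M)
  for (j in classes) {
    rows <- features[labels == j, , drop = FALSE]
    mu <- colMeans(rows)
    centroids[j + 1L, ] <- mu
    intra[j + 1L] <- mean(rowSums(sweep(rows, 2, mu)^2))
  }
  pairs <- utils::combn(M, 2)
  inter <- mean(sqrt(rowSums((centroids[pairs[1, ], , drop = FALSE] -
                                centroids[pairs[2, ], , drop = FALSE])^2)))
  structure(list(intra_class_variance = mean(intra),
                 inter_center_distance = inter, n_classes = M),
            class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat(sprintf(
    "<dispersion_summary> %d classes | intra-class variance %.4g | inter-center distance %.4g\n",
    x$n_classes, x$intra_class_variance, x$inter_center_distance))
  invisible(x)
}

#' @export
tidy.dispersion_summary <- function(x, ...) {
  tibble::tibble(intra_class_variance = x$intra_class_variance,
                 inter_center_distance = x$inter_center_distance,
                 n_classes = x$n_classes)
}
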