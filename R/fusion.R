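# The fusion stage: concatenate the three per-crown feature blocks
# (RGB class probabilities, good-band reflectance, lidar pseudo-waveform
# features) into one vector, train a shallow multilayer perceptron with the
# differentiable soft F1 loss, and post-process its probability output with
# the open-set "Other" rule.

#' Fusion feature configuration
#'
#' Fixes the expected block lengths of the fusion feature vector. The
#' reference configuration (31 taxa, 369 good bands, 39 bins + total count)
#' gives 31 + 369 + 40 = 440 elements.
#'
#' @param k_classes number of RGB probability entries (taxa).
#' @param n_good_bands reflectance block length.
#' @param n_lidar lidar block length (`n_bins + 1`).
#' @return list with the three block lengths and `total`.
#' @export
fusion_feature_config <- function(k_classes = 31L, n_good_bands = 369L,
                                  n_lidar = 40L) {
  assert_that(k_classes >= 1 && n_good_bands >= 1 && n_lidar >= 1,
              "all blocks must be nonempty")
  list(k_classes = as.integer(k_classes),
       n_good_bands = as.integer(n_good_bands),
       n_lidar = as.integer(n_lidar),
       total = as.integer(k_classes + n_good_bands + n_lidar))
}

#' Assemble one crown's fusion feature vector
#'
#' Concatenation order is fixed: RGB probabilities, then reflectance, then
#' lidar features.
#'
#' @param rgb_probs length-`k_classes` probability vector (sums to 1).
#' @param good_band_values reflectance block.
#' @param lidar_features lidar block from [waveform_features()].
#' @param config a [fusion_feature_config()].
#' @return numeric vector of length `config$total`.
#' @export
assemble_features <- function(rgb_probs, good_band_values, lidar_features,
                              config = fusion_feature_config()) {
  assert_that(length(rgb_probs) == config$k_classes,
              sprintf("rgb block has length %d, expected %d",
                      length(rgb_probs), config$k_classes))
  assert_that(length(good_band_values) == config$n_good_bands,
              sprintf("reflectance block has length %d, expected %d",
                      length(good_band_values), config$n_good_bands))
  assert_that(length(lidar_features) == config$n_lidar,
              sprintf("lidar block has length %d, expected %d",
                      length(lidar_features), config$n_lidar))
  assert_that(abs(sum(rgb_probs) - 1) < 1e-6, "rgb block must sum to 1")
  c(as.numeric(rgb_probs), as.numeric(good_band_values),
    as.numeric(lidar_features))
}

#' Soft F1 loss for one example
#'
#' The differentiable surrogate for `1 - F1` used as the fusion training
#' objective. For `K` classes, a probability vector `theta` and a one-hot
#' label `y`:
#' `L = K^-1 * sum_k [ 1 - 2 theta_k y_k / (2 theta_k y_k + theta_k (1 - y_k) + (1 - theta_k) y_k + epsilon) ]`.
#' Evaluated term by term.
#'
#' @param theta length-`K` probability vector (sums to 1).
#' @param y one-hot label vector of length `K`.
#' @param epsilon small positive constant guarding the denominator
#'   (default `1e-7`).
#' @return scalar loss in `[0, 1]`.
#' @export
soft_f1_loss <- function(theta, y, epsilon = 1e-7) {
  assert_that(length(theta) == length(y), "theta and y lengths differ")
  assert_that(all(y %in% c(0, 1)) && sum(y) == 1, "y must be one-hot")
  assert_that(epsilon > 0, "epsilon must be positive")
  assert_that(all(theta >= 0 & theta <= 1) && abs(sum(theta) - 1) < 1e-6,
              "theta must be a probability vector")
  K <- length(theta)
  denom <- 2 * theta * y + theta * (1 - y) + (1 - theta) * y + epsilon
  mean(1 - 2 * theta * y / denom)
}

#' Fusion network training configuration
#'
#' Defaults follow the reference setup: hidden layers of size 64 and 32,
#' minibatches of 64 examples, 20 epochs of momentum-free stochastic
#' gradient descent under a one-cycle schedule peaking at `1e-2`.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param max_learning_rate one-cycle peak learning rate.
#' @param warmup_frac fraction of steps in the linear warm-up phase.
#' @param loss `"soft_f1"` (default) or `"cross_entropy"`.
#' @param epsilon soft F1 denominator guard.
#' @param seed integer seed controlling initialization and shuffling.
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(hidden_sizes = c(64L, 32L), batch_size = 64L,
                          epochs = 20L, max_learning_rate = 1e-2,
                          warmup_frac = 0.25, loss = c("soft_f1", "cross_entropy"),
                          epsilon = 1e-7, seed = 1L) {
  assert_that(all(hidden_sizes > 0), "hidden sizes must be positive")
  assert_that(max_learning_rate > 0, "max_learning_rate must be positive")
  loss <- match.arg(loss)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 max_learning_rate = max_learning_rate, warmup_frac = warmup_frac,
                 loss = loss, epsilon = epsilon, seed = as.integer(seed)),
            class = "fusion_config")
}

#' Train the fusion network
#'
#' Feature columns are z-scored with training-set statistics (stored in the
#' model) before entering the network; the lidar total-point count would
#' otherwise dwarf the probability and reflectance blocks.
#'
#' @param features numeric matrix, one row per individual.
#' @param labels character (or factor) taxon codes, one per row.
#' @param config a [fusion_config()].
#' @return A `fusion_model` with elements `layers`, `classes`, `center`,
#'   `scale` and `history` (per-epoch mean training loss).
#' @export
train_fusion <- function(features, labels, config = fusion_config()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  assert_that(nrow(features) == length(labels), "one label per feature row required")
  classes <- sort(unique(labels))
  assert_that(length(classes) >= 2, "training requires at least 2 classes")
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  x <- sweep(sweep(features, 2, center), 2, scale, "/")
  fit <- mlp_train(x, match(labels, classes),
                   sizes = c(ncol(x), config$hidden_sizes, length(classes)),
                   epochs = config$epochs, batch_size = config$batch_size,
                   max_lr = config$max_learning_rate, loss = config$loss,
                   epsilon = config$epsilon, warmup_frac = config$warmup_frac,
                   seed = config$seed)
  structure(list(layers = fit$layers, classes = classes, center = center,
                 scale = scale, history = fit$history, config = config),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("fusion_model: %d features -> %s -> %d classes; final training loss %.4f\n",
              length(x$center), paste(x$config$hidden_sizes, collapse = "+"),
              length(x$classes), tail(x$history, 1)))
  invisible(x)
}

#' Predict taxon probabilities with a trained fusion model
#'
#' @param model a `fusion_model` from [train_fusion()].
#' @param features numeric vector (one crown) or matrix (one row per crown).
#' @return Named probability vector over the training classes, or a matrix
#'   with one row per crown; rows sum to 1.
#' @export
predict_taxa <- function(model, features) {
  assert_that(inherits(model, "fusion_model"), "model must come from train_fusion()")
  single <- is.null(dim(features))
  x <- if (single) matrix(features, nrow = 1) else as.matrix(features)
  assert_that(ncol(x) == length(model$center),
              sprintf("feature length %d does not match the model's %d",
                      ncol(x), length(model$center)))
  x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  a <- mlp_forward(model$layers, x)
  probs <- a[[length(a)]]
  colnames(probs) <- model$classes
  if (single) probs[1, ] else probs
}

#' Open-set "Other" post-processing
#'
#' If the maximum class probability is below `threshold`, probability
#' `other_mass` is assigned to an appended `"Other"` class and the original
#' entries are rescaled by `(1 - other_mass)` so the vector still sums to 1;
#' otherwise the vector passes through with `Other = 0`. A maximum exactly
#' equal to the threshold counts as confident. The ranking of the original
#' classes is preserved either way.
#'
#' @param probs normalized probability vector (or matrix, one row per crown).
#' @param threshold confidence threshold in `(0, 1]` (default 0.5).
#' @param other_mass probability assigned to `"Other"` when unconfident
#'   (default 0.5).
#' @return Vector (or matrix) with one extra `"Other"` entry, rows summing to 1.
#' @export
apply_other_threshold <- function(probs, threshold = 0.5, other_mass = 0.5) {
  assert_that(threshold > 0 && threshold <= 1, "threshold must lie in (0, 1]")
  assert_that(other_mass > 0 && other_mass < 1, "other_mass must lie in (0, 1)")
  if (!is.null(dim(probs))) {
    out <- t(apply(probs, 1, apply_other_threshold, threshold = threshold,
                   other_mass = other_mass))
    colnames(out) <- c(colnames(probs), "Other")
    return(out)
  }
  assert_that(all(probs >= 0) && abs(sum(probs) - 1) < 1e-6,
              "input probabilities must be normalized")
  if (max(probs) < threshold) {
    out <- c(probs * (1 - other_mass) / sum(probs), other_mass)
  } else {
    out <- c(probs, 0)
  }
  nm <- names(probs)
  if (is.null(nm)) nm <- rep("", length(probs))
  names(out) <- c(nm, "Other")
  out
}

#' Hard labels from augmented probability vectors
#'
#' Argmax over the augmented (K + 1) vector, ties broken toward the lowest
#' class index.
#'
#' @param probs matrix of augmented probabilities with named columns.
#' @return character vector of predicted labels.
#' @export
hard_labels <- function(probs) {
  probs <- if (is.null(dim(probs))) matrix(probs, nrow = 1,
                                           dimnames = list(NULL, names(probs))) else probs
  colnames(probs)[max.col(probs, ties.method = "first")]
}
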