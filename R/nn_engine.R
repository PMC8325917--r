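# Minimal feed-forward network machinery shared by the fusion network and
# the RGB classification head: dense layers with rectifier activations and
# a softmax output, trained by plain (momentum-free) minibatch stochastic
# gradient descent under a one-cycle learning-rate schedule. Written in
# base R matrix algebra; everything is deterministic given the seed because
# execution is single-threaded.

# He-scaled initialization for a stack of dense layers.
# sizes: c(n_in, hidden..., n_out)
mlp_init <- function(sizes, seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(i) {
      list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1],
                                   sd = sqrt(2 / sizes[i])),
                      sizes[i], sizes[i + 1]),
           b = rep(0, sizes[i + 1]))
    })
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; returns the per-layer activations (a[[1]] = input,
# a[[L+1]] = softmax probabilities).
mlp_forward <- function(layers, x) {
  a <- vector("list", length(layers) + 1)
  a[[1]] <- x
  for (i in seq_along(layers)) {
    z <- a[[i]] %*% layers[[i]]$W + rep(layers[[i]]$b, each = nrow(x))
    a[[i + 1]] <- if (i < length(layers)) pmax(z, 0) else softmax_rows(z)
  }
  a
}

# Gradient of the mean per-example loss with respect to the softmax logits.
# y_idx: integer true-class index per row. theta: softmax output.
loss_logit_grad <- function(theta, y_idx, loss, epsilon = 1e-7) {
  n <- nrow(theta); K <- ncol(theta)
  if (loss == "cross_entropy") {
    g <- theta
    g[cbind(seq_len(n), y_idx)] <- g[cbind(seq_len(n), y_idx)] - 1
    return(g / n)
  }
  # soft F1: per example, only the true-class probability enters the loss;
  # dL/dtheta_t = -2(1+eps) / (K (1 + theta_t + eps)^2), other entries 0.
  th_t <- theta[cbind(seq_len(n), y_idx)]
  g_t <- -2 * (1 + epsilon) / (K * (1 + th_t + epsilon)^2)
  # backprop through softmax: dz_i = theta_i * (g_i - sum_j g_j theta_j)
  dot <- g_t * th_t
  g <- -theta * dot
  g[cbind(seq_len(n), y_idx)] <- g[cbind(seq_len(n), y_idx)] + theta[cbind(seq_len(n), y_idx)] * g_t
  g / n
}

mean_example_loss <- function(theta, y_idx, loss, epsilon = 1e-7) {
  n <- nrow(theta); K <- ncol(theta)
  th_t <- theta[cbind(seq_len(n), y_idx)]
  if (loss == "cross_entropy") {
    return(mean(-log(pmax(th_t, 1e-15))))
  }
  mean(1 - 2 * th_t / (K * (1 + th_t + epsilon)))
}

#' One-cycle learning-rate schedule
#'
#' Linear warm-up from `max_lr / div` to `max_lr` over the first
#' `warmup_frac` of the run, then cosine decay back to `max_lr / (div * 100)`.
#'
#' @param step current step (1-based).
#' @param total_steps total optimization steps.
#' @param max_lr maximum (peak) learning rate.
#' @param warmup_frac fraction of steps spent warming up (default 0.25).
#' @param div initial learning rate divisor (default 25).
#' @return learning rate for `step`.
#' @export
one_cycle_lr <- function(step, total_steps, max_lr, warmup_frac = 0.25, div = 25) {
  warm <- max(1, round(warmup_frac * total_steps))
  lr0 <- max_lr / div
  lr_end <- max_lr / (div * 100)
  if (step <= warm) {
    lr0 + (max_lr - lr0) * (step - 1) / max(1, warm - 1)
  } else {
    t <- (step - warm) / max(1, total_steps - warm)
    lr_end + (max_lr - lr_end) * (1 + cos(pi * t)) / 2
  }
}

# Train a dense softmax network by minibatch SGD.
# x: n x d matrix; y_idx: integer class per row (1..K).
# Returns list(layers, history = per-epoch mean training loss).
mlp_train <- function(x, y_idx, sizes, epochs = 20L, batch_size = 64L,
                      max_lr = 1e-2, loss = "soft_f1", epsilon = 1e-7,
                      warmup_frac = 0.25, seed = 1L) {
  layers <- mlp_init(sizes, seed = seed)
  n <- nrow(x)
  steps_per_epoch <- max(1L, ceiling(n / batch_size))
  total_steps <- epochs * steps_per_epoch
  step <- 0L
  history <- numeric(epochs)
  orders <- withr::with_seed(seed + 1L, {
    lapply(seq_len(epochs), function(e) sample.int(n))
  })
  for (e in seq_len(epochs)) {
    ord <- orders[[e]]
    ep_loss <- 0; ep_n <- 0L
    for (s in seq_len(steps_per_epoch)) {
      step <- step + 1L
      idx <- ord[(((s - 1L) * batch_size + 1L):min(s * batch_size, n))]
      xb <- x[idx, , drop = FALSE]
      yb <- y_idx[idx]
      a <- mlp_forward(layers, xb)
      theta <- a[[length(a)]]
      ep_loss <- ep_loss + mean_example_loss(theta, yb, loss, epsilon) * length(idx)
      ep_n <- ep_n + length(idx)
      dz <- loss_logit_grad(theta, yb, loss, epsilon)
      lr <- one_cycle_lr(step, total_steps, max_lr, warmup_frac)
      for (i in rev(seq_along(layers))) {
        dW <- crossprod(a[[i]], dz)
        db <- colSums(dz)
        if (i > 1) {
          da <- dz %*% t(layers[[i]]$W)
          dz <- da * (a[[i]] > 0)
        }
        layers[[i]]$W <- layers[[i]]$W - lr * dW
        layers[[i]]$b <- layers[[i]]$b - lr * db
      }
    }
    history[e] <- ep_loss / ep_n
  }
  list(layers = layers, history = history)
}
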