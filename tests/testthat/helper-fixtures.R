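# Shared fixtures, all generated in code.

# Solid-color chips with additive Gaussian noise, one color per class.
make_color_chips <- function(n_per_class, colors, labels, h = 24, w = 30,
                             noise_sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    out <- list()
    for (k in seq_along(labels)) {
      for (i in seq_len(n_per_class)) {
        v <- array(rep(colors[[k]], each = h * w), c(h, w, 3)) +
          array(rnorm(h * w * 3, sd = noise_sd), c(h, w, 3))
        out[[length(out) + 1]] <- list(values = pmin(pmax(v, 0), 1),
                                       individual_id = sprintf("%s%03d", labels[k], i),
                                       label = labels[k])
      }
    }
    out
  })
}

# Gaussian class clusters with configurable centroid margin (in noise sds).
make_cluster_features <- function(n_per_class, n_classes, dim, margin_sd = 5,
                                  seed = 1) {
  withr::with_seed(seed, {
    mu <- matrix(rnorm(n_classes * dim), n_classes, dim)
    mu <- mu / sqrt(rowSums(mu^2)) * margin_sd
    X <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
      matrix(rep(mu[k, ], each = n_per_class), n_per_class) +
        matrix(rnorm(n_per_class * dim), n_per_class)
    }))
    list(x = X, labels = rep(LETTERS[seq_len(n_classes)], each = n_per_class),
         centroids = mu)
  })
}

# A small, fast scene configuration (coarser RGB to keep rasters light).
fast_scene_config <- function(n_taxa = 4, seed = 1, ...) {
  scene_config(n_taxa = n_taxa, class_weights = rep(1, n_taxa),
               rgb_resolution = 0.5, crowns_per_plot = c(4L, 6L),
               seed = seed, ...)
}

# Independent type-7 percentile oracle (linear interpolation between order
# statistics), written without stats::quantile.
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  k <- 1 + (p / 100) * (n - 1)
  lo <- floor(k)
  hi <- ceiling(k)
  xs[lo] + (k - lo) * (xs[hi] - xs[lo])
}
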