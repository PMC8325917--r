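test_that("chip standardization yields fixed-size normalized squares", {
  std <- chip_standardization()
  out <- standardize_chip(array(runif(50 * 120 * 3), c(50, 120, 3)), std)
  expect_equal(dim(out), c(224, 224, 3))
  # a 1 x 6 sliver is upsampled without error
  sliver <- standardize_chip(array(runif(1 * 6 * 3), c(1, 6, 3)), std)
  expect_equal(dim(sliver), c(224, 224, 3))

  # identity normalization leaves an already-square 224 chip unchanged
  ident <- chip_standardization(channel_means = c(0, 0, 0),
                                channel_stds = c(1, 1, 1))
  sq <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_equal(standardize_chip(sq, ident), sq, tolerance = 1e-6)
  # and the recipe is idempotent on its own output
  once <- standardize_chip(array(runif(30 * 40 * 3), c(30, 40, 3)), ident)
  expect_equal(standardize_chip(once, ident), once, tolerance = 1e-6)

  # channel normalization applies (value - mean) / std
  const <- array(rep(c(0.5, 0.6, 0.7), each = 224 * 224), c(224, 224, 3))
  norm <- standardize_chip(const, chip_standardization(
    channel_means = c(0.5, 0.5, 0.5), channel_stds = c(0.5, 0.5, 0.5)))
  expect_equal(unique(as.vector(norm[, , 1])), 0, tolerance = 1e-6)
  expect_equal(unique(as.vector(norm[, , 3])), 0.4, tolerance = 1e-6)

  expect_error(standardize_chip(array(0, c(4, 4, 1))), "\\[H, W, 3\\]")
})

test_that("the classifier separates color-distinct classes and is deterministic", {
  chips <- make_color_chips(60, list(c(0.8, 0.2, 0.2), c(0.2, 0.7, 0.3)),
                            c("RED", "GRN"), seed = 3)
  cfg <- rgb_train_config(seed = 4, epochs = 8)
  m <- fit_rgb_classifier(chips, cfg)
  expect_gte(m$val_accuracy, 0.9)

  p <- predict_rgb_probs(m, chips[[1]]$values)
  expect_length(p, 2)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_setequal(names(p), c("RED", "GRN"))
  expect_identical(p, predict_rgb_probs(m, chips[[1]]$values))

  m2 <- fit_rgb_classifier(chips, cfg)
  expect_identical(m$val_macro_f1, m2$val_macro_f1)
  expect_identical(m$history, m2$history)

  expect_error(fit_rgb_classifier(chips[1:10], cfg), "2 classes")
})

test_that("probability vectors cover K classes for K-class training data", {
  chips <- make_color_chips(12, list(c(0.9, 0.1, 0.1), c(0.1, 0.9, 0.1),
                                     c(0.1, 0.1, 0.9), c(0.6, 0.6, 0.1)),
                            c("C1", "C2", "C3", "C4"), h = 16, w = 16, seed = 6)
  m <- fit_rgb_classifier(chips, rgb_train_config(seed = 2, epochs = 2))
  p <- predict_rgb_probs(m, chips[[5]]$values)
  expect_length(p, 4)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("backbone comparison selects the macro-F1 argmax, smaller depth on ties", {
  chips <- make_color_chips(16, list(c(0.9, 0.1, 0.1), c(0.1, 0.9, 0.1)),
                            c("R", "G"), h = 16, w = 16, noise_sd = 0.02, seed = 8)
  cfg <- rgb_train_config(seed = 3, epochs = 6)
  tab <- compare_backbones(c(18, 34), chips, cfg)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$depth, c("18", "34"))
  best <- attr(tab, "selected")
  expect_equal(tab$macro_f1[tab$depth == best], max(tab$macro_f1))
  if (tab$macro_f1[tab$depth == "18"] == tab$macro_f1[tab$depth == "34"]) {
    expect_equal(best, "18")  # tie broken toward the cheaper backbone
  }
  single <- compare_backbones("small", chips, cfg)
  expect_equal(attr(single, "selected"), "small")
})
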