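test_that("feature assembly enforces the configured block lengths", {
  cfg <- fusion_feature_config()  # 31 + 369 + 40
  v <- assemble_features(rep(1 / 31, 31), runif(369), runif(40), cfg)
  expect_length(v, 440)
  toy <- fusion_feature_config(2, 3, 4)
  expect_length(assemble_features(c(0.5, 0.5), 1:3, 1:4, toy), 9)
  expect_error(assemble_features(rep(1 / 31, 31), runif(368), runif(40), cfg),
               "reflectance block")
  expect_error(assemble_features(rep(1, 31), runif(369), runif(40), cfg),
               "sum to 1")
})

test_that("the soft F1 loss matches its closed form and boundary values", {
  # zero probability on the true class: every numerator is 0, so L = 1 exactly
  expect_identical(soft_f1_loss(c(0, 0.4, 0.6), c(1, 0, 0)), 1)
  # perfect 2-class prediction: true term ~ 1 - 2/(2 + eps), other term 1
  expect_equal(soft_f1_loss(c(1, 0), c(1, 0)), 0.5, tolerance = 1e-6)
  # randomized equivalence with the one-hot closed form
  withr::with_seed(31, {
    for (i in 1:50) {
      K <- sample(2:40, 1)
      th <- runif(K); th <- th / sum(th)
      t <- sample(K, 1); y <- rep(0, K); y[t] <- 1
      eps <- 1e-7
      closed <- 1 - 2 * th[t] / (K * (1 + th[t] + eps))
      expect_equal(soft_f1_loss(th, y, eps), closed, tolerance = 1e-12)
    }
  })
  expect_error(soft_f1_loss(c(0.5, 0.5), c(1, 1)), "one-hot")
  expect_error(soft_f1_loss(c(0.7, 0.7), c(1, 0)), "probability")
})

test_that("the loss depends only on the true-class probability, decreasingly", {
  K <- 5
  grid <- seq(0, 1, by = 0.05)
  losses <- vapply(grid, function(tt) {
    rest <- rep((1 - tt) / (K - 1), K - 1)
    soft_f1_loss(c(tt, rest), c(1, rep(0, K - 1)))
  }, 0)
  expect_true(all(diff(losses) < 0))
  # redistributing the off-class mass leaves the loss unchanged
  l1 <- soft_f1_loss(c(0.4, 0.6, 0, 0, 0), c(1, 0, 0, 0, 0))
  l2 <- soft_f1_loss(c(0.4, 0.1, 0.3, 0.1, 0.1), c(1, 0, 0, 0, 0))
  expect_equal(l1, l2, tolerance = 1e-12)
  # minimum achievable per-example loss approaches (K-1)/K
  for (K in c(2, 5, 31)) {
    at_one <- soft_f1_loss(c(1, rep(0, K - 1)), c(1, rep(0, K - 1)))
    expect_equal(at_one, 1 - 2 / (K * (2 + 1e-7)), tolerance = 1e-12)
    expect_equal(at_one, (K - 1) / K, tolerance = 1e-4)
  }
})

test_that("the fusion network separates well-margined classes", {
  data <- make_cluster_features(300, 3, 25, margin_sd = 5, seed = 33)
  # the separation is real: a nearest-centroid oracle is near-perfect
  d2 <- as.matrix(dist(rbind(data$centroids, data$x)))[-(1:3), 1:3]
  oracle_acc <- mean(LETTERS[apply(d2, 1, which.min)] == data$labels)
  expect_gte(oracle_acc, 0.99)

  sp <- split_individuals(data.frame(i = seq_len(nrow(data$x))), 0.8, seed = 2)
  fm <- train_fusion(data$x[sp$train$i, ], data$labels[sp$train$i],
                     fusion_config(seed = 5, epochs = 60, max_learning_rate = 0.05))
  probs <- predict_taxa(fm, data$x[sp$holdout$i, ])
  acc <- mean(colnames(probs)[max.col(probs)] == data$labels[sp$holdout$i])
  expect_gte(acc, 0.9)
  # training sanity: epoch-20 mean loss no worse than epoch-1
  expect_lte(tail(fm$history, 1), fm$history[1])
  # determinism: identical seeds give identical losses and predictions
  fm2 <- train_fusion(data$x[sp$train$i, ], data$labels[sp$train$i],
                      fusion_config(seed = 5, epochs = 60, max_learning_rate = 0.05))
  expect_identical(fm$history, fm2$history)
  expect_identical(probs, predict_taxa(fm2, data$x[sp$holdout$i, ]))

  expect_error(train_fusion(data$x, rep("A", nrow(data$x))), "2 classes")
})

test_that("predicted probability vectors are normalized and repeatable", {
  data <- make_cluster_features(30, 4, 10, seed = 35)
  fm <- train_fusion(data$x, data$labels, fusion_config(epochs = 5, seed = 1))
  p1 <- predict_taxa(fm, data$x[1, ])
  expect_length(p1, 4)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, predict_taxa(fm, data$x[1, ]))
  pm <- predict_taxa(fm, data$x[1:7, ])
  expect_equal(unname(rowSums(pm)), rep(1, 7), tolerance = 1e-6)
  expect_error(predict_taxa(fm, runif(3)), "feature length")
})

test_that("the open-set rule assigns mass 0.5 to Other only when unconfident", {
  out <- apply_other_threshold(c(0.4, 0.3, 0.3))
  expect_equal(unname(out), c(0.2, 0.15, 0.15, 0.5))
  expect_equal(names(out)[4], "Other")

  conf <- apply_other_threshold(c(0.7, 0.2, 0.1))
  expect_equal(unname(conf), c(0.7, 0.2, 0.1, 0))

  # a maximum of exactly 0.5 is not "less than 0.5": pass through
  edge <- apply_other_threshold(c(0.5, 0.25, 0.25))
  expect_equal(unname(edge), c(0.5, 0.25, 0.25, 0))

  withr::with_seed(37, {
    for (i in 1:25) {
      K <- sample(2:31, 1)
      p <- runif(K); p <- p / sum(p)
      aug <- apply_other_threshold(p)
      expect_equal(sum(aug), 1, tolerance = 1e-6)
      expect_true(all(aug >= 0))
      # original class ranking preserved
      expect_identical(order(aug[seq_len(K)]), order(p))
      if (max(p) < 0.5) expect_identical(unname(aug[K + 1]), 0.5)
      else expect_identical(unname(aug[K + 1]), 0)
    }
  })
  expect_error(apply_other_threshold(c(0.9, 0.9)), "normalized")
})
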