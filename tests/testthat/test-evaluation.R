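test_that("confusion matrices count pairs and group out-of-sample taxa", {
  truth <- c("A", "B", "C", "A", "B", "C")
  cm <- confusion_matrix(truth, truth, class_order = c("A", "B", "C"))
  expect_equal(diag(cm), c(A = 2L, B = 2L, C = 2L))
  expect_equal(sum(cm), 6)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))

  cm2 <- confusion_matrix(c("A", "ZZZZ"), c("A", "A"),
                          class_order = c("A", "B"), reduce_unknown = TRUE)
  expect_equal(cm2["Other", "A"], 1L)
  expect_equal(sum(cm2), 2)
  expect_error(confusion_matrix(c("A", "ZZZZ"), c("A", "A"),
                                class_order = c("A", "B")), "outside class_order")
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(f1_from_pr(0.65, 0.80791), 0.720403, tolerance = 5e-6)
  for (x in c(0, 0.3, 0.77, 1)) expect_equal(f1_from_pr(x, x), x)
  expect_equal(f1_from_pr(0, 0.9), 0)
  expect_equal(f1_from_pr(0, 0), 0)
  expect_equal(f1_from_pr(c(0.5, 0), c(0.5, 0)), c(0.5, 0))
})

test_that("score reports match direct counting on random label sets", {
  withr::with_seed(41, {
    for (i in 1:10) {
      classes <- LETTERS[1:sample(3:6, 1)]
      n <- sample(20:80, 1)
      truth <- sample(classes, n, replace = TRUE)
      probs <- matrix(runif(n * length(classes)), n)
      probs <- probs / rowSums(probs)
      colnames(probs) <- classes
      rep_ <- score_report(truth, probs)
      pred <- classes[max.col(probs, ties.method = "first")]
      for (k in seq_along(classes)) {
        cl <- classes[k]
        tp <- sum(truth == cl & pred == cl)
        expect_equal(rep_$per_class$recall[k],
                     if (sum(truth == cl) == 0) 0 else tp / sum(truth == cl))
        expect_equal(rep_$per_class$precision[k],
                     if (sum(pred == cl) == 0) 0 else tp / sum(pred == cl))
        expect_equal(rep_$per_class$support[k], sum(truth == cl))
      }
      expect_equal(rep_$accuracy, mean(pred == truth))
      expect_equal(rep_$accuracy,
                   sum(diag(rep_$confusion)) / sum(rep_$confusion))
      expect_gte(max(rep_$per_class$f1), rep_$macro_f1)
      expect_lte(min(rep_$per_class$f1), rep_$macro_f1)
    }
  })
})

test_that("cross-entropy of uniform 31-class probabilities is ln 31", {
  n <- 40
  probs <- matrix(1 / 31, n, 31,
                  dimnames = list(NULL, sprintf("T%02d", 1:31)))
  truth <- sample(colnames(probs), n, replace = TRUE)
  rep_ <- score_report(truth, probs)
  expect_equal(rep_$cross_entropy, log(31), tolerance = 1e-12)
})

test_that("zero-support classes stay in the report and the macro average", {
  probs <- matrix(c(0.9, 0.05, 0.05,
                    0.1, 0.8, 0.1), 2, 3, byrow = TRUE,
                  dimnames = list(NULL, c("A", "B", "C")))
  rep_ <- score_report(c("A", "B"), probs)
  expect_equal(nrow(rep_$per_class), 3)
  expect_equal(rep_$per_class$support[3], 0)
  expect_equal(rep_$per_class$f1[3], 0)
  expect_equal(rep_$macro_f1, mean(c(1, 1, 0)))
  # weighted average ignores the unsupported class
  expect_equal(rep_$weighted_f1, 1)

  dir <- withr::local_tempdir()
  write_score_report(rep_, file.path(dir, "rep"))
  expect_true(all(file.exists(file.path(dir, c("rep.csv", "rep.json",
                                               "rep_confusion.csv")))))
  csv <- read.csv(file.path(dir, "rep.csv"))
  expect_equal(tail(csv$class, 3), c("accuracy", "macro avg", "weighted avg"))
})

test_that("the shipped benchmark report is internally consistent", {
  tab <- competition_test_report()
  expect_equal(nrow(tab), 27)
  expect_equal(sum(tab$support), 585)
  expect_equal(f1_from_pr(tab$precision, tab$recall), tab$f1, tolerance = 5e-6)
})
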