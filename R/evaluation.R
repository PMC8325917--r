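# Competition-style evaluation: confusion matrices (optionally grouping
# out-of-sample taxa into "Other"), per-class precision/recall/F1/support,
# macro and support-weighted F1, accuracy, and categorical cross-entropy.
# Zero-denominator precision/recall/F1 are reported as 0, and classes with
# zero support still appear in the report and in the macro average.

#' F1 score from precision and recall
#'
#' The harmonic mean `2pr/(p + r)`, defined as 0 when `p + r = 0`.
#' Vectorized.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return numeric vector of F1 scores.
#' @export
f1_from_pr <- function(precision, recall) {
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / ifelse(s == 0, 1, s))
}

#' Confusion matrix over a fixed class order
#'
#' @param true_labels,predicted_labels equal-length character vectors.
#' @param class_order ordered class labels defining rows/columns.
#' @param reduce_unknown if `TRUE`, any true label outside `class_order` is
#'   grouped into an `"Other"` class (appended to the order if absent);
#'   if `FALSE` such labels are an error.
#' @return integer matrix, rows = true classes, columns = predicted.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             class_order = sort(unique(c(true_labels, predicted_labels))),
                             reduce_unknown = FALSE) {
  assert_that(length(true_labels) == length(predicted_labels),
              "label vectors must have equal length")
  if (reduce_unknown) {
    if (!"Other" %in% class_order) class_order <- c(class_order, "Other")
    true_labels[!true_labels %in% class_order] <- "Other"
  } else if (!all(true_labels %in% class_order)) {
    stop("true label(s) outside class_order; enable reduce_unknown to group them")
  }
  assert_that(all(predicted_labels %in% class_order),
              "predicted label(s) outside class_order")
  tf <- factor(true_labels, levels = class_order)
  pf <- factor(predicted_labels, levels = class_order)
  m <- table(true = tf, predicted = pf)
  matrix(as.integer(m), nrow = length(class_order),
         dimnames = list(true = class_order, predicted = class_order))
}

per_class_metrics <- function(cm) {
  diagc <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted == 0, 0, diagc / ifelse(predicted == 0, 1, predicted))
  recall <- ifelse(support == 0, 0, diagc / ifelse(support == 0, 1, support))
  data.frame(class = rownames(cm), precision = precision, recall = recall,
             f1 = f1_from_pr(precision, recall), support = as.integer(support),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classification score report
#'
#' Per-class one-vs-rest precision, recall, F1 and support from argmax
#' predictions; macro F1 (unweighted mean over all report classes, including
#' zero-support classes), weighted F1 (support-weighted mean), accuracy, and
#' mean categorical cross-entropy of the probability assigned to the true
#' class (probabilities clipped below at `clip`).
#'
#' @param true_labels character vector of true classes.
#' @param probs numeric matrix, one row per individual, columns named (or
#'   ordered) by `class_order`; each row must sum to 1 within `1e-6`.
#' @param class_order ordered class labels; defaults to `colnames(probs)`.
#' @param clip lower clip for cross-entropy probabilities (default `1e-15`).
#' @return A `score_report`: list with `per_class` (data.frame), `macro_f1`,
#'   `weighted_f1`, `accuracy`, `cross_entropy`, `confusion` and `n`.
#' @export
score_report <- function(true_labels, probs, class_order = colnames(probs),
                         clip = 1e-15) {
  probs <- as.matrix(probs)
  assert_that(!is.null(class_order), "class_order is required (or name probs columns)")
  assert_that(ncol(probs) == length(class_order),
              "probability columns must match class_order")
  assert_that(nrow(probs) == length(true_labels),
              "one probability row per true label required")
  assert_that(all(abs(rowSums(probs) - 1) < 1e-6),
              "probability rows must be normalized")
  colnames(probs) <- class_order
  # ties broken toward the lowest class index
  pred <- class_order[max.col(probs, ties.method = "first")]
  cm <- confusion_matrix(true_labels, pred, class_order = class_order,
                         reduce_unknown = !all(true_labels %in% class_order))
  pc <- per_class_metrics(cm)
  p_true <- probs[cbind(seq_along(true_labels),
                        match(true_labels, class_order))]
  p_true[is.na(p_true)] <- 0  # true class absent from the probability columns
  p_true <- pmin(pmax(p_true, clip), 1)
  structure(list(
    per_class = pc,
    macro_f1 = mean(pc$f1),
    weighted_f1 = sum(pc$f1 * pc$support) / sum(pc$support),
    accuracy = mean(pred == ifelse(true_labels %in% class_order, true_labels, "Other")),
    cross_entropy = mean(-log(p_true)),
    confusion = cm,
    n = length(true_labels)), class = "score_report")
}

#' @export
print.score_report <- function(x, digits = 6, ...) {
  cat(sprintf("score_report over %d individuals, %d classes\n",
              x$n, nrow(x$per_class)))
  print(format(x$per_class, digits = digits), row.names = FALSE)
  cat(sprintf("accuracy      %.*f\nmacro avg F1  %.*f\nweighted F1   %.*f\ncross-entropy %.*f\n",
              digits, x$accuracy, digits, x$macro_f1, digits, x$weighted_f1,
              digits, x$cross_entropy))
  invisible(x)
}

#' Write a score report to CSV and JSON
#'
#' The CSV mirrors the per-class table layout with trailing accuracy, macro
#' and weighted average rows; the JSON carries the summary scalars. The
#' confusion matrix is written alongside with labeled axes.
#'
#' @param report a [score_report()].
#' @param stem output path stem; writes `<stem>.csv`, `<stem>.json`,
#'   `<stem>_confusion.csv`.
#' @export
write_score_report <- function(report, stem) {
  pc <- report$per_class
  n_total <- sum(pc$support)
  tail_rows <- data.frame(
    class = c("accuracy", "macro avg", "weighted avg"),
    precision = c(report$accuracy, mean(pc$precision),
                  sum(pc$precision * pc$support) / n_total),
    recall = c(report$accuracy, mean(pc$recall),
               sum(pc$recall * pc$support) / n_total),
    f1 = c(report$accuracy, report$macro_f1, report$weighted_f1),
    support = c(n_total, n_total, n_total), stringsAsFactors = FALSE)
  utils::write.csv(rbind(pc, tail_rows), paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = report$accuracy, macro_f1 = report$macro_f1,
         weighted_f1 = report$weighted_f1, cross_entropy = report$cross_entropy,
         n = report$n),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   paste0(stem, "_confusion.csv"))
  invisible(stem)
}

#' Published benchmark test-set score report
#'
#' Loads the per-class score report released for the 2020 IDTReeS
#' tree-crown classification benchmark (taxon code, precision, recall, F1,
#' support over 585 evaluated individuals, out-of-sample taxa grouped as
#' "Other"), shipped as a plain-text fixture. Useful for checking metric
#' identities: each printed F1 is the harmonic mean of the printed precision
#' and recall, and the printed macro/weighted averages follow from the
#' per-class column.
#'
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
competition_test_report <- function() {
  utils::read.csv(system.file("extdata", "competition_test_report.csv",
                              package = "treefusion"),
                  stringsAsFactors = FALSE)
}
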