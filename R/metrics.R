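#' Confusion matrix
#'
#' Counts of true class (rows) by predicted class (columns) in a fixed
#' class order.
#'
#' @param truth character vector of true labels.
#' @param predicted character vector of predicted labels, same length.
#' @param class_order character vector fixing row/column order; defaults
#'   to the sorted union of observed labels.
#' @return a `K x K` integer matrix of class `wbc_confusion` with
#'   dimnames `truth` x `predicted`.
#' @examples
#' confusion_matrix(c("a", "b", "b"), c("a", "b", "a"), c("a", "b"))
#' @export
confusion_matrix <- function(truth, predicted,
                             class_order = sort(unique(c(truth, predicted)))) {
  if (length(truth) != length(predicted))
    abort("truth and predicted must have the same length")
  check_labels(truth, class_order, "truth")
  check_labels(predicted, class_order, "predictions")
  k <- length(class_order)
  cm <- matrix(0L, k, k, dimnames = list(truth = class_order,
                                         predicted = class_order))
  for (i in seq_along(truth))
    cm[truth[i], predicted[i]] <- cm[truth[i], predicted[i]] + 1L
  class(cm) <- c("wbc_confusion", class(cm))
  cm
}

#' Per-class precision, sensitivity and specificity
#'
#' One-vs-rest rates from a confusion matrix. Undefined ratios (zero
#' denominator, e.g. precision for a class never predicted) are reported
#' as `NA` with the `undefined` column naming the affected metric(s) —
#' never silently coerced to 0.
#'
#' @param cm a [confusion_matrix()].
#' @return tibble with one row per class: `class`, `support`, `tp`,
#'   `precision`, `sensitivity`, `specificity`, `undefined`.
#' @export
class_metrics <- function(cm) {
  classes <- rownames(cm)
  total <- sum(cm)
  purrr::map_dfr(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    tn <- total - tp - fp - fn
    rate <- function(num, den) if (den == 0) NA_real_ else num / den
    p <- rate(tp, tp + fp)
    s <- rate(tp, tp + fn)
    sp <- rate(tn, tn + fp)
    und <- c(if (tp + fp == 0) "precision", if (tp + fn == 0) "sensitivity",
             if (tn + fp == 0) "specificity")
    tibble(class = classes[k], support = sum(cm[k, ]), tp = as.integer(tp),
           precision = p, sensitivity = s, specificity = sp,
           undefined = paste(und, collapse = ","))
  })
}

#' F-score (harmonic mean of precision and sensitivity)
#'
#' @param precision,sensitivity rates in `[0, 1]` (vectorized).
#' @return `2 * P * S / (P + S)`; `NA` when both inputs are 0 (undefined)
#'   or either input is `NA`.
#' @examples
#' f_score(1.00, 0.94)  # 0.9691...
#' f_score(0.20, 1.00)  # 0.3333...
#' @export
f_score <- function(precision, sensitivity) {
  ifelse(is.na(precision) | is.na(sensitivity), NA_real_,
         ifelse(precision + sensitivity == 0, NA_real_,
                2 * precision * sensitivity / (precision + sensitivity)))
}

#' Overall accuracy
#'
#' @param cm a [confusion_matrix()].
#' @return trace / total, in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  if (sum(cm) == 0) abort("empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

#' Binary ROC curve and AUC
#'
#' `roc_points()` sweeps all distinct score thresholds and returns the
#' (FPR, TPR) operating points; `roc_auc()` integrates them by the
#' trapezoidal rule, which equals the Mann-Whitney probability that a
#' positive outranks a negative with ties counted 1/2.
#'
#' @param truth logical (or 0/1) vector; `TRUE` = positive.
#' @param scores numeric scores, higher = more positive.
#' @return `roc_auc()`: area in `[0, 1]`. `roc_points()`: tibble with
#'   columns `threshold`, `fpr`, `tpr`.
#' @examples
#' roc_auc(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.3, 0.1))  # 1
#' roc_auc(c(TRUE, FALSE), c(0.5, 0.5))                          # 0.5
#' @export
roc_auc <- function(truth, scores) {
  pts <- roc_points(truth, scores)
  # trapezoid over the FPR axis
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

#' @rdname roc_auc
#' @export
roc_points <- function(truth, scores) {
  truth <- as.logical(truth)
  if (length(truth) != length(scores))
    abort("truth and scores must have the same length")
  np <- sum(truth)
  nn <- sum(!truth)
  if (np == 0 || nn == 0)
    abort("ROC needs both positive and negative examples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # group tied scores so both classes at a tie move together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t)
  fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(threshold = c(Inf, s[last]),
         fpr = c(0, fp[last] / nn),
         tpr = c(0, tp[last] / np))
}

#' One-vs-rest multiclass AUC
#'
#' Computes a per-class ROC AUC using each class's predicted probability
#' as the score, plus the macro (unweighted) average over the classes for
#' which both outcomes are present. Classes absent from the truth are
#' flagged (`NA` AUC) and excluded from the macro average.
#'
#' @param truth character vector of true labels.
#' @param probs `n x K` matrix of class probabilities with columns
#'   following `class_order`.
#' @param class_order character vector of class names.
#' @return list with `per_class` (tibble: `class`, `auc`, `present`) and
#'   `macro_auc`.
#' @export
multiclass_auc <- function(truth, probs, class_order = colnames(probs)) {
  if (is.null(class_order)) abort("class_order is required")
  if (length(unique(truth)) < 2)
    abort("multiclass AUC needs at least two classes present")
  per <- purrr::map_dfr(seq_along(class_order), function(k) {
    pos <- truth == class_order[k]
    if (sum(pos) == 0 || sum(!pos) == 0)
      tibble(class = class_order[k], auc = NA_real_, present = FALSE)
    else
      tibble(class = class_order[k], auc = roc_auc(pos, probs[, k]),
             present = TRUE)
  })
  list(per_class = per, macro_auc = mean(per$auc[per$present]))
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, per-class precision / sensitivity /
#' specificity / F-score (/ AUC when probabilities are supplied), overall
#' accuracy and macro-average AUC into one object with `tidy()`,
#' `glance()`, `autoplot()` and JSON export support.
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param probs optional `n x K` probability matrix (columns =
#'   `class_order`) enabling the AUC columns.
#' @param class_order class ordering (default: sorted observed labels).
#' @return a `wbc_eval_report` object.
#' @export
evaluation_report <- function(truth, predicted, probs = NULL,
                              class_order = sort(unique(c(truth, predicted)))) {
  cm <- confusion_matrix(truth, predicted, class_order)
  per <- class_metrics(cm)
  per$f_score <- f_score(per$precision, per$sensitivity)
  macro_auc <- NA_real_
  if (!is.null(probs) && length(unique(truth)) >= 2) {
    ma <- multiclass_auc(truth, probs, class_order)
    per <- dplyr::left_join(per, ma$per_class[, c("class", "auc")],
                            by = "class")
    macro_auc <- ma$macro_auc
  } else per$auc <- NA_real_
  structure(list(confusion = cm, per_class = per,
                 overall_accuracy = overall_accuracy(cm),
                 macro_auc = macro_auc,
                 macro_sensitivity = mean(per$sensitivity, na.rm = TRUE)),
            class = "wbc_eval_report")
}

#' @export
print.wbc_eval_report <- function(x, ...) {
  cat("WBC classification evaluation\n")
  cat(sprintf("  overall accuracy: %.4f\n", x$overall_accuracy))
  if (!is.na(x$macro_auc))
    cat(sprintf("  macro AUC:        %.4f\n", x$macro_auc))
  cat(sprintf("  macro sensitivity: %.4f\n", x$macro_sensitivity))
  print(as.data.frame(x$per_class), digits = 3)
  invisible(x)
}

#' @export
tidy.wbc_eval_report <- function(x, ...) x$per_class

#' @export
glance.wbc_eval_report <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy, macro_auc = x$macro_auc,
         macro_sensitivity = x$macro_sensitivity,
         n = sum(x$confusion), n_classes = nrow(x$per_class))
}

#' @export
autoplot.wbc_eval_report <- function(object, ...) {
  cm <- object$confusion
  class(cm) <- "matrix"
  df <- as_tibble(as.data.frame(as.table(cm), stringsAsFactors = FALSE))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::labs(x = "predicted", y = "truth",
                  title = "Confusion matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' ROC curves for a multiclass report
#'
#' @param truth true labels.
#' @param probs `n x K` probability matrix with class-name columns.
#' @return a ggplot of one-vs-rest ROC curves per class.
#' @export
plot_roc_curves <- function(truth, probs) {
  dfs <- purrr::map_dfr(colnames(probs), function(cl) {
    pos <- truth == cl
    if (sum(pos) == 0 || sum(!pos) == 0) return(NULL)
    pts <- roc_points(pos, probs[, cl])
    pts$class <- cl
    pts
  })
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = "One-vs-rest ROC curves") +
    ggplot2::theme_minimal()
}

#' Round half-up for report display
#'
#' Standard `round()` uses banker's rounding; report tables round half
#' away from zero to 4 decimals.
#'
#' @param x numeric.
#' @param digits decimal places (default 4).
#' @export
round_half_up <- function(x, digits = 4) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Export an evaluation report as JSON
#'
#' Keys: `per_class.<label>.{precision,sensitivity,specificity,f_score,
#' auc,support}` and `overall.{accuracy,macro_auc}`.
#'
#' @param report a `wbc_eval_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  per <- report$per_class
  per_list <- setNames(lapply(seq_len(nrow(per)), function(i) {
    list(precision = per$precision[i], sensitivity = per$sensitivity[i],
         specificity = per$specificity[i], f_score = per$f_score[i],
         auc = per$auc[i], support = per$support[i])
  }), per$class)
  jsonlite::write_json(
    list(per_class = per_list,
         overall = list(accuracy = report$overall_accuracy,
                        macro_auc = report$macro_auc,
                        macro_sensitivity = report$macro_sensitivity)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
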