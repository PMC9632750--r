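#' Confusion matrix and one-vs-rest counts
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Ordered class list; defaults to the sorted union of labels.
#' @return List of class `confusion_counts` with `matrix` (K x K, rows =
#'   true, columns = predicted) and `counts` (per-class data frame with
#'   one-vs-rest TP/FP/FN/TN and support).
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) stop("labels outside class set: ", paste(bad, collapse = ", "))
  m <- table(factor(y_true, classes), factor(y_pred, classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(true = classes, pred = classes))
  n <- length(y_true)
  counts <- data.frame(
    class = classes,
    TP = diag(m),
    FP = colSums(m) - diag(m),
    FN = rowSums(m) - diag(m),
    support = rowSums(m),
    row.names = NULL, stringsAsFactors = FALSE)
  counts$TN <- n - counts$TP - counts$FP - counts$FN
  structure(list(matrix = m, counts = counts), class = "confusion_counts")
}

safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)

#' Per-class metrics from one-vs-rest counts
#'
#' Computes, for every class: one-vs-rest accuracy `(TP+TN)/total`,
#' sensitivity/recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)` and the F1 harmonic mean. Undefined ratios (0/0) are
#' reported as 0 and flagged in the `undefined` column so weighted averages
#' stay computable.
#'
#' @param cc A `confusion_counts` object.
#' @return Data frame with one row per class.
#' @export
per_class_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  k <- cc$counts
  total <- k$TP + k$FP + k$FN + k$TN
  precision <- safe_ratio(k$TP, k$TP + k$FP)
  recall <- safe_ratio(k$TP, k$TP + k$FN)
  data.frame(
    class = k$class,
    support = k$support,
    accuracy = (k$TP + k$TN) / total,
    recall = recall,
    specificity = safe_ratio(k$TN, k$TN + k$FP),
    precision = precision,
    f1 = safe_ratio(2 * precision * recall, precision + recall),
    undefined = (k$TP + k$FP == 0) | (k$TP + k$FN == 0),
    stringsAsFactors = FALSE)
}

#' Support-weighted average of per-class metric values
#'
#' `sum(values * supports) / sum(supports)`: each class contributes in
#' proportion to its sample share.
#'
#' @param values Per-class metric values.
#' @param supports Per-class sample counts.
#' @return Scalar weighted average.
#' @export
weighted_average <- function(values, supports) {
  stopifnot(length(values) == length(supports), sum(supports) > 0)
  sum(values * supports) / sum(supports)
}

#' One-vs-rest ROC AUC with midrank tie handling
#'
#' For each class, the AUC of its probability column against the binary
#' one-vs-rest truth, computed from midranks (equivalent to the normalized
#' Mann-Whitney U statistic, counting ties as half). Classes absent from
#' `y_true` get `NA`.
#'
#' @param scores N x K matrix of class scores/probabilities, columns named
#'   (or ordered) by `classes`.
#' @param y_true Length-N label vector.
#' @param classes Ordered class list; defaults to `colnames(scores)`.
#' @return List with `per_class` (named AUC vector) and `weighted`
#'   (support-weighted average over the classes present).
#' @export
roc_auc <- function(scores, y_true, classes = colnames(scores)) {
  if (is.null(classes)) stop("classes must be given or scores must have colnames")
  stopifnot(nrow(scores) == length(y_true), ncol(scores) == length(classes))
  auc <- vapply(seq_along(classes), function(j) {
    pos <- y_true == classes[j]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores[, j], ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  names(auc) <- classes
  supports <- vapply(classes, function(cl) sum(y_true == cl), numeric(1))
  ok <- !is.na(auc)
  list(per_class = auc,
       weighted = if (any(ok)) weighted_average(auc[ok], supports[ok]) else NA_real_)
}

#' Full evaluation report
#'
#' Assembles the complete metric suite: the K x K confusion matrix,
#' per-class one-vs-rest accuracy, sensitivity/recall, specificity,
#' precision, F1 (and AUC when scores are supplied), the support-weighted
#' average of each, and the overall (micro) accuracy used for headline
#' comparisons. Per-class one-vs-rest accuracy and recall are both reported
#' and labeled distinctly since they are different quantities.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels; defaults to the argmax of `scores`.
#' @param scores Optional N x K probability matrix (enables AUC).
#' @param classes Ordered class list.
#' @return An object of class `metrics_report` with elements `confusion`,
#'   `per_class`, `weighted` (named vector), `overall_accuracy` and
#'   `n_classes`.
#' @export
metrics_report <- function(y_true, y_pred = NULL, scores = NULL,
                           classes = NULL) {
  if (is.null(y_pred)) {
    if (is.null(scores)) stop("supply y_pred or scores")
    cls <- if (!is.null(classes)) classes else colnames(scores)
    y_pred <- cls[max.col(scores)]
  }
  if (is.null(classes))
    classes <- if (!is.null(scores) && !is.null(colnames(scores)))
      colnames(scores) else sort(unique(c(y_true, y_pred)))
  cc <- confusion_matrix(y_true, y_pred, classes)
  pc <- per_class_metrics(cc)
  weighted <- vapply(c("accuracy", "recall", "specificity", "precision", "f1"),
                     function(v) weighted_average(pc[[v]], pc$support),
                     numeric(1))
  if (!is.null(scores)) {
    a <- roc_auc(scores, y_true, classes)
    pc$auc <- as.numeric(a$per_class)
    weighted <- c(weighted, auc = a$weighted)
  }
  structure(list(confusion = cc, per_class = pc, weighted = weighted,
                 overall_accuracy = mean(y_true == y_pred),
                 n_classes = length(classes)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report> ", x$n_classes, " classes, overall accuracy ",
      round(x$overall_accuracy, digits), "\n", sep = "")
  pc <- x$per_class
  num <- vapply(pc, is.numeric, logical(1))
  pc[num] <- lapply(pc[num], round, digits)
  print(pc, row.names = FALSE)
  cat("support-weighted averages:\n")
  print(round(x$weighted, digits))
  invisible(x)
}

#' Write a metrics report to JSON and a per-class CSV
#'
#' @param report A `metrics_report`.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    out <- list(overall_accuracy = report$overall_accuracy,
                weighted = as.list(report$weighted),
                per_class = report$per_class,
                confusion = report$confusion$matrix)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(report$per_class, csv_path, row.names = FALSE)
  invisible(report)
}
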