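#' Confusion matrix of true versus predicted scores
#'
#' @param truth per-instance true scores.
#' @param predicted per-instance predicted (mapped) scores, same length.
#' @param classes ordered label set indexing rows (true) and columns
#'   (predicted); defaults to the sorted union of observed labels. All values
#'   in \code{truth} and \code{predicted} must belong to it.
#' @return Square integer matrix; entry \code{[a, b]} counts instances with
#'   true label \code{a} predicted as \code{b}.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  if (!all(truth %in% classes))
    stop("true label(s) outside 'classes': ",
         paste(unique(truth[!truth %in% classes]), collapse = ", "))
  if (!all(predicted %in% classes))
    stop("predicted label(s) outside 'classes': ",
         paste(unique(predicted[!predicted %in% classes]), collapse = ", "))
  f <- factor(truth, levels = classes)
  g <- factor(predicted, levels = classes)
  m <- table(true = f, predicted = g)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(true = as.character(classes),
                         predicted = as.character(classes)))
}

#' Binary classification metrics from a 2x2 confusion matrix
#'
#' Accuracy, precision, recall and F1 for a chosen positive class:
#' \deqn{Precision = TP/(TP+FP), \quad Recall = TP/(TP+FN),}
#' \deqn{F1 = 2 P R / (P + R), \quad Accuracy = (TP+TN)/(TP+TN+FP+FN).}
#' Precision and recall are defined as 0 when their denominator is 0 (the
#' \code{undefined} field flags which); F1 is 0 when both are 0.
#'
#' @param confusion 2x2 matrix from [confusion_matrix()].
#' @param positive the positive class (a label among the matrix dimnames).
#' @return List: \code{accuracy}, \code{precision}, \code{recall}, \code{f1},
#'   \code{TP}, \code{FP}, \code{TN}, \code{FN}, \code{undefined}.
#' @export
binary_metrics <- function(confusion, positive) {
  if (!is.matrix(confusion) || nrow(confusion) != 2 || ncol(confusion) != 2)
    stop("'confusion' must be a 2x2 matrix")
  labs <- rownames(confusion)
  pos <- as.character(positive)
  if (!pos %in% labs) stop("'positive' (", pos, ") not among classes: ",
                           paste(labs, collapse = ", "))
  neg <- setdiff(labs, pos)
  TP <- confusion[pos, pos]
  FP <- confusion[neg, pos]
  FN <- confusion[pos, neg]
  TN <- confusion[neg, neg]
  undefined <- character(0)
  precision <- if (TP + FP > 0) TP / (TP + FP) else {
    undefined <- c(undefined, "precision"); 0
  }
  recall <- if (TP + FN > 0) TP / (TP + FN) else {
    undefined <- c(undefined, "recall"); 0
  }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(accuracy = (TP + TN) / sum(confusion),
       precision = precision, recall = recall, f1 = f1,
       TP = TP, FP = FP, TN = TN, FN = FN, undefined = undefined)
}

#' Multiclass evaluation report
#'
#' One-vs-rest precision, recall and F1 per class with unweighted (macro)
#' averages, plus overall accuracy (the trace of the confusion matrix over
#' the total count). Macro averaging is used because each severity class is
#' given equal weight regardless of its support.
#'
#' @param confusion square count matrix from [confusion_matrix()].
#' @param task optional task identifier recorded in the report.
#' @return An object of class \code{"tremor_eval"}: \code{task},
#'   \code{confusion}, \code{accuracy}, \code{per_class} (data frame with
#'   class, precision, recall, f1, TP, FP, FN, support) and \code{macro}
#'   (named vector).
#' @export
multiclass_metrics <- function(confusion, task = NA) {
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stop("'confusion' must be a square matrix")
  classes <- rownames(confusion)
  total <- sum(confusion)
  per <- lapply(seq_along(classes), function(i) {
    TP <- confusion[i, i]
    FP <- sum(confusion[-i, i])
    FN <- sum(confusion[i, -i])
    precision <- if (TP + FP > 0) TP / (TP + FP) else 0
    recall <- if (TP + FN > 0) TP / (TP + FN) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(class = classes[i], precision = precision, recall = recall,
               f1 = f1, TP = TP, FP = FP, FN = FN,
               support = sum(confusion[i, ]), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  macro <- c(precision = mean(per$precision), recall = mean(per$recall),
             f1 = mean(per$f1))
  structure(list(task = task,
                 confusion = confusion,
                 accuracy = sum(diag(confusion)) / total,
                 per_class = per,
                 macro = macro),
            class = "tremor_eval")
}

#' @export
print.tremor_eval <- function(x, digits = 2, ...) {
  if (!is.na(x$task)) cat("Task ", x$task, " ", sep = "")
  cat("evaluation (", sum(x$confusion), " instances)\n", sep = "")
  cat("Accuracy: ", sprintf("%.*f", digits, x$accuracy), " (",
      sum(diag(x$confusion)), "/", sum(x$confusion), ")\n", sep = "")
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  tab <- x$per_class
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  tab$f1 <- round(tab$f1, digits)
  print(tab[c("class", "precision", "recall", "f1", "support")],
        row.names = FALSE)
  cat("Macro: precision ", sprintf("%.*f", digits, x$macro["precision"]),
      ", recall ", sprintf("%.*f", digits, x$macro["recall"]),
      ", F1 ", sprintf("%.*f", digits, x$macro["f1"]), "\n", sep = "")
  invisible(x)
}
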