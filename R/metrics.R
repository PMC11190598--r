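#' Multi-class confusion matrix
#'
#' `counts[i, j]` is the number of epochs with true label `i` predicted as
#' label `j`; correctly classified epochs sit on the diagonal.
#'
#' @param true,predicted Label vectors of equal length; every label must
#'   belong to `vocabulary`.
#' @param vocabulary Ordered label set (a registered name or explicit
#'   vector).
#' @return A `confusion_matrix`: an integer matrix with the vocabulary as
#'   dimnames.
#' @examples
#' confusion_matrix(c("LG", "TG", "LG"), c("LG", "TG", "TG"), "HG-6")
#' @export
confusion_matrix <- function(true, predicted, vocabulary) {
  vocabulary <- resolve_vocabulary(vocabulary)
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted)) {
    stop("true and predicted must have equal length")
  }
  bad <- setdiff(unique(c(true, predicted)), vocabulary)
  if (length(bad) > 0) {
    stop("label(s) outside the vocabulary: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(true, levels = vocabulary),
                  factor(predicted, levels = vocabulary))
  m <- matrix(as.integer(counts), nrow = length(vocabulary),
              dimnames = list(true = vocabulary, predicted = vocabulary))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest reduction of a confusion matrix
#'
#' Treats one class as positive and the rest as negative:
#' `TP = counts[i, i]`, `FN` the rest of row `i`, `FP` the rest of column
#' `i`, `TN` everything else. The four counts always sum to the total.
#'
#' @param cm A [confusion_matrix()].
#' @param class_index Positive-class index (1-based) or label.
#' @return Named numeric vector `c(TP, TN, FP, FN)`.
#' @export
binary_reduce <- function(cm, class_index) {
  stopifnot(inherits(cm, "confusion_matrix"))
  k <- nrow(cm)
  if (is.character(class_index)) {
    class_index <- match(class_index, rownames(cm))
  }
  if (is.na(class_index) || class_index < 1 || class_index > k) {
    stop("class_index out of range")
  }
  tp <- cm[class_index, class_index]
  fn <- sum(cm[class_index, ]) - tp
  fp <- sum(cm[, class_index]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Accuracy, sensitivity and specificity report
#'
#' Per class (one-vs-rest): `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`. Macro
#' averages are unweighted means over classes; a class with a zero
#' denominator (e.g. absent from the evaluated epochs) yields `NaN` with a
#' warning and is excluded from that macro average. Overall accuracy is the
#' diagonal sum over the total.
#'
#' @param cm A [confusion_matrix()] with at least one count.
#' @return A `metrics_report`: list with `per_class` (data.frame),
#'   `macro` (named vector) and `overall_accuracy`.
#' @examples
#' cm <- confusion_matrix(rep(c("LG", "TG"), c(10, 90)),
#'                        rep(c("LG", "TG", "LG", "TG"), c(9, 1, 1, 89)),
#'                        c("LG", "TG"))
#' classification_metrics(cm)
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix: no epochs evaluated")
  per <- t(vapply(seq_len(nrow(cm)), function(i) {
    q <- binary_reduce(cm, i)
    c(accuracy = unname((q["TP"] + q["TN"]) / total),
      sensitivity = unname(q["TP"] / (q["TP"] + q["FN"])),
      specificity = unname(q["TN"] / (q["TN"] + q["FP"])))
  }, numeric(3)))
  per_class <- data.frame(label = rownames(cm), per,
                          row.names = NULL, stringsAsFactors = FALSE)
  if (anyNA(per)) {
    warning("metric undefined for class(es) with a zero denominator; ",
            "excluded from macro averages")
  }
  macro <- colMeans(per, na.rm = TRUE)
  structure(
    list(per_class = per_class, macro = macro,
         overall_accuracy = sum(diag(cm)) / total),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  overall accuracy: %.*f\n", digits, x$overall_accuracy))
  cat(sprintf("  macro: accuracy %.*f  sensitivity %.*f  specificity %.*f\n",
              digits, x$macro["accuracy"], digits, x$macro["sensitivity"],
              digits, x$macro["specificity"]))
  print(format(x$per_class, digits = digits), row.names = FALSE)
  invisible(x)
}
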