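#' Binary confusion matrix with a designated positive class
#'
#' @param truth,prediction character/factor vectors of equal length.
#' @param positive the positive class (default `"naked"`, the hull-less food
#'   type; the choice only relabels which cell is TP).
#' @return an object of class `confusion_matrix` with counts `tp`, `tn`,
#'   `fp`, `fn` and `n`.
#' @export
confusion_matrix <- function(truth, prediction, positive = "naked") {
  truth <- as.character(truth); prediction <- as.character(prediction)
  stopifnot(length(truth) == length(prediction), length(truth) > 0L)
  tp <- sum(truth == positive & prediction == positive)
  tn <- sum(truth != positive & prediction != positive)
  fp <- sum(truth != positive & prediction == positive)
  fn <- sum(truth == positive & prediction != positive)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = tp + tn + fp + fn,
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive=%s  TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$positive, x$tp, x$tn, x$fp, x$fn, x$n))
  invisible(x)
}

#' Accuracy, recall and precision of a confusion matrix
#'
#' `accuracy = (TP + TN) / n`, `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`. A zero denominator yields `NaN` with a
#' warning -- never a silent 0.
#'
#' @param cm a [confusion_matrix()].
#' @return a number in `[0, 1]` (or `NaN`).
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"), cm$n > 0L)
  (cm$tp + cm$tn) / cm$n
}

#' @rdname accuracy
#' @export
recall <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  den <- cm$tp + cm$fn
  if (den == 0L) {
    warning("recall undefined: no positive-class samples", call. = FALSE)
    return(NaN)
  }
  cm$tp / den
}

#' @rdname accuracy
#' @export
precision <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  den <- cm$tp + cm$fp
  if (den == 0L) {
    warning("precision undefined: no positive predictions", call. = FALSE)
    return(NaN)
  }
  cm$tp / den
}

#' Full classification report
#'
#' Per-class precision/recall plus their macro averages and the overall
#' accuracy. The headline accuracy is the plain correct-over-total fraction;
#' the binary report designates `"naked"` as the positive class.
#'
#' @param truth,prediction label vectors.
#' @param positive positive class for the binary view.
#' @return list with `accuracy`, `per_class` (data.frame of class, precision,
#'   recall), `macro_precision`, `macro_recall` and the binary
#'   `confusion` matrix.
#' @export
classification_report <- function(truth, prediction, positive = "naked") {
  truth <- as.character(truth); prediction <- as.character(prediction)
  classes <- sort(unique(c(truth, prediction)))
  per <- do.call(rbind, lapply(classes, function(cl) {
    cmc <- confusion_matrix(truth, prediction, positive = cl)
    data.frame(class = cl,
               precision = suppressWarnings(precision(cmc)),
               recall = suppressWarnings(recall(cmc)),
               support = sum(truth == cl))
  }))
  cm <- confusion_matrix(truth, prediction,
                         positive = if (positive %in% classes) positive else classes[1])
  list(accuracy = mean(truth == prediction),
       per_class = per,
       macro_precision = mean(per$precision, na.rm = TRUE),
       macro_recall = mean(per$recall, na.rm = TRUE),
       confusion = cm)
}

#' Write a metrics report to JSON and the per-sample table to CSV
#'
#' @param eval result of [loso_evaluate()] or a list with `predictions` and
#'   `metrics`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return invisibly, the report list.
#' @export
write_report <- function(eval, json_path = NULL, csv_path = NULL) {
  m <- eval$metrics
  rep <- list(accuracy = m$accuracy,
              macro_precision = m$macro_precision,
              macro_recall = m$macro_recall,
              per_class = m$per_class,
              confusion = m$confusion[c("tp", "tn", "fp", "fn", "n", "positive")])
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(eval$predictions, csv_path, row.names = FALSE)
  invisible(rep)
}
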