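#' Confusion matrix
#'
#' Cross-tabulates true against predicted class labels: `counts[i, j]` is
#' the number of samples whose true class is `classes[i]` and predicted
#' class is `classes[j]`.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param classes ordered class labels; defaults to the sorted union of the
#'   labels seen. Labels outside `classes` are an error.
#' @return a `confusion_matrix`: an integer k x k matrix (rows = true,
#'   columns = predicted) with the class labels as dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred differ in length")
  }
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) {
    abort(paste0("label(s) outside the class set: ",
                 paste(bad, collapse = ", ")))
  }
  counts <- table(factor(y_true, levels = classes),
                  factor(y_pred, levels = classes))
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = true, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' @param x a `confusion_matrix`.
#' @param ... unused.
#' @return `tidy()` returns one row per (true, predicted) cell.
#' @rdname confusion_matrix
#' @exportS3Method generics::tidy
#' @export
tidy.confusion_matrix <- function(x, ...) {
  classes <- rownames(x)
  tibble(true = rep(classes, times = length(classes)),
         predicted = rep(classes, each = length(classes)),
         n = as.integer(x[cbind(rep(seq_along(classes), length(classes)),
                                rep(seq_along(classes),
                                    each = length(classes)))]))
}

#' Per-class and macro-averaged classification metrics
#'
#' Reduces a k-class confusion matrix to one-vs-rest binary problems and
#' computes, per class, accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and `F1 = 2PR/(P+R)`. Macro metrics
#' are the unweighted means of the per-class values. Whenever a precision,
#' recall or F1 denominator is zero the metric is defined as 0 and the
#' event is recorded in the report's `zero_division` log. The overall
#' (micro) accuracy, `sum(diag)/total`, is reported separately from the
#' macro accuracy.
#'
#' @param cm a [confusion_matrix()].
#' @return a `classification_report` with elements `per_class` (tibble),
#'   `macro` (named list), `micro_accuracy`, `n`, and `zero_division`.
#' @export
classification_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    abort("cm must be a confusion_matrix")
  }
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix")
  classes <- rownames(cm)
  zero_log <- list()
  ratio <- function(num, den, class, metric) {
    if (den == 0) {
      zero_log[[length(zero_log) + 1]] <<- tibble(class = class,
                                                  metric = metric)
      return(0)
    }
    num / den
  }
  per <- purrr::map_dfr(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    p <- ratio(tp, tp + fp, classes[i], "precision")
    r <- ratio(tp, tp + fn, classes[i], "recall")
    f1 <- ratio(2 * p * r, p + r, classes[i], "f1")
    tibble(class = classes[i], tp = tp, fn = fn, fp = fp, tn = tn,
           accuracy = (tp + tn) / total, precision = p, recall = r,
           f1 = f1)
  })
  structure(list(
    per_class = per,
    macro = list(accuracy = mean(per$accuracy),
                 precision = mean(per$precision),
                 recall = mean(per$recall),
                 f1 = mean(per$f1)),
    micro_accuracy = sum(diag(cm)) / total,
    n = total,
    zero_division = if (length(zero_log)) bind_rows(zero_log) else
      tibble(class = character(), metric = character())),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d samples, %d classes\n",
              x$n, nrow(x$per_class)))
  print(x$per_class)
  cat(sprintf(
    "macro: accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
    x$macro$accuracy, x$macro$precision, x$macro$recall, x$macro$f1))
  cat(sprintf("overall (micro) accuracy %.3f\n", x$micro_accuracy))
  invisible(x)
}

#' @param x a `classification_report`.
#' @param ... unused.
#' @return `tidy()` returns the per-class metric tibble; `glance()` a
#'   one-row tibble of the macro metrics plus micro accuracy.
#' @rdname classification_metrics
#' @exportS3Method generics::tidy
#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' @rdname classification_metrics
#' @exportS3Method generics::glance
#' @export
glance.classification_report <- function(x, ...) {
  tibble(macro_accuracy = x$macro$accuracy,
         macro_precision = x$macro$precision,
         macro_recall = x$macro$recall,
         macro_f1 = x$macro$f1,
         micro_accuracy = x$micro_accuracy,
         n = x$n)
}
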