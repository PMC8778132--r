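#' Confusion matrix with rows = true class, columns = predicted class
#'
#' @param truth True class labels.
#' @param estimate Predicted class labels, same length as `truth`.
#' @param levels Fixed class order; defaults to the sorted union of the
#'   labels seen. Labels outside `levels` are an error.
#' @return A K x K integer matrix of class `confusion_matrix`; entry (r, c)
#'   counts samples of true class r predicted as class c.
#' @examples
#' confusion_matrix(c("A", "A", "B"), c("A", "B", "B"))
#' @export
confusion_matrix <- function(truth, estimate, levels = NULL) {
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have equal length", call. = FALSE)
  }
  truth <- as.character(truth); estimate <- as.character(estimate)
  if (is.null(levels)) levels <- sort(unique(c(truth, estimate)))
  unknown <- setdiff(unique(c(truth, estimate)), levels)
  if (length(unknown) > 0) {
    stop("label(s) not in `levels`: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(factor(truth, levels = levels), factor(estimate, levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(truth = levels, predicted = levels))
  as_confusion_matrix(m)
}

#' @rdname confusion_matrix
#' @param x A square numeric matrix of counts (rows = true class) to tag as
#'   a confusion matrix; row/column names give the class order.
#' @export
as_confusion_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("confusion matrix must be square", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) {
    stop("confusion matrix entries must be nonnegative integers", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    rownames(x) <- colnames(x) <- as.character(seq_len(nrow(x)))
  }
  storage.mode(x) <- "integer"
  structure(x, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class precision, recall, F1 and support weight
#'
#' One-vs-rest readout of a confusion matrix: for class i, `TP` is the
#' diagonal entry, `FP` the rest of column i, `FN` the rest of row i, so
#' precision = TP/(TP+FP), recall = TP/(TP+FN) and F1 is their harmonic
#' mean. The support weight is the class's share of true samples (row sum /
#' total). A class never predicted has undefined precision (and a class
#' with no true samples undefined recall); these are reported as `NA` with
#' a warning, never silently as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A tibble with columns `class`, `precision`, `recall`, `f1`,
#'   `support`, `weight`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- diag(cm)
  row_sums <- rowSums(cm)
  col_sums <- colSums(cm)
  precision <- ifelse(col_sums > 0, tp / col_sums, NA_real_)
  recall <- ifelse(row_sums > 0, tp / row_sums, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  und <- rownames(cm)[is.na(precision) | is.na(recall) | is.na(f1)]
  if (length(und) > 0) {
    warning("undefined metric(s) for class(es): ", paste(und, collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(
    class = rownames(cm),
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    support = as.integer(row_sums),
    weight = as.numeric(row_sums / sum(cm))
  )
}

#' Overall accuracy of a confusion matrix
#'
#' The fraction of samples on the diagonal (trace / total).
#'
#' @param cm A [confusion_matrix()].
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' Support-weighted F1 score
#'
#' `Fw = sum_i w_i * F1_i` where `w_i` is class i's share of the evaluated
#' samples (row sum over total). Classes with undefined F1 make the score
#' undefined and raise an error naming them.
#'
#' @param x A [confusion_matrix()] or the tibble from [per_class_metrics()].
#' @return A fraction in `[0, 1]`.
#' @export
weighted_f1 <- function(x) {
  if (inherits(x, "confusion_matrix")) {
    x <- suppressWarnings(per_class_metrics(x))
  }
  stopifnot(is.data.frame(x), all(c("f1", "weight") %in% names(x)))
  bad <- x$class[is.na(x$f1)]
  if (length(bad) > 0) {
    stop("F1 undefined for class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sum(x$weight * x$f1)
}

#' Metric report in the style of a published HAR confusion table
#'
#' Formats counts with a trailing precision (PRC) row and recall (RCL) /
#' F1-score (F1S) columns, all rounded half-up to two decimals.
#'
#' @param cm A [confusion_matrix()].
#' @return A character matrix ready for printing or writing as CSV.
#' @export
format_metric_table <- function(cm) {
  m <- suppressWarnings(per_class_metrics(cm))
  round2 <- function(x) {
    ifelse(is.na(x), "", formatC(floor(x * 100 + 0.5) / 100, format = "f", digits = 2))
  }
  body <- cbind(format(unclass(cm)), RCL = round2(m$recall), F1S = round2(m$f1))
  prc <- c(round2(m$precision), "", "")
  out <- rbind(body, PRC = prc)
  rownames(out) <- c(rownames(cm), "PRC")
  out
}
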