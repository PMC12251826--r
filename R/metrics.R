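#' Categorical accuracy of a confusion matrix
#'
#' Diagonal sum over total count.
#'
#' @param confusion Square nonnegative integer matrix (rows: measured,
#'   columns: predicted).
#' @return Fraction between 0 and 1.
#' @export
categorical_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (length(confusion) == 0 || nrow(confusion) != ncol(confusion))
    stop("confusion must be a non-empty square matrix")
  if (any(confusion < 0)) stop("negative counts")
  tot <- sum(confusion)
  if (tot == 0) stop("empty confusion matrix")
  sum(diag(confusion)) / tot
}

#' Confusion matrix from label vectors
#'
#' @param truth,pred Vectors of equal length (coerced to factors over
#'   `levels`).
#' @param levels Label levels ordering rows/columns.
#' @return Integer matrix (rows: measured, columns: predicted).
#' @export
confusion_matrix <- function(truth, pred, levels = sort(unique(c(truth, pred)))) {
  stopifnot(length(truth) == length(pred))
  t <- factor(truth, levels = levels)
  p <- factor(pred, levels = levels)
  as.matrix(table(measured = t, predicted = p))
}
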