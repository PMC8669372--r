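# Confusion matrices, per-class TP/FP/FN/TN decomposition, accuracy.

#' Multiclass confusion matrix
#'
#' Counts with rows = actual class, columns = predicted class, over the
#' four screening categories by default.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param classes Ordered class labels; any label outside this set is an
#'   error.
#' @return A `confusion_matrix`: integer matrix with class attribute.
#' @export
confusion_matrix <- function(actual, predicted, classes = category_labels()) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted differ in length", call. = FALSE)
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad))
    stop("label(s) outside class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  m <- table(factor(actual, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(actual = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @rdname confusion_matrix
#' @param counts A square count matrix (rows = actual) to classify as a
#'   `confusion_matrix`, e.g. a reference matrix loaded from file.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("matrix must be square", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  cls <- rownames(counts) %||% paste0("A", seq_len(nrow(counts)))
  m <- matrix(as.integer(counts), nrow(counts), ncol(counts),
              dimnames = list(actual = cls, predicted = cls))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> ", sum(x), " observations, accuracy ",
      sprintf("%.2f%%", accuracy(x)), "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Per-class TP/FP/FN/TN decomposition
#'
#' With rows = actual and columns = predicted, the study convention
#' (`convention = "study"`, the default) takes FP of a class as its row sum
#' minus the diagonal and FN as its column sum minus the diagonal; note
#' this swaps the textbook meanings, and is kept because the reference
#' per-class tables were computed that way. `convention = "standard"` gives
#' the usual orientation (FP from the predicted column, FN from the actual
#' row). TN uses inclusion-exclusion,
#' `TN = total - rowsum - colsum + TP`, under both conventions.
#'
#' @param cm A `confusion_matrix`.
#' @param convention `"study"` or `"standard"`.
#' @return Data frame with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
per_class_counts <- function(cm, convention = c("study", "standard")) {
  convention <- match.arg(convention)
  m <- unclass(cm)
  tp <- diag(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  fp <- if (convention == "study") rs - tp else cs - tp
  fn <- if (convention == "study") cs - tp else rs - tp
  data.frame(class = rownames(m), tp = as.integer(tp), fp = as.integer(fp),
             fn = as.integer(fn),
             tn = as.integer(sum(m) - rs - cs + tp),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classification accuracy
#'
#' `100 * trace / total`, as a percentage.
#'
#' @param cm A `confusion_matrix`.
#' @return A percentage in \[0, 100\].
#' @export
accuracy <- function(cm) {
  m <- unclass(cm)
  tot <- sum(m)
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(m)) / tot
}

#' Plain-text metrics report
#'
#' @param cm A `confusion_matrix`.
#' @param convention Passed to [per_class_counts()].
#' @return Invisibly, the per-class count table.
#' @export
metrics_report <- function(cm, convention = "study") {
  print(cm)
  pc <- per_class_counts(cm, convention)
  cat("\nper-class counts (", convention, " convention):\n", sep = "")
  print(pc, row.names = FALSE)
  invisible(pc)
}
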