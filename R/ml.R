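# Comparison classifiers: stratified split, nearest-neighbour mean
# oversampling, and SVM / KNN / decision-tree training on the ordinal
# encoding.

#' Stratified train/test split
#'
#' Samples `train_fraction` of each class (rounded) into the training
#' partition, the rest into the test partition; reproducible under a fixed
#' seed.
#'
#' @param x Feature matrix (subjects in rows).
#' @param y Class labels (one per row).
#' @param train_fraction Fraction of each class used for training
#'   (default 0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`
#'   (disjoint, union = all rows).
#' @export
stratified_split <- function(x, y, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("labels do not match rows", call. = FALSE)
  tab <- table(y)
  if (any(tab < 2L))
    stop("class with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(y == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(x)), train))
}

#' Balance training classes by nearest-neighbour means
#'
#' Augments each minority class up to the majority count: a synthetic row
#' is the arithmetic mean of a randomly chosen class member and its `k`
#' within-class nearest neighbours (Euclidean distance on the ordinal
#' encoding). Original rows are never modified or dropped; `k` is clamped
#' to class size minus one when the class is small.
#'
#' @param x Training feature matrix.
#' @param y Training labels.
#' @param k Neighbour count (default 5).
#' @param seed Integer seed.
#' @return List with the augmented `x` and `y`; synthetic rows are
#'   appended after the originals.
#' @export
knn_balance <- function(x, y, k = 5L, seed = 1L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  y <- as.character(y)
  tab <- table(y)
  target <- max(tab)
  set.seed(seed)
  add_x <- list()
  add_y <- character(0)
  for (cl in names(tab)[tab < target]) {
    idx <- which(y == cl)
    if (length(idx) < 2L)
      stop("cannot balance single-member class ", cl, call. = FALSE)
    kc <- min(k, length(idx) - 1L)
    xc <- x[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(xc))
    need <- target - length(idx)
    anchors <- sample.int(length(idx), need, replace = TRUE)
    rows <- matrix(NA_real_, need, ncol(x))
    for (q in seq_len(need)) {
      a <- anchors[q]
      nn <- order(d[a, ])[seq_len(kc + 1L)]   # anchor itself + kc neighbours
      rows[q, ] <- colMeans(xc[nn, , drop = FALSE])
    }
    add_x[[cl]] <- rows
    add_y <- c(add_y, rep(cl, need))
  }
  if (length(add_x)) {
    extra <- do.call(rbind, add_x)
    colnames(extra) <- colnames(x)
    x <- rbind(x, extra)
    y <- c(y, add_y)
  }
  list(x = x, y = y)
}

#' Train a baseline classifier and predict the test set
#'
#' Fits one of the comparison models on the training partition only and
#' predicts the test rows. Models: `"svm"` (radial-kernel support vector
#' machine), `"knn"` (k-nearest neighbours, `k = 5`), `"dtree"` (CART
#' decision tree, unconstrained depth). Hyperparameters can be overridden
#' through `params`.
#'
#' @param x_train,y_train Training features and labels.
#' @param x_test Test features.
#' @param model `"svm"`, `"knn"` or `"dtree"`.
#' @param params Named list of hyperparameter overrides (`svm`: passed to
#'   [e1071::svm()]; `knn`: `k`; `dtree`: passed to [rpart::rpart()]).
#' @param seed Integer seed (ties in KNN, surrogate choices).
#' @return Character vector of predicted labels, one per test row.
#' @export
train_and_predict <- function(x_train, y_train, x_test,
                              model = c("svm", "knn", "dtree"),
                              params = list(), seed = 1L) {
  model <- match.arg(model)
  y_train <- factor(as.character(y_train))
  set.seed(seed)
  if (model == "svm") {
    args <- utils::modifyList(list(x = x_train, y = y_train,
                                   kernel = "radial", scale = FALSE),
                              params)
    fit <- do.call(e1071::svm, args)
    as.character(stats::predict(fit, x_test))
  } else if (model == "knn") {
    k <- params$k %||% 5L
    k <- min(k, nrow(x_train))
    as.character(class::knn(x_train, x_test, y_train, k = k))
  } else {
    df_tr <- data.frame(.y = y_train, x_train, check.names = FALSE)
    args <- utils::modifyList(
      list(formula = stats::as.formula(".y ~ ."), data = df_tr,
           method = "class",
           control = rpart::rpart.control(minsplit = 2, cp = 0)),
      params)
    fit <- do.call(rpart::rpart, args)
    df_te <- data.frame(x_test, check.names = FALSE)
    as.character(stats::predict(fit, df_te, type = "class"))
  }
}
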