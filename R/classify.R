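#' Stratified train/test split
#'
#' Deterministic given the seed; stratified by class by default so every
#' class is represented in the training set.
#'
#' @param labels character/factor vector of class labels.
#' @param train_fraction fraction assigned to training, default 0.8.
#' @param seed integer seed.
#' @param stratify logical; split within each class.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(labels, train_fraction = 0.8, seed = 1,
                             stratify = TRUE) {
  n <- length(labels)
  if (train_fraction < 0 || train_fraction > 1)
    stop("`train_fraction` must be in [0, 1]")
  if (train_fraction == 1)
    warning("train_fraction = 1 leaves an empty test set")
  withr::with_seed(seed, {
    if (stratify) {
      if (!n || any(table(labels) < 1L))
        stop("empty class in stratified split")
      train <- unlist(lapply(split(seq_len(n), labels), function(idx) {
        k <- round(train_fraction * length(idx))
        sample(idx, k)
      }), use.names = FALSE)
    } else {
      train <- sample(seq_len(n), round(train_fraction * n))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

.standardize_pair <- function(train_x, query_x) {
  mu <- colMeans(train_x)
  sd <- apply(train_x, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(train = sweep(sweep(train_x, 2L, mu), 2L, sd, "/"),
       query = sweep(sweep(query_x, 2L, mu), 2L, sd, "/"))
}

#' k-nearest-neighbor label prediction
#'
#' Majority vote among the `k` nearest training points under Euclidean
#' distance. Features are z-scored on the training set by default, because
#' diagnostic features mix bohr^2 and dimensionless axes and unscaled
#' distances would be unit-dependent. Vote ties are broken by the smallest
#' mean distance to the query among the tied classes, which makes the
#' prediction deterministic.
#'
#' @param train_x numeric matrix of training features (rows = points).
#' @param train_y training labels.
#' @param query_x numeric matrix (or vector) of query features.
#' @param k number of neighbors, default 13 (about the square root of a
#'   ~170-point training set).
#' @param standardize z-score features on the training set, default TRUE.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, query_x, k = 13,
                        standardize = TRUE) {
  train_x <- as.matrix(train_x)
  query_x <- if (is.null(dim(query_x)))
    matrix(query_x, ncol = ncol(train_x)) else as.matrix(query_x)
  if (k <= 0) stop("`k` must be positive")
  if (nrow(train_x) == 0L) stop("empty training set")
  if (k > nrow(train_x))
    stop("`k` exceeds the training set size")
  if (!all(is.finite(train_x)) || !all(is.finite(query_x)))
    stop("feature values must be finite")
  train_y <- as.character(train_y)
  if (standardize) {
    z <- .standardize_pair(train_x, query_x)
    train_x <- z$train; query_x <- z$query
  }
  apply(query_x, 1L, function(q) {
    d2 <- colSums((t(train_x) - q)^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    # tie: smallest mean distance to the query among tied classes
    md <- vapply(top, function(cl) mean(d2[nn][train_y[nn] == cl]),
                 numeric(1L))
    top[which.min(md)]
  })
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes; the trace counts the
#' correctly identified points.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes class ordering of the matrix; defaults to the three
#'   excitation characters.
#' @return Integer matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(truth, predicted,
                             classes = c("local", "CT", "Rydberg")) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(classes, collapse = ", "), ")")
  m <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Cross-validated k-NN evaluation
#'
#' Stratified k-fold cross-validation; per-fold confusion matrices are
#' summed so every point is scored exactly once. With `folds = 0`
#' resubstitution is used instead (train = test), for comparison.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param k neighbors, default 13.
#' @param folds number of folds, default 5.
#' @param seed fold-assignment seed.
#' @param standardize z-score per training fold, default TRUE.
#' @param classes class ordering for the confusion matrix.
#' @return List with `confusion`, `accuracy`, and per-class
#'   `precision` / `recall`.
#' @export
knn_cv <- function(x, y, k = 13, folds = 5, seed = 1, standardize = TRUE,
                   classes = c("local", "CT", "Rydberg")) {
  x <- as.matrix(x); y <- as.character(y)
  n <- length(y)
  if (folds == 0) {
    pred <- knn_predict(x, y, x, k = k, standardize = standardize)
    cm <- confusion_matrix(y, pred, classes)
  } else {
    fold_of <- withr::with_seed(seed, {
      f <- integer(n)
      for (idx in split(seq_len(n), y)) {  # random fold rotation per class
        lab <- rep_len(sample.int(folds), length(idx))
        f[idx] <- lab[sample.int(length(idx))]
      }
      f
    })
    cm <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
    for (fd in seq_len(folds)) {
      te <- which(fold_of == fd)
      tr <- which(fold_of != fd)
      if (!length(te) || !length(tr)) next
      kk <- min(k, length(tr))
      pred <- knn_predict(x[tr, , drop = FALSE], y[tr],
                          x[te, , drop = FALSE], k = kk,
                          standardize = standardize)
      cm <- cm + confusion_matrix(y[te], pred, classes)
    }
  }
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / pmax(colSums(cm), 1L)
  rec <- diag(cm) / pmax(rowSums(cm), 1L)
  list(confusion = cm, accuracy = acc, precision = prec, recall = rec)
}

#' k-NN decision map over a 2D feature box
#'
#' Predicted label on a regular raster spanning the box — the background
#' shading of the diagnostic-plane figures.
#'
#' @param train_x two-column feature matrix.
#' @param train_y labels.
#' @param xlim,ylim numeric length-2 box limits.
#' @param resolution raster points per axis, default 100.
#' @param k neighbors.
#' @param standardize z-score on the training set.
#' @return Character matrix `resolution x resolution`; rows follow `xlim`,
#'   columns `ylim`, with axis coordinates in the dimnames.
#' @export
decision_map <- function(train_x, train_y, xlim, ylim, resolution = 100,
                         k = 13, standardize = TRUE) {
  train_x <- as.matrix(train_x)
  if (ncol(train_x) != 2L)
    stop("decision maps require exactly two features")
  gx <- seq(xlim[1L], xlim[2L], length.out = resolution)
  gy <- seq(ylim[1L], ylim[2L], length.out = resolution)
  grid <- cbind(rep(gx, times = resolution), rep(gy, each = resolution))
  pred <- knn_predict(train_x, train_y, grid, k = k,
                      standardize = standardize)
  matrix(pred, resolution, resolution,
         dimnames = list(x = signif(gx, 6), y = signif(gy, 6)))
}
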