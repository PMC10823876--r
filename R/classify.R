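# Back-propagation neural-network gesture classifier.
#
# A single-hidden-layer feed-forward network with logistic hidden units
# and a softmax output, fitted by nnet; the default hidden width is
# 2*I + 1 for I input features. The comparison the package makes is
# relative (same learner with and without virtual channels), so any
# fixed, reasonable network serves; the configuration is seeded and
# echoed in every evaluation report.

#' Stratified train/test split specification
#'
#' @param train_fraction fraction of each class assigned to training
#'   (default 2/3, i.e. a 2:1 train:test ratio).
#' @param per_class stratify per gesture class (default TRUE).
#' @param seed integer seed for the shuffle.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 2 / 3, per_class = TRUE, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)")
  }
  structure(list(train_fraction = train_fraction, per_class = per_class,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a labeled feature set into train and test sets
#'
#' Stratified split: per class, `round(J_k * train_fraction)` rows go to
#' training after a seeded shuffle, the rest to test. The two parts are
#' disjoint and exhaustive. With 150 samples per gesture and the default
#' fraction 2/3 this gives 100 training and 50 test rows per gesture.
#'
#' @param fs a [feature_set()].
#' @param spec a [split_spec()].
#' @return List with elements `train`, `test` (feature sets) and
#'   `train_idx`, `test_idx` (row indices into `fs`).
#' @export
split_feature_set <- function(fs, spec = split_spec()) {
  stopifnot(inherits(fs, "feature_set"), inherits(spec, "split_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- nrow(fs$x)
  if (spec$per_class) {
    train_idx <- integer(0)
    for (k in sort(unique(fs$labels))) {
      rows <- which(fs$labels == k)
      if (length(rows) < 2) {
        stop("class ", k, " has fewer than 2 samples; cannot split")
      }
      n_tr <- round(length(rows) * spec$train_fraction)
      n_tr <- min(max(n_tr, 1L), length(rows) - 1L)
      train_idx <- c(train_idx, sample(rows, n_tr))
    }
  } else {
    n_tr <- min(max(round(n * spec$train_fraction), 1L), n - 1L)
    train_idx <- sample(n, n_tr)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(
    train = feature_set(fs$x[train_idx, , drop = FALSE], fs$labels[train_idx]),
    test = feature_set(fs$x[test_idx, , drop = FALSE], fs$labels[test_idx]),
    train_idx = train_idx, test_idx = test_idx
  )
}

#' MLP classifier configuration
#'
#' @param hidden hidden-layer width; `NULL` (default) means `2 * I + 1`
#'   where I is the feature dimensionality at fit time.
#' @param max_epochs maximum optimizer iterations (default 150).
#' @param decay weight decay (default 1e-3, stabilizes training).
#' @param seed integer seed for weight initialization.
#' @return Object of class `mlp_config`.
#' @export
mlp_config <- function(hidden = NULL, max_epochs = 150, decay = 1e-3,
                       seed = 1L) {
  if (!is.null(hidden) && hidden < 1) stop("hidden width must be >= 1")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(hidden = hidden, max_epochs = max_epochs, decay = decay,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Train the gesture classifier
#'
#' Fits a single-hidden-layer feed-forward network (back-propagation
#' family) mapping I normalized features to K gesture-class scores.
#' Training is seeded: the same data and seed give identical weights
#' and predictions on the same platform.
#'
#' @param train a [feature_set()] with at least 2 classes.
#' @param cfg an [mlp_config()].
#' @return Object of class `gesture_mlp` with `fit` (the underlying
#'   nnet object), `classes`, `config`, `n_features`.
#' @export
train_gesture_mlp <- function(train, cfg = mlp_config()) {
  stopifnot(inherits(train, "feature_set"), inherits(cfg, "mlp_config"))
  classes <- sort(unique(train$labels))
  if (length(classes) < 2) stop("training set must contain >= 2 classes")
  I <- ncol(train$x)
  hidden <- if (is.null(cfg$hidden)) 2L * I + 1L else as.integer(cfg$hidden)
  y <- nnet::class.ind(factor(train$labels, levels = classes))
  max_nwts <- (I + 1L) * hidden + (hidden + 1L) * length(classes) + 10L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  fit <- nnet::nnet(train$x, y, size = hidden, softmax = TRUE,
                    maxit = cfg$max_epochs, decay = cfg$decay,
                    MaxNWts = max_nwts, trace = FALSE)
  structure(list(fit = fit, classes = classes, config = cfg,
                 n_features = I, hidden = hidden),
            class = "gesture_mlp")
}

#' @export
print.gesture_mlp <- function(x, ...) {
  cat("Gesture MLP: ", x$n_features, " features -> ", x$hidden,
      " hidden (logistic) -> ", length(x$classes),
      " classes (softmax)\n", sep = "")
  invisible(x)
}

#' Predict gesture labels
#'
#' Returns the class with the highest network score for each row; score
#' ties are broken toward the lowest class id.
#'
#' @param object a `gesture_mlp`.
#' @param newdata feature matrix or [feature_set()].
#' @param ... unused.
#' @return Integer vector of predicted gesture ids.
#' @export
predict.gesture_mlp <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_set")) newdata$x else rbind(newdata)
  if (ncol(x) != object$n_features) {
    stop("feature dimensionality (", ncol(x), ") does not match the model (",
         object$n_features, ")")
  }
  scores <- stats::predict(object$fit, x)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Evaluate a trained classifier on a test set
#'
#' @param model a `gesture_mlp`.
#' @param test a nonempty [feature_set()].
#' @return Object of class `evaluation_report`: `overall_accuracy`,
#'   `per_class_accuracy`, `confusion` (true x predicted), `n_test`,
#'   `config`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "gesture_mlp"), inherits(test, "feature_set"))
  if (nrow(test$x) < 1) stop("test set is empty")
  pred <- predict(model, test)
  levels_all <- sort(unique(c(model$classes, test$labels)))
  confusion <- table(
    true = factor(test$labels, levels = levels_all),
    predicted = factor(pred, levels = levels_all)
  )
  acc <- sum(diag(confusion)) / sum(confusion)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(overall_accuracy = acc, per_class_accuracy = per_class,
                 confusion = confusion, n_test = nrow(test$x),
                 config = model$config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Recognition accuracy: %.4f on %d test windows\n",
              x$overall_accuracy, x$n_test))
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}
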