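# Stratified splitting and the MLP gesture classifier.

make_blobs <- function(n_per = 30, K = 2, I = 2, spread = 0.01, seed = 1) {
  set.seed(seed)
  centers <- seq(0.1, 0.9, length.out = K)
  x <- NULL; labels <- integer(0)
  for (k in seq_len(K)) {
    x <- rbind(x, matrix(rnorm(n_per * I, centers[k], spread), n_per, I))
    labels <- c(labels, rep(k, n_per))
  }
  feature_set(pmin(pmax(x, 0), 1), labels)
}

test_that("stratified split is disjoint, exhaustive and reproducible", {
  fs <- make_blobs(n_per = 150, K = 5)
  sp <- split_feature_set(fs, split_spec(seed = 3))
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), seq_len(750))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  # 2:1 ratio per class: 100 train / 50 test each
  expect_equal(as.vector(table(sp$train$labels)), rep(100, 5))
  expect_equal(as.vector(table(sp$test$labels)), rep(50, 5))
  sp2 <- split_feature_set(fs, split_spec(seed = 3))
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_feature_set(fs, split_spec(seed = 4))
  expect_false(identical(sp$train_idx, sp3$train_idx))
})

test_that("split handles minimal classes and rejects singletons", {
  fs <- feature_set(matrix(runif(12), 6, 2), c(1, 1, 1, 2, 2, 2))
  sp <- split_feature_set(fs, split_spec(seed = 1))
  expect_equal(as.vector(table(sp$train$labels)), c(2, 2))
  expect_equal(as.vector(table(sp$test$labels)), c(1, 1))
  bad <- feature_set(matrix(runif(6), 3, 2), c(1, 1, 2))
  expect_error(split_feature_set(bad, split_spec()), "class 2")
  expect_error(split_spec(train_fraction = 1), "in \\(0, 1\\)")
})

test_that("the MLP separates non-overlapping clusters", {
  for (seed in 1:5) {
    fs <- make_blobs(n_per = 30, K = 2, spread = 0.01, seed = seed)
    model <- train_gesture_mlp(fs, mlp_config(seed = seed))
    pred <- predict(model, fs)
    expect_equal(mean(pred == fs$labels), 1.0)
  }
})

test_that("training is seed-deterministic and single-class sets are rejected", {
  fs <- make_blobs(n_per = 40, K = 3, spread = 0.1, seed = 2)
  m1 <- train_gesture_mlp(fs, mlp_config(seed = 9))
  m2 <- train_gesture_mlp(fs, mlp_config(seed = 9))
  expect_identical(predict(m1, fs), predict(m2, fs))
  one <- feature_set(matrix(runif(20), 10, 2), rep(1, 10))
  expect_error(train_gesture_mlp(one), ">= 2 classes")
})

test_that("uninformative features yield chance-level accuracy", {
  # features identical across classes carry no information: accuracy on a
  # balanced 5-class test set must fall within binomial 99% bounds of 0.2
  set.seed(21)
  n <- 500
  x <- matrix(runif(n * 4), n, 4)
  labels <- rep(1:5, each = n / 5)[sample(n)]  # labels independent of x
  fs <- feature_set(x, labels)
  sp <- split_feature_set(fs, split_spec(seed = 5))
  model <- train_gesture_mlp(sp$train, mlp_config(seed = 5))
  rep_ <- evaluate(model, sp$test)
  n_test <- rep_$n_test
  bounds <- qbinom(c(0.005, 0.995), n_test, 0.2) / n_test
  expect_gte(rep_$overall_accuracy, bounds[1])
  expect_lte(rep_$overall_accuracy, bounds[2])
})

test_that("evaluate reports a consistent confusion matrix", {
  fs <- make_blobs(n_per = 30, K = 3, spread = 0.05, seed = 6)
  sp <- split_feature_set(fs, split_spec(seed = 6))
  model <- train_gesture_mlp(sp$train, mlp_config(seed = 6))
  rep_ <- evaluate(model, sp$test)
  expect_equal(sum(rep_$confusion), rep_$n_test)
  expect_equal(sum(diag(rep_$confusion)) / sum(rep_$confusion),
               rep_$overall_accuracy)
  expect_equal(as.vector(rowSums(rep_$confusion)),
               as.vector(table(sp$test$labels)))
  expect_true(rep_$overall_accuracy >= 0 && rep_$overall_accuracy <= 1)
  # dimension mismatch is caught
  expect_error(predict(model, matrix(0, 2, 5)), "does not match")
})
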