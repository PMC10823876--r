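# SFV separability statistic.

test_that("class means and stds follow their definitions", {
  fs <- feature_set(rbind(c(0, 0), c(1, 1), c(0.5, 0.5)), c(1, 1, 2))
  mu <- class_means(fs)
  expect_equal(mu["1", ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(mu["2", ], c(0.5, 0.5), ignore_attr = TRUE)  # single sample
  sd_ <- class_stds(fs)
  expect_equal(sd_["1", ], c(0.5, 0.5), ignore_attr = TRUE)  # population, J = 2
  expect_equal(sd_["2", ], c(0, 0), ignore_attr = TRUE)      # J = 1 gives 0
  # duplicated rows leave the mean unchanged
  fs2 <- feature_set(rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1)), c(1, 1, 1, 1))
  expect_equal(class_means(fs2)["1", ], c(0.5, 0.5), ignore_attr = TRUE)
  # sample-divisor variant
  expect_equal(class_stds(fs, divisor = "sample")["1", ],
               c(sd(c(0, 1)), sd(c(0, 1))), ignore_attr = TRUE)
})

test_that("between_dispersion averages pairwise distances of class means", {
  expect_equal(between_dispersion(rbind(0.1, 0.9)), 0.8)
  expect_equal(between_dispersion(rbind(0, 1, 2)), 4 / 3)  # (2/6)(1+1+2)
  expect_equal(between_dispersion(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  expect_error(between_dispersion(rbind(c(1, 2))), "K >= 2")
})

test_that("within_dispersion is the grand mean of the std matrix", {
  expect_equal(within_dispersion(rbind(0.1, 0.1)), 0.1)
  expect_equal(within_dispersion(matrix(0, 3, 4)), 0)
  expect_equal(within_dispersion(matrix(0.7, 2, 3)), 0.7)
})

test_that("the worked 1-D two-class example gives D = 0.8, c = 0.1, SFV = 8", {
  fs <- feature_set(matrix(c(0, 0.2, 0.8, 1.0), ncol = 1), c(1, 1, 2, 2))
  out <- sfv_score(fs)
  expect_equal(out$D, 0.8)
  expect_equal(out$c, 0.1)
  expect_equal(out$sfv, 8.0)
})

test_that("sfv_score matches the brute-force oracle on random sets", {
  set.seed(101)
  for (rep in 1:40) {
    K <- sample(2:5, 1)
    I <- sample(1:6, 1)
    fs <- random_feature_set(K, I, J_max = 10)
    got <- sfv_score(fs)
    want <- brute_force_sfv(fs$x, fs$labels)
    expect_equal(got$D, want$D, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    expect_equal(got$sfv, want$sfv, tolerance = 1e-12)
  }
})

test_that("SFV is invariant to label permutation, feature permutation, scale and shift", {
  set.seed(7)
  fs <- random_feature_set(4, 3, J_max = 8)
  base <- sfv_score(fs)$sfv
  # label permutation (relabelling classes)
  perm <- sample(1:4)
  fs_l <- feature_set(fs$x, perm[fs$labels])
  expect_equal(sfv_score(fs_l)$sfv, base, tolerance = 1e-12)
  # feature (column) permutation
  fs_f <- feature_set(fs$x[, c(3, 1, 2)], fs$labels)
  expect_equal(sfv_score(fs_f)$sfv, base, tolerance = 1e-12)
  # positive scaling and translation (warns: leaves [0, 1])
  fs_s <- feature_set(0.4 * fs$x, fs$labels)
  expect_equal(sfv_score(fs_s)$sfv, base, tolerance = 1e-12)
  fs_t <- feature_set(fs$x + 5, fs$labels)
  expect_equal(suppressWarnings(sfv_score(fs_t)$sfv), base, tolerance = 1e-12)
})

test_that("moving a class mean outward does not decrease SFV", {
  set.seed(13)
  x <- rbind(matrix(runif(20, 0.4, 0.6), 10, 2),
             matrix(runif(20, 0.2, 0.4), 10, 2))
  labels <- rep(1:2, each = 10)
  base <- sfv_score(feature_set(x, labels))$sfv
  pushed <- x
  pushed[labels == 1, ] <- pushed[labels == 1, ] + 0.3  # radially away
  expect_gte(sfv_score(feature_set(pushed, labels))$sfv, base)
})

test_that("degenerate cases: identical means, collapsed clusters, undefined SFV", {
  # identical class means with spread: D = 0 so SFV = 0
  x <- rbind(c(0, 1), c(1, 0), c(0, 0), c(1, 1))
  out <- sfv_score(feature_set(x, c(1, 1, 2, 2)))
  expect_equal(out$sfv, 0)
  # collapsed clusters with distinct means: +Inf with the degenerate flag
  y <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  out2 <- sfv_score(feature_set(y, c(1, 1, 2, 2)))
  expect_true(is.infinite(out2$sfv))
  expect_true(out2$degenerate)
  # everything identical: undefined
  z <- matrix(0.5, 4, 2)
  expect_error(sfv_score(feature_set(z, c(1, 1, 2, 2))), "undefined")
  # single class: not enough classes
  expect_error(sfv_score(feature_set(y, rep(1, 4))), "K >= 2")
  # out-of-range features warn but compute
  expect_warning(sfv_score(feature_set(y * 2, c(1, 1, 2, 2))), "outside")
})
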