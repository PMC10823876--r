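# Independent brute-force oracles and tiny fixtures, built in code.

# Brute-force SFV: explicit double loops over the definitions of the
# class means, class standard deviations (population), the mean
# pairwise distance between class means and the grand mean of the
# standard deviations. Kept deliberately naive and separate from the
# package implementation.
brute_force_sfv <- function(x, labels) {
  classes <- sort(unique(labels))
  K <- length(classes)
  I <- ncol(x)
  means <- matrix(0, K, I)
  stds <- matrix(0, K, I)
  for (ki in seq_len(K)) {
    rows <- which(labels == classes[ki])
    J <- length(rows)
    for (i in seq_len(I)) {
      s <- 0
      for (j in rows) s <- s + x[j, i]
      mu <- s / J
      means[ki, i] <- mu
      ss <- 0
      for (j in rows) ss <- ss + (x[j, i] - mu)^2
      stds[ki, i] <- sqrt(ss / J)
    }
  }
  total <- 0
  for (p in seq_len(K - 1)) {
    for (q in (p + 1):K) {
      d2 <- 0
      for (i in seq_len(I)) d2 <- d2 + (means[p, i] - means[q, i])^2
      total <- total + sqrt(d2)
    }
  }
  D <- 2 * total / (K * (K - 1))
  cs <- 0
  for (ki in seq_len(K)) for (i in seq_len(I)) cs <- cs + stds[ki, i]
  c_ <- cs / (I * K)
  list(D = D, c = c_, sfv = D / c_)
}

# Random labeled feature set with every class nonempty.
random_feature_set <- function(K, I, J_max) {
  labels <- integer(0)
  for (k in seq_len(K)) labels <- c(labels, rep(k, sample(1:J_max, 1)))
  if (length(labels) < 2) labels <- c(labels, labels)
  x <- matrix(runif(length(labels) * I), ncol = I)
  feature_set(x, labels)
}

# Small deterministic window for structural tests.
toy_window <- function(m = 40, n = 3, fs = 1000, seed = 1) {
  set.seed(seed)
  sample_matrix(matrix(rnorm(m * n), m, n), fs = fs)
}

# A quiet profile variant for fast simulator tests.
quiet_profile <- function(...) {
  p <- default_activation_profile()
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}
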