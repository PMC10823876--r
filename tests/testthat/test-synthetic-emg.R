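# Gesture-conditioned synthetic sEMG generator.

test_that("default activation profile is a fixed 5 x 4 pattern with distinct rows", {
  p1 <- default_activation_profile()
  p2 <- default_activation_profile()
  expect_identical(p1$matrix, p2$matrix)
  expect_equal(dim(p1$matrix), c(5L, 4L))
  expect_true(all(p1$matrix >= 0))
  for (a in 1:4) for (b in (a + 1):5) {
    expect_false(all(p1$matrix[a, ] == p1$matrix[b, ]))
  }
  # qualitative involvement: thumb extensor raised for thumbs-up, fist,
  # open hand relative to its resting level on the "V" sign
  epl <- p1$matrix[, "extensor_pollicis_longus"]
  expect_true(all(epl[c("thumbs_up", "fist", "open_hand")] > epl["v_sign"]))
  edm <- p1$matrix[, "extensor_digiti_minimi"]
  expect_true(all(edm[c("ok_sign", "fist", "open_hand")] > edm["thumbs_up"]))
})

test_that("profile constructor rejects invalid inputs", {
  p <- default_activation_profile()
  expect_error(activation_profile(p$matrix[, 1:3], p$channels), "channels")
  bad <- p$matrix; bad[2, ] <- bad[1, ]
  expect_error(activation_profile(bad, p$channels), "distinct")
  neg <- p$matrix; neg[1, 1] <- -0.1
  expect_error(activation_profile(neg, p$channels), ">= 0")
  expect_error(activation_profile(p$matrix, p$channels, band = c(450, 20)))
})

test_that("simulate_window is seed-deterministic and validates inputs", {
  prof <- default_activation_profile()
  cfg <- sim_config(seed = 7)
  w1 <- simulate_window("fist", prof, cfg, seed = 7)
  w2 <- simulate_window("fist", prof, cfg, seed = 7)
  expect_identical(unclass(w1), unclass(w2))
  expect_equal(dim(w1), c(200L, 4L))
  w3 <- simulate_window("fist", prof, cfg, seed = 8)
  expect_false(identical(unclass(w1), unclass(w3)))
  expect_error(simulate_window("clap", prof, cfg, seed = 1), "unknown gesture")
  expect_error(simulate_window(9, prof, cfg, seed = 1), "unknown gesture")
  short <- sim_config(window_len = 20, seed = 1)
  expect_error(simulate_window(1, prof, short, seed = 1), "minimum is 25")
})

test_that("zero activation with a silent noise floor gives an all-zero window", {
  prof <- quiet_profile(baseline_sd = 0)
  prof$matrix["thumbs_up", ] <- 0
  # rebuild through the constructor to keep invariants honest
  w <- simulate_window("thumbs_up", prof, sim_config(seed = 1), seed = 3)
  expect_true(all(w == 0))
})

test_that("doubling the activation scales the same seeded carrier exactly", {
  prof_a <- quiet_profile(baseline_sd = 0, jitter_sd = 0)
  prof_2a <- prof_a
  prof_2a$matrix <- 2 * prof_a$matrix
  cfg <- sim_config(seed = 5)
  wa <- simulate_window("fist", prof_a, cfg, seed = 5)
  w2a <- simulate_window("fist", prof_2a, cfg, seed = 5)
  ratio <- apply(unclass(w2a), 2, var) / apply(unclass(wa), 2, var)
  expect_equal(ratio, rep(4, 4), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("expected per-channel RMS is proportional to the activation", {
  # baseline off: RMS of a * jitter * carrier must scale linearly in a
  prof1 <- quiet_profile(baseline_sd = 0)
  prof3 <- prof1
  prof3$matrix <- 3 * prof1$matrix
  cfg <- sim_config(window_len = 200, seed = 2)
  r1 <- r3 <- numeric(50)
  for (i in 1:50) {
    r1[i] <- rms(unclass(simulate_window("fist", prof1, cfg, seed = i))[, 1])
    r3[i] <- rms(unclass(simulate_window("fist", prof3, cfg, seed = 1000 + i))[, 1])
  }
  expect_equal(mean(r3) / mean(r1), 3, tolerance = 0.1)
})

test_that("default profile separates gestures on every channel", {
  prof <- default_activation_profile()
  cfg <- sim_config(window_len = 200, n_windows_per_gesture = 50, seed = 4)
  ds <- simulate_dataset(prof, cfg)
  rms_mat <- t(vapply(ds$windows, function(w) apply(unclass(w), 2, rms),
                      numeric(4)))
  for (ch in 1:4) {
    found <- FALSE
    for (a in 1:4) for (b in (a + 1):5) {
      xa <- rms_mat[ds$labels == a, ch]
      xb <- rms_mat[ds$labels == b, ch]
      gap <- abs(mean(xa) - mean(xb))
      pooled_se <- sqrt(var(xa) / length(xa) + var(xb) / length(xb))
      if (gap > 3 * pooled_se) found <- TRUE
    }
    expect_true(found, label = paste("channel", ch, "separates some pair"))
  }
})

test_that("simulate_dataset obeys the count law and is reproducible", {
  prof <- default_activation_profile()
  ds1 <- simulate_dataset(prof, sim_config(n_windows_per_gesture = 3, seed = 9))
  expect_length(ds1$windows, 15)
  expect_equal(as.vector(table(ds1$labels)), rep(3, 5))
  ds2 <- simulate_dataset(prof, sim_config(n_windows_per_gesture = 3, seed = 9))
  expect_identical(lapply(ds1$windows, unclass), lapply(ds2$windows, unclass))
  ds3 <- simulate_dataset(prof, sim_config(n_windows_per_gesture = 1, seed = 9))
  expect_length(ds3$windows, 5)
  expect_equal(sort(unique(ds3$labels)), 1:5)
})

test_that("channel subsetting preserves window content and profile noise model", {
  prof <- default_activation_profile()
  ds <- simulate_dataset(prof, sim_config(n_windows_per_gesture = 2, seed = 6))
  keep <- c("extensor_pollicis_longus", "extensor_digiti_minimi")
  sub <- subset_channels(ds, keep)
  expect_identical(colnames(sub$windows[[1]]), keep)
  expect_equal(unclass(sub$windows[[3]])[, 1],
               unclass(ds$windows[[3]])[, "extensor_pollicis_longus"])
  expect_equal(sub$profile$common_gain, prof$common_gain)
  expect_error(subset_channels(ds, "biceps"), "unknown channel")
})

test_that("write_dataset produces per-window files and a manifest that reads back", {
  dir <- withr::local_tempdir()
  prof <- quiet_profile()
  ds <- simulate_dataset(prof, sim_config(n_windows_per_gesture = 1, seed = 2))
  manifest <- write_dataset(ds, dir)
  expect_equal(nrow(manifest), 5)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  w <- read_window(file.path(dir, manifest$filename[1]), fs = 1000)
  expect_equal(unclass(w), unclass(ds$windows[[1]]), tolerance = 1e-12,
               ignore_attr = TRUE)
})
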