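# Experiment pipeline: simulate -> (augment) -> extract -> normalize ->
# SFV -> split -> train -> evaluate, with paired before/after-
# augmentation comparisons, the channel-count sweep and the small-
# subsample study.

#' Default channel subsets for the 2-/3-/4-channel experiments
#'
#' The 2-channel configuration uses the thumb extensor (extensor
#' pollicis longus) and the little-finger extensor (extensor digiti
#' minimi); the 3-channel configuration adds the finger flexor (flexor
#' digitorum superficialis); the 4-channel configuration adds extensor
#' carpi ulnaris.
#'
#' @param n_channels 2, 3 or 4.
#' @return Character vector of muscle channel names.
#' @export
default_channel_subset <- function(n_channels) {
  all4 <- c("extensor_pollicis_longus", "extensor_digiti_minimi",
            "flexor_digitorum_superficialis", "extensor_carpi_ulnaris")
  if (!(n_channels %in% 2:4)) stop("n_channels must be 2, 3 or 4")
  all4[seq_len(n_channels)]
}

#' Experiment configuration
#'
#' @param channels character vector of 2-4 muscle channel names drawn
#'   from the simulator's 4 muscles (default: all 4).
#' @param augment append all pairwise virtual channels before feature
#'   extraction (default TRUE).
#' @param n_per_gesture simulated windows per gesture (default 150).
#' @param train_fraction training fraction of the stratified split
#'   (default 2/3).
#' @param n_seeds number of independent replicate seeds, each playing
#'   the role of one recorded subject (default 20).
#' @param seed master integer seed.
#' @param profile an [activation_profile()]; default
#'   [default_activation_profile()].
#' @param mlp an [mlp_config()] used for every arm.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(channels = default_channel_subset(4),
                              augment = TRUE,
                              n_per_gesture = 150,
                              train_fraction = 2 / 3,
                              n_seeds = 20,
                              seed = 1L,
                              profile = default_activation_profile(),
                              mlp = mlp_config()) {
  if (length(channels) < 1) stop("channel subset must be nonempty")
  if (!all(channels %in% profile$channels)) {
    stop("channels must be drawn from the simulated muscles: ",
         paste(profile$channels, collapse = ", "))
  }
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  structure(list(channels = channels, augment = isTRUE(augment),
                 n_per_gesture = as.integer(n_per_gesture),
                 train_fraction = train_fraction,
                 n_seeds = as.integer(n_seeds), seed = as.integer(seed),
                 profile = profile, mlp = mlp),
            class = "experiment_config")
}

# Stage-seed tags; arbitrary distinct constants outside gesture ids 1..5.
.SEED_ARM <- 11L
.SEED_SPLIT <- 12L
.SEED_MLP <- 13L
.SEED_SUBSAMPLE <- 14L

#' Run one experiment arm
#'
#' Executes the full pipeline for one arm (with or without virtual
#' channels) under one seed: simulate a dataset (or reuse a supplied
#' one), optionally augment every window, extract features, draw the
#' stratified split, fit the min-max normalizer on the training rows
#' and apply it to all rows, compute SFV on the normalized set, train
#' the classifier and evaluate it on the test rows. All stage seeds are
#' derived from `seed`.
#'
#' @param cfg an [experiment_config()].
#' @param augment override of `cfg$augment` (logical).
#' @param seed integer arm seed.
#' @param dataset optional pre-simulated `emg_dataset` (it is subset to
#'   `cfg$channels`); used by the paired comparison so both arms see
#'   byte-identical raw windows.
#' @return List with `accuracy`, `sfv` (an `sfv_components`), `report`
#'   (an `evaluation_report`), `n_features`, `seed`, `augment`.
#' @export
run_arm <- function(cfg, augment = cfg$augment, seed = cfg$seed,
                    dataset = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(dataset)) {
    sim_cfg <- sim_config(n_windows_per_gesture = cfg$n_per_gesture,
                          seed = seed)
    dataset <- simulate_dataset(cfg$profile, sim_cfg)
  }
  if (!identical(dataset$profile$channels, cfg$channels)) {
    dataset <- subset_channels(dataset, cfg$channels)
  }
  windows <- dataset$windows
  if (augment) windows <- lapply(windows, augment, pairs = "all")
  feats <- extract_features_all(windows)

  raw_fs <- feature_set(feats, dataset$labels)
  sp <- split_feature_set(
    raw_fs, split_spec(train_fraction = cfg$train_fraction,
                       seed = derive_seed(seed, .SEED_SPLIT, 1L)))
  norm <- fit_normalizer(feats[sp$train_idx, , drop = FALSE])
  x_norm <- apply_normalizer(feats, norm)
  fs_all <- feature_set(x_norm, dataset$labels)
  train <- feature_set(x_norm[sp$train_idx, , drop = FALSE],
                       dataset$labels[sp$train_idx])
  test <- feature_set(x_norm[sp$test_idx, , drop = FALSE],
                      dataset$labels[sp$test_idx])

  sfv <- sfv_score(fs_all)
  mlp_cfg <- cfg$mlp
  mlp_cfg$seed <- derive_seed(seed, .SEED_MLP, 1L)
  model <- train_gesture_mlp(train, mlp_cfg)
  report <- evaluate(model, test)
  list(accuracy = report$overall_accuracy, sfv = sfv, report = report,
       n_features = ncol(feats), seed = seed, augment = augment)
}

#' Paired before/after-augmentation comparison
#'
#' For each of `n_seeds` replicate seeds, simulates one dataset and
#' runs both arms — plain physical channels and channels plus all
#' virtual channels — on byte-identical raw windows, recording test
#' accuracy and the SFV decomposition for each arm. Reports per-seed
#' values, per-seed deltas (augmented minus plain) and aggregate means
#' and standard deviations.
#'
#' @param cfg an [experiment_config()]; its `augment` flag is ignored
#'   (both arms are run).
#' @return Object of class `vdi_comparison`: `runs` (long data.frame:
#'   seed, arm, accuracy, sfv, D, c, n_features), `deltas` (per-seed
#'   accuracy and SFV differences), `summary` (per-arm means/sds),
#'   `config`.
#' @export
compare_vdi <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list()
  deltas <- list()
  for (s in seq_len(cfg$n_seeds)) {
    arm_seed <- derive_seed(cfg$seed, .SEED_ARM, s)
    sim_cfg <- sim_config(n_windows_per_gesture = cfg$n_per_gesture,
                          seed = arm_seed)
    ds <- simulate_dataset(cfg$profile, sim_cfg)
    ds <- subset_channels(ds, cfg$channels)
    plain <- run_arm(cfg, augment = FALSE, seed = arm_seed, dataset = ds)
    aug <- run_arm(cfg, augment = TRUE, seed = arm_seed, dataset = ds)
    for (arm in list(plain, aug)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seed = arm_seed,
        arm = if (arm$augment) "augmented" else "plain",
        accuracy = arm$accuracy, sfv = arm$sfv$sfv,
        D = arm$sfv$D, c = arm$sfv$c, n_features = arm$n_features)
    }
    deltas[[length(deltas) + 1L]] <- data.frame(
      seed = arm_seed,
      d_accuracy = aug$accuracy - plain$accuracy,
      d_sfv = aug$sfv$sfv - plain$sfv$sfv)
  }
  runs <- do.call(rbind, rows)
  deltas <- do.call(rbind, deltas)
  summary <- do.call(rbind, lapply(split(runs, runs$arm), function(g) {
    data.frame(arm = g$arm[1], n_seeds = nrow(g),
               mean_accuracy = mean(g$accuracy), sd_accuracy = stats::sd(g$accuracy),
               mean_sfv = mean(g$sfv), sd_sfv = stats::sd(g$sfv))
  }))
  rownames(summary) <- NULL
  structure(list(runs = runs, deltas = deltas, summary = summary,
                 config = cfg),
            class = "vdi_comparison")
}

#' @export
print.vdi_comparison <- function(x, ...) {
  cat("Before/after virtual-dimension increase (", length(x$config$channels),
      " channels, ", x$config$n_seeds, " seeds)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("mean delta (augmented - plain): accuracy %+0.4f, SFV %+0.4f\n",
              mean(x$deltas$d_accuracy), mean(x$deltas$d_sfv)))
  invisible(x)
}

#' Channel-count sweep with paired arms
#'
#' Runs the paired comparison at 2, 3 and 4 channels. For each seed one
#' 4-channel dataset is simulated and the smaller configurations reuse
#' its columns, so results across channel counts are paired as well.
#'
#' @param cfg an [experiment_config()]; `channels` is ignored (the
#'   default subsets for each count are used).
#' @param channel_counts subset of 2:4 (default all three).
#' @return Long data.frame: seed, n_channels, arm, accuracy, sfv, D, c,
#'   n_features.
#' @export
channel_sweep <- function(cfg, channel_counts = 2:4) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list()
  for (s in seq_len(cfg$n_seeds)) {
    arm_seed <- derive_seed(cfg$seed, .SEED_ARM, s)
    sim_cfg <- sim_config(n_windows_per_gesture = cfg$n_per_gesture,
                          seed = arm_seed)
    ds4 <- simulate_dataset(cfg$profile, sim_cfg)
    for (nc in channel_counts) {
      chans <- default_channel_subset(nc)
      ds <- subset_channels(ds4, chans)
      cfg_nc <- cfg
      cfg_nc$channels <- chans
      for (aug in c(FALSE, TRUE)) {
        arm <- run_arm(cfg_nc, augment = aug, seed = arm_seed, dataset = ds)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = arm_seed, n_channels = nc,
          arm = if (aug) "augmented" else "plain",
          accuracy = arm$accuracy, sfv = arm$sfv$sfv,
          D = arm$sfv$D, c = arm$sfv$c, n_features = arm$n_features)
      }
    }
  }
  do.call(rbind, rows)
}

#' Small-subsample study
#'
#' Emulates the sample-size experiment: from each simulated dataset,
#' `size` windows per gesture are drawn at random, split 2:1, and both
#' recognition accuracy and SFV are recorded, for every per-gesture
#' size and every channel count. Accuracy estimated from few test
#' windows is noisy, while SFV, computed from the whole subsample,
#' varies less — the property this study quantifies.
#'
#' @param cfg an [experiment_config()]; `cfg$augment` selects the arm
#'   used throughout (default TRUE: the augmented pipeline).
#' @param sizes per-gesture subsample sizes, each at most
#'   `cfg$n_per_gesture` (default `c(60, 90, 120, 150)`).
#' @param channel_counts subset of 2:4 (default all three).
#' @return Long data.frame: seed, size, n_channels, accuracy, sfv, D, c.
#' @export
subsample_study <- function(cfg, sizes = c(60, 90, 120, 150),
                            channel_counts = 2:4) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (any(sizes > cfg$n_per_gesture)) {
    stop("subsample size exceeds n_per_gesture (", cfg$n_per_gesture, ")")
  }
  if (any(sizes < 3)) stop("subsample sizes must be >= 3 per gesture")
  rows <- list()
  for (s in seq_len(cfg$n_seeds)) {
    arm_seed <- derive_seed(cfg$seed, .SEED_ARM, s)
    sim_cfg <- sim_config(n_windows_per_gesture = cfg$n_per_gesture,
                          seed = arm_seed)
    ds4 <- simulate_dataset(cfg$profile, sim_cfg)
    for (size in sizes) {
      keep <- subsample_indices(ds4$labels, size,
                                derive_seed(arm_seed, .SEED_SUBSAMPLE, size))
      sub4 <- ds4
      sub4$windows <- ds4$windows[keep]
      sub4$labels <- ds4$labels[keep]
      sub4$cfg$n_windows_per_gesture <- as.integer(size)
      for (nc in channel_counts) {
        chans <- default_channel_subset(nc)
        cfg_nc <- cfg
        cfg_nc$channels <- chans
        arm <- run_arm(cfg_nc, augment = cfg$augment, seed = arm_seed,
                       dataset = subset_channels(sub4, chans))
        rows[[length(rows) + 1L]] <- data.frame(
          seed = arm_seed, size = size, n_channels = nc,
          accuracy = arm$accuracy, sfv = arm$sfv$sfv,
          D = arm$sfv$D, c = arm$sfv$c)
      }
    }
  }
  do.call(rbind, rows)
}

# Seeded per-class subsample; indices are sorted so that drawing the
# full class reproduces the original dataset exactly.
subsample_indices <- function(labels, size, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  keep <- integer(0)
  for (k in sort(unique(labels))) {
    rows <- which(labels == k)
    if (size > length(rows)) stop("subsample size exceeds class size")
    keep <- c(keep, sort(sample(rows, size)))
  }
  sort(keep)
}

#' Write an experiment report with a JSON provenance record
#'
#' Writes the long run table as CSV and a JSON provenance record
#' (configuration, seeds, package version) next to it.
#'
#' @param runs data.frame of runs (from [compare_vdi()], `$runs`, or
#'   [channel_sweep()] / [subsample_study()]).
#' @param cfg the [experiment_config()] that produced them.
#' @param dir output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(runs, cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  runs_path <- file.path(dir, "runs.csv")
  prov_path <- file.path(dir, "provenance.json")
  utils::write.csv(runs, runs_path, row.names = FALSE)
  prov <- list(
    package = "vdiemg",
    version = as.character(utils::packageVersion("vdiemg")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = list(channels = cfg$channels, augment = cfg$augment,
                  n_per_gesture = cfg$n_per_gesture,
                  train_fraction = cfg$train_fraction,
                  n_seeds = cfg$n_seeds, seed = cfg$seed,
                  jitter_sd = cfg$profile$jitter_sd,
                  baseline_sd = cfg$profile$baseline_sd,
                  band = cfg$profile$band))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(runs_path, prov_path))
}
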