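# Per-column window features and min-max normalization.
#
# Three features per column: the amplitude spread of the rectified
# signal (abs_std), the root mean square (rms), and the mean power
# frequency (mpf) of the periodogram. Population (1/m) denominators are
# used throughout for internal consistency with the separability
# statistic.

#' Absolute standard deviation of a signal
#'
#' The population standard deviation of the rectified signal `|s|`:
#' `sqrt(mean((|s| - mean(|s|))^2))`. An amplitude-spread feature of
#' the time domain. Set `method = "mav"` to use the mean absolute value
#' instead, an alternative standard sEMG amplitude feature.
#'
#' @param column numeric vector, length >= 2.
#' @param method `"abs_std"` (default) or `"mav"`.
#' @return scalar feature value.
#' @examples
#' abs_std(c(0, 2))  # |s| = (0, 2): mean 1, population sd 1
#' @export
abs_std <- function(column, method = c("abs_std", "mav")) {
  method <- match.arg(method)
  if (length(column) < 2) stop("abs_std needs at least 2 samples")
  r <- abs(column)
  if (method == "mav") return(mean(r))
  sqrt(mean((r - mean(r))^2))
}

#' Root mean square of a signal
#'
#' `sqrt(mean(s^2))` — the standard sEMG amplitude/intensity feature.
#'
#' @param column numeric vector, length >= 1.
#' @return scalar feature value.
#' @export
rms <- function(column) {
  if (length(column) < 1) stop("rms needs at least 1 sample")
  sqrt(mean(column^2))
}

#' Mean power frequency of a signal
#'
#' The power-weighted mean frequency `sum(f * P) / sum(P)` over the
#' positive-frequency bins of the single-taper periodogram of the
#' mean-removed signal (no zero padding; bins `fs/m` apart; DC bin
#' excluded). Defined only for signals with nonzero power after mean
#' removal.
#'
#' @param column numeric vector, length >= 4.
#' @param fs sampling frequency in Hz.
#' @return scalar frequency in (0, fs/2].
#' @examples
#' t <- (0:199) / 1000
#' mean_power_frequency(sin(2 * pi * 100 * t), fs = 1000)  # 100
#' @export
mean_power_frequency <- function(column, fs) {
  m <- length(column)
  if (m < 4) stop("mean_power_frequency needs at least 4 samples")
  x <- column - mean(column)
  if (all(x == 0)) stop("undefined MPF for zero-power signal")
  spec <- Mod(stats::fft(x))^2
  nb <- floor(m / 2)
  bins <- 2:(nb + 1)            # positive frequencies, DC excluded
  f <- (bins - 1) * fs / m
  p <- spec[bins]
  sum(f * p) / sum(p)
}

#' Extract the three per-column features from a window
#'
#' Computes, for every column of a (possibly augmented) window, the
#' triplet `(abs_std, rms, mpf)` in a fixed layout: all three features
#' of column 1, then of column 2, and so on. A plain 4-channel window
#' gives 12 values; the fully augmented 4-channel window (10 columns)
#' gives 30.
#'
#' @param window a [sample_matrix()] or [augment()]ed matrix.
#' @param amplitude_method passed to [abs_std()].
#' @return Named numeric vector of length `3 * ncol(window)`, names
#'   `<col>_absstd`, `<col>_rms`, `<col>_mpf`.
#' @export
extract_features <- function(window, amplitude_method = "abs_std") {
  stopifnot(inherits(window, "sample_matrix"))
  fs <- attr(window, "fs")
  x <- unclass(window)
  out <- numeric(3L * ncol(x))
  nm <- character(length(out))
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    k <- 3L * (j - 1L)
    out[k + 1L] <- abs_std(col, method = amplitude_method)
    out[k + 2L] <- rms(col)
    out[k + 3L] <- mean_power_frequency(col, fs)
    nm[k + (1:3)] <- paste0(colnames(x)[j], c("_absstd", "_rms", "_mpf"))
  }
  names(out) <- nm
  out
}

#' Extract a feature matrix from a list of windows
#'
#' @param windows list of windows (all the same width), e.g.
#'   `emg_dataset$windows`, optionally after [augment()].
#' @param amplitude_method passed to [abs_std()].
#' @return Numeric matrix, one row per window.
#' @export
extract_features_all <- function(windows, amplitude_method = "abs_std") {
  rows <- lapply(windows, extract_features, amplitude_method = amplitude_method)
  do.call(rbind, rows)
}

#' Fit a per-feature min-max normalizer
#'
#' Records the per-feature minimum and maximum over a training feature
#' matrix; [apply_normalizer()] then maps each feature linearly via
#' `y = (x - x_min) / (x_max - x_min)` onto `[0, 1]`. Fit the
#' normalizer on training rows only: fitting on all data would leak
#' test-set information.
#'
#' @param x numeric feature matrix (>= 2 rows) or list of feature
#'   vectors.
#' @return Object of class `minmax_normalizer` with fields `x_min`,
#'   `x_max`.
#' @export
fit_normalizer <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("fit_normalizer needs >= 2 training vectors")
  structure(list(x_min = apply(x, 2, min), x_max = apply(x, 2, max)),
            class = "minmax_normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' Maps each feature through `y = (x - x_min) / (x_max - x_min)` and
#' clips the result to `[0, 1]`, so test values outside the training
#' range saturate at the endpoints. Degenerate features with
#' `x_min == x_max` map to 0.
#'
#' @param x feature vector or matrix whose width matches the params.
#' @param params a `minmax_normalizer` from [fit_normalizer()].
#' @return Normalized vector or matrix with entries in `[0, 1]`.
#' @export
apply_normalizer <- function(x, params) {
  stopifnot(inherits(params, "minmax_normalizer"))
  vec <- is.null(dim(x))
  x <- rbind(x)
  if (ncol(x) != length(params$x_min)) {
    stop("feature length (", ncol(x), ") does not match normalizer (",
         length(params$x_min), ")")
  }
  rng <- params$x_max - params$x_min
  out <- sweep(x, 2, params$x_min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (vec) out[1, ] else out
}

#' Bundle normalized features and gesture labels
#'
#' A labeled feature set is the classifier- and SFV-facing container:
#' a J_total x I matrix of normalized feature vectors (entries in
#' `[0, 1]`) with one gesture label per row.
#'
#' @param x numeric matrix of normalized feature vectors.
#' @param labels integer gesture ids (or factor), one per row.
#' @return Object of class `feature_set` with fields `x`, `labels`.
#' @export
feature_set <- function(x, labels) {
  x <- as.matrix(x)
  labels <- if (is.factor(labels)) as.integer(as.character(labels)) else as.integer(labels)
  if (length(labels) != nrow(x)) stop("one label per feature row required")
  if (any(!is.finite(x))) stop("feature values must be finite")
  structure(list(x = x, labels = labels), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("Labeled feature set: ", nrow(x$x), " samples x ", ncol(x$x),
      " features, classes: ", paste(sort(unique(x$labels)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
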