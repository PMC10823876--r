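# Raw sample-matrix container and delimited-text I/O.

#' Construct a raw sEMG sample matrix
#'
#' A sample matrix holds one analysis window: an m x n real matrix with
#' rows = time samples and columns = physical channels, together with
#' the sampling frequency. The canonical window in this package is
#' 200 ms at 1 kHz, i.e. m = 200, but any m >= 2 is accepted.
#'
#' @param data numeric matrix, m >= 2 rows, n >= 1 columns, all entries
#'   finite.
#' @param fs sampling frequency in Hz.
#' @param channel_names optional character vector of unique channel
#'   names; defaults to existing column names, else `ch1..chn`.
#' @return A numeric matrix of class `sample_matrix` with attribute
#'   `fs` and channel names as column names.
#' @export
sample_matrix <- function(data, fs, channel_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("sample matrix must be numeric")
  if (nrow(data) < 2) stop("sample matrix needs m >= 2 time samples")
  if (ncol(data) < 1) stop("sample matrix needs n >= 1 channels")
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite entry at row ", bad[1, 1], ", column ", bad[1, 2])
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (is.null(channel_names)) {
    channel_names <- colnames(data)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(ncol(data)))
    }
  }
  if (length(channel_names) != ncol(data)) {
    stop("channel_names length must equal the number of columns")
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  dimnames(data) <- list(NULL, channel_names)
  structure(data, fs = fs, class = c("sample_matrix", "matrix", "array"))
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat("sEMG window: ", nrow(x), " samples x ", ncol(x), " channels, fs = ",
      attr(x, "fs"), " Hz\n", sep = "")
  utils::str(unclass(x))
  invisible(x)
}

# Detect comma vs tab from the first line; decimal point assumed.
detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read one raw window from a delimited text file
#'
#' Reads a rectangular numeric CSV/TSV matrix (delimiter auto-detected),
#' with an optional header row of channel names, and validates it as a
#' [sample_matrix()]. Non-numeric or missing cells are rejected with the
#' offending row and column.
#'
#' @param path file path.
#' @param fs sampling frequency in Hz of the recording.
#' @return A [sample_matrix()].
#' @export
read_window <- function(path, fs) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  first <- gsub('^"|"$', "", first)
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  raw <- utils::read.table(path, header = has_header, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  mat <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop("non-numeric or non-finite value at row ", bad[1],
           ", column ", j, " of ", path)
    }
    mat[, j] <- v
  }
  ch <- if (has_header) make.unique(first) else NULL
  sample_matrix(mat, fs = fs, channel_names = ch)
}

#' Write a window to a delimited text file
#'
#' @param x a [sample_matrix()] or [augment()]ed matrix.
#' @param path output file path (CSV, header = channel names).
#' @return Invisibly, `path`.
#' @export
write_window <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  invisible(path)
}

#' Segment a longer recording into fixed-length analysis windows
#'
#' Cuts an m-row recording into windows of `window_len` rows starting at
#' 0-based offsets `0, step, 2*step, ...`; a trailing partial window is
#' discarded. The default step equals the window length (disjoint
#' 200-ms samples).
#'
#' @param recording a [sample_matrix()].
#' @param window_len window length in samples.
#' @param step hop between window starts in samples (default
#'   `window_len`, no overlap).
#' @return A list of [sample_matrix()] windows with `fs` and channel
#'   names preserved.
#' @examples
#' rec <- sample_matrix(matrix(rnorm(1000 * 2), 1000, 2), fs = 1000)
#' length(segment(rec, 200))  # 5 disjoint windows
#' @export
segment <- function(recording, window_len, step = window_len) {
  stopifnot(inherits(recording, "sample_matrix"))
  m <- nrow(recording)
  if (window_len > m) {
    stop("window_len (", window_len, ") exceeds recording length (", m, ")")
  }
  if (window_len < 2) stop("window_len must be >= 2")
  if (step < 1) stop("step must be >= 1")
  starts <- seq(0L, m - window_len, by = step)
  lapply(starts, function(s) {
    sample_matrix(unclass(recording)[(s + 1):(s + window_len), , drop = FALSE],
                  fs = attr(recording, "fs"),
                  channel_names = colnames(recording))
  })
}
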