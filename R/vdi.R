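# Virtual-dimension increase: append pairwise |S_i^2 - S_j^2| virtual
# channels to a raw window, encoding the difference in activity
# intensity between two muscles without extra electrodes.

#' Elementwise square of a sample matrix
#'
#' Squaring the raw samples gives, pointwise in time, the instantaneous
#' intensity of activity of each muscle; it is the first step of the
#' virtual-dimension increase.
#'
#' @param S a [sample_matrix()].
#' @return The m x n matrix of squared entries (plain matrix).
#' @export
square_sample <- function(S) {
  stopifnot(inherits(S, "sample_matrix"))
  unclass(S)^2
}

#' One virtual channel from a pair of physical channels
#'
#' The virtual channel for channels `i` and `j` is the elementwise
#' absolute difference of their squared signals, `|S_i^2 - S_j^2|`: a
#' nonnegative time series measuring how differently the two muscles
#' are contracting at each instant. It is symmetric in `(i, j)` and
#' identically zero when the channels coincide.
#'
#' @param S a [sample_matrix()].
#' @param i,j distinct physical channel indices.
#' @return Numeric m-vector.
#' @examples
#' S <- sample_matrix(cbind(c(1, 2), c(1, 0)), fs = 1000)
#' virtual_channel(S, 1, 2)  # (0, 4)
#' @export
virtual_channel <- function(S, i, j) {
  stopifnot(inherits(S, "sample_matrix"))
  n <- ncol(S)
  for (idx in c(i, j)) {
    if (!is.numeric(idx) || length(idx) != 1L || idx < 1 || idx > n ||
        idx != round(idx)) {
      stop("channel index ", idx, " out of range 1..", n)
    }
  }
  if (i == j) {
    stop("i and j must differ: the virtual channel of a channel with ",
         "itself is identically zero")
  }
  x <- unclass(S)
  abs(x[, i]^2 - x[, j]^2)
}

# Canonical pair order: lexicographic (i, j), i < j.
all_pairs <- function(n) {
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) out[[length(out) + 1L]] <- c(i, j)
  out
}

normalize_pairs <- function(pairs, n) {
  if (identical(pairs, "all")) {
    if (n < 2) {
      stop("virtual-dimension increase requires >= 2 physical channels")
    }
    return(all_pairs(n))
  }
  if (is.matrix(pairs)) pairs <- lapply(seq_len(nrow(pairs)), function(r) pairs[r, ])
  if (!is.list(pairs)) pairs <- list(pairs)
  pairs <- lapply(pairs, function(p) {
    if (length(p) != 2L) stop("each pair must have exactly 2 indices")
    p <- as.integer(p)
    if (any(p < 1) || any(p > n)) {
      stop("pair (", p[1], ",", p[2], ") out of channel range 1..", n)
    }
    if (p[1] == p[2]) stop("degenerate pair (", p[1], ",", p[2], ")")
    sort(p)
  })
  keys <- vapply(pairs, function(p) paste(p, collapse = "_"), "")
  if (anyDuplicated(keys)) {
    stop("duplicate pair: (", gsub("_", ",", keys[duplicated(keys)][1]), ")")
  }
  pairs
}

#' Augment a window with pairwise virtual channels
#'
#' Appends one virtual channel per requested channel pair to the
#' physical columns of `S`. With `pairs = "all"` (the default and the
#' method's standard setting) every unordered pair is used, so an
#' n-channel window gains `n(n-1)/2` virtual columns, for a total width
#' of `n + n(n-1)/2`. Virtual columns are ordered lexicographically by
#' `(i, j)` with `i < j` and named `v_i_j`; units are amplitude squared
#' (downstream min-max normalization absorbs the scale difference).
#'
#' @param S a [sample_matrix()].
#' @param pairs `"all"` or an explicit duplicate-free list of index
#'   pairs (each of length 2).
#' @return An object of class `augmented_matrix` (also a
#'   `sample_matrix`): the m x (n + P) matrix with attributes
#'   `physical_cols` (indices of the original columns) and
#'   `virtual_pairs` (list of `(i, j)` pairs in column order).
#' @examples
#' S <- sample_matrix(matrix(rnorm(400), 200, 2), fs = 1000)
#' ncol(augment(S))  # 2 physical + 1 virtual = 3
#' @export
augment <- function(S, pairs = "all") {
  stopifnot(inherits(S, "sample_matrix"))
  n <- ncol(S)
  pr <- normalize_pairs(pairs, n)
  vcols <- vapply(pr, function(p) virtual_channel(S, p[1], p[2]),
                  numeric(nrow(S)))
  vnames <- vapply(pr, function(p) sprintf("v_%d_%d", p[1], p[2]), "")
  out <- cbind(unclass(S), vcols)
  colnames(out) <- c(colnames(S), vnames)
  structure(out,
            fs = attr(S, "fs"),
            physical_cols = seq_len(n),
            virtual_pairs = pr,
            class = c("augmented_matrix", "sample_matrix", "matrix", "array"))
}

#' @export
print.augmented_matrix <- function(x, ...) {
  n <- length(attr(x, "physical_cols"))
  cat("Augmented sEMG window: ", nrow(x), " samples x ", ncol(x),
      " columns (", n, " physical + ", ncol(x) - n,
      " virtual), fs = ", attr(x, "fs"), " Hz\n", sep = "")
  invisible(x)
}
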