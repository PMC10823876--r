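# SFV: separability of feature vectors.
#
# SFV = D / c, where D is the mean Euclidean distance between all
# unordered pairs of class-mean feature vectors (interclass dispersion)
# and c is the grand mean of the per-class, per-feature standard
# deviations (intraclass dispersion). Larger SFV means classes form
# tighter, farther-apart clusters in feature space and predicts higher
# recognition accuracy before any classifier is trained.

split_by_class <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  classes <- sort(unique(fs$labels))
  lapply(stats::setNames(classes, classes),
         function(k) fs$x[fs$labels == k, , drop = FALSE])
}

#' Per-class mean feature vectors
#'
#' @param fs a [feature_set()].
#' @return K x I matrix; row k is the mean feature vector of class k.
#' @export
class_means <- function(fs) {
  by_cl <- split_by_class(fs)
  if (any(vapply(by_cl, nrow, 0L) == 0L)) stop("empty class")
  do.call(rbind, lapply(by_cl, colMeans))
}

#' Per-class, per-feature standard deviations
#'
#' Population form: divisor J_k (the class sample count), matching the
#' definition used by the separability statistic. A sample-form
#' (J_k - 1) variant is available for sensitivity analysis.
#'
#' @param fs a [feature_set()].
#' @param divisor `"population"` (default, divisor J) or `"sample"`
#'   (divisor J - 1; single-sample classes get 0).
#' @return K x I matrix of standard deviations.
#' @export
class_stds <- function(fs, divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  by_cl <- split_by_class(fs)
  if (any(vapply(by_cl, nrow, 0L) == 0L)) stop("empty class")
  do.call(rbind, lapply(by_cl, function(xk) {
    J <- nrow(xk)
    mu <- colMeans(xk)
    ss <- colSums(sweep(xk, 2, mu, "-")^2)
    den <- if (divisor == "population") J else max(J - 1, 1)
    sqrt(ss / den)
  }))
}

#' Interclass dispersion D
#'
#' The average Euclidean distance between class-mean feature vectors
#' over all unordered class pairs:
#' `D = 2 / (K (K - 1)) * sum_{p < q} ||mean_p - mean_q||`.
#'
#' @param means K x I matrix of class means (K >= 2).
#' @return Nonnegative scalar D.
#' @export
between_dispersion <- function(means) {
  means <- as.matrix(means)
  K <- nrow(means)
  if (K < 2) stop("between_dispersion needs K >= 2 classes")
  total <- 0
  for (p in 1:(K - 1)) for (q in (p + 1):K) {
    total <- total + sqrt(sum((means[p, ] - means[q, ])^2))
  }
  2 * total / (K * (K - 1))
}

#' Intraclass dispersion c
#'
#' The grand mean of all class-feature standard deviations:
#' `c = 1 / (I K) * sum_{i,k} s_i^k`. Smaller c means tighter class
#' clusters.
#'
#' @param stds K x I matrix of class standard deviations.
#' @return Nonnegative scalar c.
#' @export
within_dispersion <- function(stds) {
  stds <- as.matrix(stds)
  if (length(stds) < 1) stop("within_dispersion needs K >= 1, I >= 1")
  mean(stds)
}

#' Separability of feature vectors (SFV)
#'
#' Computes the full decomposition: class means, class standard
#' deviations, interclass dispersion D, intraclass dispersion c, and
#' `SFV = D / c`. If every cluster collapses to a point (c = 0) while
#' the means still differ (D > 0), the classes are perfectly separable
#' and SFV is reported as `Inf` with `degenerate = TRUE`; if in
#' addition D = 0 the whole dataset is one point and SFV is undefined.
#'
#' SFV is intended for feature sets normalized to `[0, 1]`; a warning
#' (not an error) is raised when inputs fall outside that interval.
#'
#' @param fs a [feature_set()] with K >= 2 nonempty classes.
#' @param divisor passed to [class_stds()].
#' @return Object of class `sfv_components`: list with `class_means`,
#'   `class_stds`, `D`, `c`, `sfv`, `degenerate`, `K`, `I`, `J_k`.
#' @examples
#' fs <- feature_set(matrix(c(0, 0.2, 0.8, 1.0), ncol = 1), c(1, 1, 2, 2))
#' sfv_score(fs)  # D = 0.8, c = 0.1, SFV = 8
#' @export
sfv_score <- function(fs, divisor = "population") {
  stopifnot(inherits(fs, "feature_set"))
  if (length(unique(fs$labels)) < 2) stop("sfv_score needs K >= 2 classes")
  if (any(fs$x < 0 | fs$x > 1)) {
    warning("feature values outside [0, 1]; SFV is defined on ",
            "min-max normalized features")
  }
  mu <- class_means(fs)
  sd_ <- class_stds(fs, divisor = divisor)
  D <- between_dispersion(mu)
  c_ <- within_dispersion(sd_)
  degenerate <- FALSE
  if (c_ == 0) {
    if (D == 0) stop("SFV undefined: D = c = 0 (all samples identical)")
    sfv <- Inf
    degenerate <- TRUE
  } else {
    sfv <- D / c_
  }
  structure(
    list(class_means = mu, class_stds = sd_, D = D, c = c_, sfv = sfv,
         degenerate = degenerate, K = nrow(mu), I = ncol(mu),
         J_k = table(fs$labels)),
    class = "sfv_components"
  )
}

#' @export
print.sfv_components <- function(x, ...) {
  cat("SFV decomposition (K = ", x$K, " classes, I = ", x$I,
      " features)\n", sep = "")
  cat(sprintf("  interclass dispersion D = %.6g\n", x$D))
  cat(sprintf("  intraclass dispersion c = %.6g\n", x$c))
  cat(sprintf("  SFV = D/c = %.6g%s\n", x$sfv,
              if (x$degenerate) " (degenerate: collapsed clusters)" else ""))
  invisible(x)
}
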