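# ---------------------------------------------------------------------------
# Preprocessing: zero-mean normalization, differential filtering, and
# three-state discretization.  These are the stages every selector's input
# passes through: features are z-scored per row, screened by a one-way
# ANOVA F test across the classes (p < alpha kept), and mapped to states
# {-1, 0, +1} for the mutual-information machinery.
# ---------------------------------------------------------------------------

row_sd <- function(x, population = TRUE) {
  n <- ncol(x)
  mu <- rowMeans(x)
  ss <- rowSums((x - mu)^2)
  sqrt(ss / if (population) n else n - 1L)
}

#' Drop constant features
#'
#' Features with zero variance across samples cannot be z-scored and carry
#' no class information; the pipeline removes them (with a warning) before
#' normalization.
#'
#' @param matrix an [omics_matrix()].
#' @return The matrix restricted to non-constant features.
#' @export
drop_constant_features <- function(matrix) {
  sds <- row_sd(unclass(matrix))
  const <- sds == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(const),
                    paste(utils::head(rownames(matrix)[const], 5),
                          collapse = ", ")))
    matrix <- omics_matrix(unclass(matrix)[!const, , drop = FALSE],
                           feature_ids = rownames(matrix)[!const],
                           sample_ids = colnames(matrix))
  }
  matrix
}

#' Zero-mean, unit-variance normalization per feature
#'
#' Each feature row x is mapped to (x - mu) / sigma where mu and sigma are
#' the mean and standard deviation of that feature over all samples.  The
#' population convention (divisor n) is the default; the sample convention
#' (n - 1) is available via `population = FALSE`.  The operation is
#' idempotent under a fixed convention.
#'
#' @param matrix an [omics_matrix()]; every feature must have non-zero
#'   standard deviation (see [drop_constant_features()]).
#' @param population logical; divide by n (default) or n - 1.
#' @return The normalized [omics_matrix()].
#' @export
zscore_normalize <- function(matrix, population = TRUE) {
  x <- unclass(matrix)
  sds <- row_sd(x, population)
  if (any(sds == 0))
    stop("constant feature(s) cannot be normalized: ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  omics_matrix((x - rowMeans(x)) / sds)
}

#' Differential screen: per-feature one-way ANOVA across classes
#'
#' Computes for every feature the one-way ANOVA F statistic and p-value of
#' class-mean differences, and keeps features with p < `alpha`.  An optional
#' moderated variant stabilizes the per-feature within-class variances by
#' shrinking them toward their grand mean with prior weight `d0` (an
#' empirical-Bayes-style moderation; `d0 = 0` disables it and is the
#' default).  No multiple-testing correction is applied: the screen is a
#' pre-filter, not an inferential endpoint.
#'
#' @param matrix an [omics_matrix()] (normalized or raw; the F statistic is
#'   scale-invariant per feature).
#' @param labels [class_labels()] aligned with the matrix; each class needs
#'   at least 2 samples.
#' @param alpha significance threshold for keeping a feature (default 0.05).
#' @param d0 prior degrees of freedom for variance moderation; 0 = plain
#'   ANOVA.
#' @param s2_prior prior variance the moderation shrinks toward; default
#'   `NULL` uses the grand mean of the per-feature variances.
#' @return A `data.frame` of class `"differential_result"` with columns
#'   `feature_id`, `statistic`, `p_value`, `kept`.
#' @export
differential_filter <- function(matrix, labels, alpha = 0.05, d0 = 0,
                                s2_prior = NULL) {
  x <- unclass(matrix)
  if (!identical(colnames(x), names(labels)))
    stop("matrix samples and labels are not aligned; call align_samples()")
  f <- as_factor(labels)
  cls_n <- table(f)
  if (any(cls_n < 2))
    stop("each class needs >= 2 samples; offending class(es): ",
         paste(names(cls_n)[cls_n < 2], collapse = ", "))
  k <- nlevels(f)
  n <- ncol(x)
  df1 <- k - 1L
  df2 <- n - k
  grand <- rowMeans(x)
  # between- and within-class sums of squares, vectorized over features
  ssb <- numeric(nrow(x))
  ssw <- numeric(nrow(x))
  for (lv in levels(f)) {
    idx <- which(f == lv)
    mu_c <- rowMeans(x[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (mu_c - grand)^2
    ssw <- ssw + rowSums((x[, idx, drop = FALSE] - mu_c)^2)
  }
  msb <- ssb / df1
  s2 <- ssw / df2
  if (d0 > 0) {
    s2_bar <- if (is.null(s2_prior)) mean(s2) else s2_prior
    # d0 = Inf: full shrinkage to the prior variance
    s2_mod <- if (is.infinite(d0)) rep(s2_bar, length(s2)) else
      (d0 * s2_bar + df2 * s2) / (d0 + df2)
    stat <- msb / s2_mod
    p <- stats::pf(stat, df1, df2 + d0, lower.tail = FALSE)
  } else {
    stat <- msb / s2
    # zero within-class variance with non-zero between: infinite F, p = 0
    stat[ssw == 0 & ssb > 0] <- Inf
    stat[ssw == 0 & ssb == 0] <- NaN
    p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
    p[is.nan(stat)] <- 1
  }
  res <- data.frame(feature_id = rownames(x), statistic = stat,
                    p_value = p, kept = p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "alpha") <- alpha
  attr(res, "d0") <- d0
  class(res) <- c("differential_result", "data.frame")
  res
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("differential_result: %d features, %d kept at alpha = %g\n",
              nrow(x), sum(x$kept), attr(x, "alpha")))
  NextMethod()
}

#' Write a differential screen result as TSV
#' @param x a `differential_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Discretize features into three states
#'
#' Per feature, values below mean - sigma map to -1, values above
#' mean + sigma map to +1, and everything else (boundaries included) maps
#' to 0.  On z-normalized input this is the symmetric rule with cut points
#' at -1 and +1.  sigma uses the same population/sample convention as
#' [zscore_normalize()].
#'
#' @param matrix an [omics_matrix()], normally the z-scored matrix.
#' @param population logical; convention for sigma (default population).
#' @return An integer matrix of class `"disc_matrix"` with entries in
#'   \{-1, 0, 1\} and the same dimnames.
#' @export
discretize <- function(matrix, population = TRUE) {
  x <- unclass(matrix)
  mu <- rowMeans(x)
  sds <- row_sd(x, population)
  lo <- mu - sds
  hi <- mu + sds
  states <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  states[x < lo] <- -1L
  states[x > hi] <- 1L
  structure(states, class = c("disc_matrix", "matrix", "array"))
}

#' @export
print.disc_matrix <- function(x, ...) {
  cat(sprintf("disc_matrix: %d features x %d samples, states {-1, 0, 1}\n",
              nrow(x), ncol(x)))
  print(table(factor(unclass(x), levels = c(-1L, 0L, 1L))))
  invisible(x)
}
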