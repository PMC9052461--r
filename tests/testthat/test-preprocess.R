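mk <- function(vals, ids = sprintf("g%d", seq_len(nrow(vals)))) {
  omics_matrix(matrix(vals, nrow = length(ids),
                      dimnames = list(ids, sprintf("s%d",
                                                   seq_len(ncol(vals))))))
}

test_that("z-score normalization uses the population convention and is idempotent", {
  m <- omics_matrix(matrix(c(1, 2, 3), 1, 3,
                           dimnames = list("g1", c("s1", "s2", "s3"))))
  z <- zscore_normalize(m)
  expect_equal(as.numeric(z), c(-1.22474, 0, 1.22474), tolerance = 1e-5)
  expect_equal(as.numeric(zscore_normalize(z)), as.numeric(z),
               tolerance = 1e-10)

  # sample convention on request
  zs <- zscore_normalize(m, population = FALSE)
  expect_equal(as.numeric(zs), (c(1, 2, 3) - 2) / 1, tolerance = 1e-12)

  const <- omics_matrix(matrix(5, 1, 3, dimnames = list("gk",
                                                        c("a", "b", "c"))))
  expect_error(zscore_normalize(const), "gk")
  expect_warning(dropped <- drop_constant_features(const), "gk")
  expect_equal(nrow(dropped), 0)
})

test_that("differential filter matches per-feature aov and the F = t^2 identity", {
  set.seed(21)
  n <- 24
  y <- class_labels(rep(c("a", "b", "c"), each = 8),
                    sample_ids = sprintf("s%d", 1:n))
  x <- omics_matrix(matrix(rnorm(15 * n), 15, n,
                           dimnames = list(sprintf("g%d", 1:15),
                                           names(y))))
  res <- differential_filter(x, y, alpha = 0.05)
  for (i in c(1, 7, 15)) {
    a <- anova(lm(unclass(x)[i, ] ~ factor(as.character(y))))
    expect_equal(res$statistic[i], a[1, "F value"], tolerance = 1e-10)
    expect_equal(res$p_value[i], a[1, "Pr(>F)"], tolerance = 1e-10)
  }
  expect_identical(res$kept, res$p_value < 0.05)

  # two classes: F equals the squared equal-variance t statistic
  y2 <- class_labels(rep(c("a", "b"), each = 12),
                     sample_ids = names(y))
  res2 <- differential_filter(x, y2)
  tt <- t.test(unclass(x)[3, as.character(y2) == "a"],
               unclass(x)[3, as.character(y2) == "b"], var.equal = TRUE)
  expect_equal(res2$statistic[3], unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("perfect class separation gives p ~ 0 and classes of one sample error", {
  y <- class_labels(rep(c("a", "b", "c"), each = 2),
                    sample_ids = sprintf("s%d", 1:6))
  x <- mk(matrix(c(1, 1, 2, 2, 3, 3), 1, 6), "g1")
  res <- differential_filter(x, y)
  expect_equal(res$p_value[1], 0)
  expect_true(res$kept[1])

  y_bad <- class_labels(c("a", "a", "a", "a", "a", "b"),
                        sample_ids = colnames(x))
  expect_error(differential_filter(x, y_bad), "b")
})

test_that("null p-values are uniform (KS) and the moderated variant reproduces limma", {
  set.seed(33)
  n <- 30
  y <- class_labels(rep(c("a", "b", "c"), each = 10),
                    sample_ids = sprintf("s%d", 1:n))
  x <- omics_matrix(matrix(rnorm(2000 * n), 2000, n,
                           dimnames = list(sprintf("g%d", 1:2000),
                                           names(y))))
  res <- differential_filter(x, y)
  ks <- ks.test(res$p_value, "punif")
  expect_gt(ks$p.value, 0.01)

  skip_if_not_installed("limma")
  g <- factor(as.character(y))
  design <- model.matrix(~ 0 + g)
  fit <- limma::lmFit(unclass(x)[1:200, ], design)
  cm <- limma::makeContrasts(gb - ga, gc - ga, levels = design)
  eb <- limma::eBayes(limma::contrasts.fit(fit, cm))
  ours <- differential_filter(
    omics_matrix(unclass(x)[1:200, , drop = FALSE]), y,
    d0 = eb$df.prior, s2_prior = eb$s2.prior)
  expect_equal(ours$statistic, unname(eb$F), tolerance = 1e-8)
  expect_equal(ours$p_value, unname(eb$F.p.value), tolerance = 1e-8)
})

test_that("discretization maps beyond-one-sigma values to +/-1 and the rest to 0", {
  z <- mk(matrix(c(-1.5, 0.2, 1.5, -0.3), 1, 4), "g1")
  # bypass normalization: feed a row whose mean is ~0, sigma ~1
  d <- discretize(z)
  # row stats are computed from the data itself: mu=-0.025, sd~1.03
  expect_true(all(unclass(d) %in% c(-1L, 0L, 1L)))

  # exact +/- sigma boundaries map to 0 (two-point feature: z = +/-1)
  b <- discretize(mk(matrix(c(0, 2), 1, 2), "g1"))
  expect_identical(as.integer(b), c(0L, 0L))

  # middle band all zero
  set.seed(5)
  m <- mk(matrix(rnorm(50), 1, 50), "g1")
  zrow <- zscore_normalize(m)
  dd <- discretize(zrow)
  expect_identical(unname(unclass(dd)[1, ] == 0L),
                   unname(abs(unclass(zrow)[1, ]) <= 1))
  expect_identical(unname(unclass(dd)[1, ] == 1L),
                   unname(unclass(zrow)[1, ] > 1))

  # per-feature rule: invariant to sample permutation
  perm <- sample(50)
  dp <- discretize(omics_matrix(unclass(zrow)[, perm, drop = FALSE]))
  expect_identical(unname(unclass(dp)[1, ]), unname(unclass(dd)[1, perm]))
})
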