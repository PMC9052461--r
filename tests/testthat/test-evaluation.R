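test_that("separable classes give near-perfect accuracy for every classifier", {
  d <- separable_data(n_per_class = 15, seed = 2)
  pp <- preprocess_for_tests(d)
  for (cl in c("C45", "NaiveBayes", "KNN", "AdaBoost")) {
    est <- cv_accuracy(pp$x, pp$labels, classifier = cl, folds = 5,
                       repeats = 2, seed = 9)
    expect_gte(est$mean_pct, 95)
  }
})

test_that("cross-validation is seed-deterministic, bit for bit", {
  d <- separable_data(n_per_class = 12, effect = 0.8, seed = 4)
  pp <- preprocess_for_tests(d)
  a <- cv_accuracy(pp$x, pp$labels, classifier = "KNN", folds = 5,
                   repeats = 3, seed = 123)
  b <- cv_accuracy(pp$x, pp$labels, classifier = "KNN", folds = 5,
                   repeats = 3, seed = 123)
  expect_identical(a$fold_accuracies, b$fold_accuracies)
  expect_identical(a$mean_pct, b$mean_pct)
  c <- cv_accuracy(pp$x, pp$labels, classifier = "KNN", folds = 5,
                   repeats = 3, seed = 124)
  expect_false(identical(a$fold_accuracies, c$fold_accuracies))
})

test_that("stratified folds preserve class proportions within one sample", {
  f <- factor(rep(c("a", "b", "c"), times = c(31, 96, 34)))
  set.seed(1)
  fold_of <- omicfs:::stratified_folds(f, 10)
  for (lv in levels(f)) {
    per_fold <- table(factor(fold_of[f == lv], levels = 1:10))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("tuning reports the best grid value's score", {
  d <- separable_data(n_per_class = 12, seed = 6)
  pp <- preprocess_for_tests(d)
  fixed <- vapply(c(1, 5), function(k)
    cv_accuracy(pp$x, pp$labels, classifier = "KNN", folds = 5, repeats = 1,
                seed = 3, tuning = k)$mean_pct, numeric(1))
  tuned <- cv_accuracy(pp$x, pp$labels, classifier = "KNN", folds = 5,
                       repeats = 1, seed = 3, tuning = c(1, 5))
  expect_equal(tuned$mean_pct, max(fixed))
  expect_true(tuned$tuned_parameter %in% c(1, 5))
})

test_that("redundancy rate hits its closed forms", {
  set.seed(31)
  v <- rnorm(40)
  dup <- matrix(rep(v, 4), 4, byrow = TRUE,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:40)))
  expect_equal(redundancy_rate(dup, "pearson"), 1.0, tolerance = 1e-12)
  dd <- discretize(omics_matrix(dup))
  expect_equal(redundancy_rate(dd, "nmi"), 1.0, tolerance = 1e-12)

  # d = 2: RR equals the single pairwise similarity
  two <- rbind(f1 = rnorm(40), f2 = rnorm(40))
  colnames(two) <- paste0("s", 1:40)
  expect_equal(redundancy_rate(two, "pearson"),
               abs(cor(two[1, ], two[2, ])), tolerance = 1e-12)

  # anticorrelated pair counts as fully redundant (|r|)
  anti <- rbind(f1 = v, f2 = -v)
  colnames(anti) <- paste0("s", 1:40)
  expect_equal(redundancy_rate(anti, "pearson"), 1.0, tolerance = 1e-12)

  # symmetric in feature order
  set.seed(8)
  m <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:30)))
  expect_equal(redundancy_rate(m, "pearson"),
               redundancy_rate(m[5:1, ], "pearson"), tolerance = 1e-12)
  expect_error(redundancy_rate(m[1, , drop = FALSE], "pearson"), ">= 2")
})

test_that("representation entropy hits its closed forms and bounds", {
  # rank-1 subset: all information in one direction -> RE = 0
  v <- rnorm(30)
  rank1 <- rbind(f1 = v, f2 = 2 * v, f3 = -0.5 * v)
  colnames(rank1) <- paste0("s", 1:30)
  expect_equal(representation_entropy(rank1)$entropy_bits, 0,
               tolerance = 1e-9)

  # exactly equal eigenvalues -> RE = log2 d (orthonormal zero-mean rows)
  n <- 9
  H <- contr.helmert(n)                       # n x (n-1), zero-sum columns
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")   # orthonormal
  eq <- t(H)
  dimnames(eq) <- list(paste0("f", 1:(n - 1)), paste0("s", 1:n))
  se <- representation_entropy(eq)
  expect_equal(se$entropy_bits, log2(n - 1), tolerance = 1e-12)
  expect_equal(sum(se$normalized), 1, tolerance = 1e-9)

  # eigenvalues {3, 1}: RE = -(0.75 log2 0.75 + 0.25 log2 0.25)
  two <- rbind(f1 = sqrt(3) * t(H)[1, ], f2 = t(H)[2, ])
  dimnames(two) <- list(c("f1", "f2"), paste0("s", 1:n))
  re <- representation_entropy(two)
  expect_equal(sort(re$eigenvalues / re$eigenvalues[2]), c(1, 3),
               tolerance = 1e-9)
  expect_equal(re$entropy_bits,
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_equal(re$entropy_bits, 0.81128, tolerance = 1e-5)

  # invariant to feature order; bounded by log2 d
  set.seed(12)
  m <- matrix(rnorm(6 * 25), 6, 25,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:25)))
  expect_equal(representation_entropy(m)$entropy_bits,
               representation_entropy(m[6:1, ])$entropy_bits,
               tolerance = 1e-9)
  expect_lte(representation_entropy(m)$entropy_bits, log2(6))

  # correlation mode is scale-invariant, covariance mode is not
  scaled <- m * c(1, 10, 100, 1, 1, 1)
  expect_equal(representation_entropy(scaled, "correlation")$entropy_bits,
               representation_entropy(m, "correlation")$entropy_bits,
               tolerance = 1e-9)
})

test_that("evaluate_selection bundles all three criteria coherently", {
  d <- separable_data(n_per_class = 12, seed = 10)
  pp <- preprocess_for_tests(d)
  ev <- evaluate_selection(pp$x, pp$disc, pp$labels,
                           features = rownames(pp$x)[1:5],
                           classifiers = c("KNN", "NaiveBayes"),
                           folds = 5, repeats = 1, seed = 2)
  expect_named(ev$accuracy, c("KNN", "NaiveBayes"))
  expect_true(ev$rr_nmi >= 0 && ev$rr_nmi <= 1)
  expect_true(ev$rr_pearson >= 0 && ev$rr_pearson <= 1)
  expect_true(ev$re >= 0 && ev$re <= log2(5))
})
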