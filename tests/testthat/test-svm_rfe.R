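# independent textbook SVM-RFE (step 1, no CBR) used as a regression oracle
plain_rfe_oracle <- function(x, labels, cost = 1) {
  f <- factor(as.character(labels))
  surv <- rownames(x)
  elim <- character(0)
  score_of <- function(feats) {
    xs <- t(scale(t(unclass(x)[feats, , drop = FALSE])))
    xs[is.na(xs)] <- 0
    sc <- numeric(length(feats))
    lv <- if (nlevels(f) == 2) levels(f)[1] else levels(f)
    for (cl in lv) {
      y <- factor(ifelse(f == cl, "pos", "rest"), c("pos", "rest"))
      fit <- e1071::svm(t(xs), y, kernel = "linear", cost = cost,
                        scale = FALSE)
      w <- drop(crossprod(fit$coefs, fit$SV))
      sc <- sc + w^2
    }
    names(sc) <- feats
    sc
  }
  while (length(surv) > 1) {
    sc <- score_of(surv)
    worst <- surv[order(sc, match(surv, rownames(x)))][1]
    elim <- c(worst, elim)
    surv <- setdiff(surv, worst)
  }
  c(surv, elim)
}

test_that("with cbr_tau = 1 and step 1 the ranking equals textbook SVM-RFE", {
  inst <- rand_cont_instance(d = 6, n_per_class = 12, seed = 40, effect = 2)
  x <- zscore_normalize(inst$matrix)
  res <- svm_rfe_cbr_rank(x, inst$labels,
                          criterion_params(k = 1, cbr_tau = 1, rfe_step = 1))
  expect_identical(res$ranking, plain_rfe_oracle(x, inst$labels))
})

test_that("pure-noise features are eliminated before informative ones", {
  set.seed(50)
  n <- 60
  y <- rep(c("a", "b"), each = 30)
  x <- rbind(inf1 = c(rnorm(30, -2), rnorm(30, 2)),
             inf2 = c(rnorm(30, 2), rnorm(30, -2)),
             noise = rnorm(n))
  colnames(x) <- sprintf("s%02d", 1:n)
  labels <- class_labels(y, sample_ids = colnames(x))
  xm <- zscore_normalize(omics_matrix(x))
  res <- svm_rfe_cbr_rank(xm, labels, criterion_params(k = 2, rfe_step = 1))
  expect_identical(res$elimination[[1]]$eliminated, "noise")
  expect_setequal(res$selected, c("inf1", "inf2"))
})

test_that("CBR defers correlated informative copies so both outrank noise", {
  # an exact duplicate pair shares its SVM weight, making each copy look
  # individually weak; the CBR rule must protect the unmarked twin's partner
  set.seed(2)
  n <- 60
  y <- rep(c("a", "b"), each = 30)
  base <- c(rnorm(30, -1), rnorm(30, 1))
  x <- rbind(dupA = base, dupB = base,       # r = 1
             mid = c(rnorm(30, -1.2), rnorm(30, 1.2)),
             weak1 = c(rnorm(30, -0.5), rnorm(30, 0.5)),
             weak2 = c(rnorm(30, -0.5), rnorm(30, 0.5)),
             n1 = rnorm(n), n2 = rnorm(n))
  colnames(x) <- sprintf("s%02d", 1:n)
  labels <- class_labels(y, sample_ids = colnames(x))
  xm <- zscore_normalize(omics_matrix(x))
  res <- svm_rfe_cbr_rank(xm, labels,
                          criterion_params(k = 2, cbr_tau = 0.9,
                                           rfe_step = 2))
  rank_of <- match(c("dupA", "dupB"), res$ranking)
  noise_rank <- match(c("n1", "n2"), res$ranking)
  expect_true(all(rank_of < min(noise_rank)))
  # deferral fired at least once
  deferred <- unlist(lapply(res$elimination, `[[`, "deferred"))
  expect_true(length(deferred) > 0)
})

test_that("the elimination trace partitions the feature set", {
  inst <- rand_cont_instance(d = 10, n_per_class = 10, seed = 70,
                             effect = 1)
  x <- zscore_normalize(inst$matrix)
  res <- svm_rfe_cbr_rank(x, inst$labels, criterion_params(k = 3))
  elim_sets <- lapply(res$elimination, `[[`, "eliminated")
  all_elim <- unlist(elim_sets)
  expect_false(anyDuplicated(all_elim) > 0)
  expect_setequal(c(all_elim, res$selected), rownames(x))
  expect_identical(length(res$ranking), nrow(x))
  # rank = survivors first, then reverse elimination order
  expect_identical(res$ranking[seq_len(3)], res$selected)
  expect_identical(res$ranking[length(res$ranking)], elim_sets[[1]][1])
})

test_that("ranking is deterministic and invariant to sample permutation", {
  inst <- rand_cont_instance(d = 8, n_per_class = 12, seed = 80, effect = 2)
  x <- zscore_normalize(inst$matrix)
  p <- criterion_params(k = 3, rfe_step = 2)
  r1 <- svm_rfe_cbr_rank(x, inst$labels, p)
  r2 <- svm_rfe_cbr_rank(x, inst$labels, p)
  expect_identical(r1$ranking, r2$ranking)

  set.seed(3)
  perm <- sample(ncol(x))
  xp <- omics_matrix(unclass(x)[, perm])
  lp <- class_labels(as.character(inst$labels)[perm],
                     sample_ids = colnames(xp))
  r3 <- svm_rfe_cbr_rank(xp, lp, p)
  expect_setequal(r3$selected, r1$selected)
})
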