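test_that("with an empty selected set every criterion is its relevance term", {
  inst <- rand_instance(d = 6, n = 40, seed = 7)
  cls <- as.integer(factor(as.character(inst$labels)))
  for (m in c("MIFS", "MIFS_U", "mRMR", "NMIFS", "INMIFS", "VWMRmR")) {
    sc <- score_candidate(m, "f03", character(0), inst$disc, inst$labels)
    expected <- if (m %in% c("INMIFS", "VWMRmR"))
      normalized_mi(inst$disc["f03", ], cls) else
      mutual_information(inst$disc["f03", ], cls)
    expect_equal(sc, expected, info = m)
  }
})

test_that("MIFS with beta = 0 ignores the selected set entirely", {
  inst <- rand_instance(d = 6, n = 40, seed = 8)
  p0 <- criterion_params(beta = 0)
  cls <- as.integer(factor(as.character(inst$labels)))
  sc <- score_candidate("MIFS", "f05", c("f01", "f02"), inst$disc,
                        inst$labels, p0)
  expect_equal(sc, mutual_information(inst$disc["f05", ], cls))
})

test_that("mRMR candidate score matches the brute-force criterion on a toy instance", {
  inst <- rand_instance(d = 4, n = 20, n_classes = 2, seed = 9)
  cls <- as.integer(factor(as.character(inst$labels)))
  p <- criterion_params()
  for (cand in 3:4) {
    sc <- score_candidate("mRMR", cand, 1:2, inst$disc, inst$labels, p)
    expect_equal(sc, oracle_score("mRMR", cand, 1:2, inst$disc, cls, p),
                 tolerance = 1e-12)
  }
})

test_that("greedy selection equals exhaustive per-step argmax for all six criteria", {
  methods <- c("MIFS", "MIFS_U", "mRMR", "NMIFS", "INMIFS", "VWMRmR")
  for (trial in 1:30) {
    inst <- rand_instance(d = sample(4:10, 1), n = sample(20:40, 1),
                          seed = 500 + trial)
    k <- sample(2:min(6, nrow(inst$disc)), 1)
    p <- criterion_params(k = k)
    for (m in methods) {
      got <- greedy_select(m, inst$disc, inst$labels, p)
      expect_identical(got$selected,
                       oracle_greedy(m, inst$disc, inst$cls, p),
                       info = sprintf("%s trial %d", m, trial))
      expect_equal(nrow(got$trace), k)
      expect_false(anyDuplicated(got$selected) > 0)
    }
  }
})

test_that("k = 1 picks the single most relevant feature", {
  inst <- rand_instance(d = 8, n = 30, seed = 77)
  cls <- as.integer(factor(as.character(inst$labels)))
  rel <- vapply(seq_len(8), function(i)
    mutual_information(inst$disc[i, ], cls), numeric(1))
  got <- greedy_select("mRMR", inst$disc, inst$labels, criterion_params(k = 1))
  expect_identical(got$selected, rownames(inst$disc)[which.max(rel)])
})

test_that("VWMRmR with w = 0 reduces to INMIFS", {
  for (trial in 1:20) {
    inst <- rand_instance(d = 8, n = 30, seed = 900 + trial)
    p <- criterion_params(w = 0, k = 5)
    expect_identical(greedy_select("VWMRmR", inst$disc, inst$labels, p)$selected,
                     greedy_select("INMIFS", inst$disc, inst$labels, p)$selected)
  }
})

test_that("an exact duplicate of a selected feature loses to an informative non-duplicate", {
  set.seed(42)
  n <- 60
  cls_chr <- rep(c("a", "b", "c"), each = 20)
  c_num <- match(cls_chr, c("a", "b", "c")) - 2L   # -1, 0, 1
  corrupt <- function(v, rate) {
    flip <- runif(n) < rate
    v[flip] <- sample(c(-1L, 0L, 1L), sum(flip), replace = TRUE)
    v
  }
  f1 <- corrupt(c_num, 0.2)
  f3 <- corrupt(c_num, 0.2)     # informative, conditionally independent of f1
  disc <- structure(rbind(f1 = f1, f2 = f1, f3 = f3),
                    class = c("disc_matrix", "matrix", "array"))
  colnames(disc) <- sprintf("s%02d", 1:n)
  labels <- class_labels(cls_chr, sample_ids = colnames(disc))
  for (m in c("mRMR", "NMIFS", "INMIFS", "VWMRmR")) {
    got <- greedy_select(m, disc, labels, criterion_params(k = 2))
    expect_identical(got$selected, c("f1", "f3"), info = m)
  }
})

test_that("selection is invariant to sample permutation and follows feature permutation", {
  inst <- rand_instance(d = 8, n = 40, seed = 1234)
  p <- criterion_params(k = 4)
  base <- greedy_select("VWMRmR", inst$disc, inst$labels, p)

  set.seed(5)
  perm <- sample(ncol(inst$disc))
  disc_p <- structure(unclass(inst$disc)[, perm],
                      class = c("disc_matrix", "matrix", "array"))
  lab_p <- class_labels(as.character(inst$labels)[perm],
                        sample_ids = colnames(disc_p))
  expect_identical(greedy_select("VWMRmR", disc_p, lab_p, p)$selected,
                   base$selected)

  fperm <- sample(nrow(inst$disc))
  disc_f <- structure(unclass(inst$disc)[fperm, ],
                      class = c("disc_matrix", "matrix", "array"))
  got_f <- greedy_select("VWMRmR", disc_f, inst$labels, p)
  expect_setequal(got_f$selected, base$selected)
})

test_that("cached pairwise values match direct recomputation", {
  inst <- rand_instance(d = 6, n = 30, seed = 55)
  p <- criterion_params(k = 4)
  got <- greedy_select("mRMR", inst$disc, inst$labels, p)
  # redundancy column of the trace must equal the oracle's redundancy term
  cls <- inst$cls
  sel_idx <- match(got$selected, rownames(inst$disc))
  for (step in 2:4) {
    v <- vapply(sel_idx[seq_len(step - 1)], function(s)
      oracle_mi(inst$disc[s, ], inst$disc[sel_idx[step], ]), numeric(1))
    expect_equal(got$trace$redundancy[step], mean(pmax(v, 0)),
                 tolerance = 1e-12)
  }
})
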