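# Independent brute-force oracles and fixture builders.  The oracles
# enumerate contingency tables directly and never share code with the
# package's estimators.

# entropy from an explicit frequency table
oracle_entropy <- function(x) {
  tab <- table(x)
  p <- as.numeric(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# mutual information as sum over joint cells of p log2(p / (px py))
oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  s <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) s <- s + pij * log2(pij / (px[i] * py[j]))
    }
  unname(s)
}

oracle_nmi <- function(x, y) {
  m <- min(oracle_entropy(x), oracle_entropy(y))
  if (m == 0) return(0)
  oracle_mi(x, y) / m
}

# criterion value computed from scratch with the oracle estimators
oracle_score <- function(method, ci, sel, disc, cls, params) {
  rel_fun <- if (method %in% c("INMIFS", "VWMRmR")) oracle_nmi else oracle_mi
  red_fun <- if (method %in% c("NMIFS", "INMIFS", "VWMRmR")) oracle_nmi else
    oracle_mi
  rel <- rel_fun(disc[ci, ], cls)
  if (length(sel) == 0) return(rel)
  v <- vapply(sel, function(s) red_fun(disc[s, ], disc[ci, ]), numeric(1))
  red <- switch(method,
    MIFS = params$beta * sum(v),
    MIFS_U = {
      h <- vapply(sel, function(s) oracle_entropy(disc[s, ]), numeric(1))
      r <- vapply(sel, function(s) oracle_mi(disc[s, ], cls), numeric(1))
      ok <- h > 0
      params$beta * sum((r[ok] / h[ok]) * v[ok])
    },
    mRMR = mean(v),
    NMIFS = mean(v),
    INMIFS = mean(v),
    VWMRmR = (1 + params$w * length(sel) / params$k) * mean(v))
  rel - red
}

# exhaustive per-step argmax forward selection using only oracle scores
oracle_greedy <- function(method, disc, cls, params) {
  d <- nrow(disc)
  k <- min(params$k, d)
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(d), sel)
    sc <- vapply(cand, function(ci)
      oracle_score(method, ci, sel, disc, cls, params), numeric(1))
    sel <- c(sel, cand[which(sc >= max(sc) - 1e-9)[1]])
  }
  rownames(disc)[sel]
}

# random discretized instance with labels
rand_instance <- function(d, n, n_classes = 3, seed = 1) {
  set.seed(seed)
  vals <- matrix(sample(c(-1L, 0L, 1L), d * n, replace = TRUE), d, n,
                 dimnames = list(sprintf("f%02d", seq_len(d)),
                                 sprintf("s%02d", seq_len(n))))
  cls <- sample(seq_len(n_classes), n, replace = TRUE)
  # guarantee every class occurs
  cls[seq_len(n_classes)] <- seq_len(n_classes)
  labels <- class_labels(paste0("c", cls), sample_ids = colnames(vals))
  list(disc = structure(vals, class = c("disc_matrix", "matrix", "array")),
       labels = labels, cls = as.integer(factor(cls)))
}

# small continuous instance for DFS / SVM-RFE tests
rand_cont_instance <- function(d, n_per_class, n_classes = 3, seed = 1,
                               effect = 0) {
  set.seed(seed)
  n <- n_per_class * n_classes
  y <- rep(paste0("c", seq_len(n_classes)), each = n_per_class)
  x <- matrix(rnorm(d * n), d, n,
              dimnames = list(sprintf("f%02d", seq_len(d)),
                              sprintf("s%03d", seq_len(n))))
  if (effect > 0) {
    shifts <- seq(-1, 1, length.out = n_classes) * effect
    x[1, ] <- x[1, ] + shifts[match(y, unique(y))]
  }
  list(matrix = omics_matrix(x),
       labels = class_labels(y, sample_ids = colnames(x)))
}

# well-separated 3-class dataset for classifier sanity checks
separable_data <- function(n_per_class = 20, d_inf = 5, d_noise = 5,
                           effect = 5, seed = 1) {
  sp <- synthetic_spec(class_sizes = rep(n_per_class, 3),
                       n_informative = d_inf, n_redundant = 0,
                       n_noise = d_noise, effect_size = effect, seed = seed)
  generate_synthetic(sp)
}

# z-scored + discretized view of a generated dataset
preprocess_for_tests <- function(data) {
  x <- zscore_normalize(drop_constant_features(data$matrix))
  list(x = x, disc = discretize(x), labels = data$labels)
}
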