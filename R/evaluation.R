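# ---------------------------------------------------------------------------
# Evaluation criteria for a selected feature subset:
#   1. supervised: repeated stratified k-fold CV accuracy under four
#      classifiers (entropy-split decision tree, Gaussian naive Bayes,
#      KNN, AdaBoost on stumps);
#   2. unsupervised: redundancy rate (mean pairwise similarity, NMI or
#      |Pearson r|) and representation entropy (Shannon entropy of the
#      normalized covariance eigenspectrum).
# Accuracy rewards class information; the other two penalize subsets that
# concentrate their information in few, mutually similar features.
# ---------------------------------------------------------------------------

CLASSIFIERS <- c("C45", "NaiveBayes", "KNN", "AdaBoost")

# evaluate `code` under a temporary RNG state, restoring the caller's
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

# per-class round-robin fold assignment: every fold holds each class's
# count to within one sample
stratified_folds <- function(f, folds) {
  assign <- integer(length(f))
  for (lv in levels(f)) {
    idx <- which(f == lv)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# --- classifiers ------------------------------------------------------------

samme_fit <- function(X, y, rounds = 50L) {
  n <- nrow(X)
  K <- nlevels(y)
  df <- data.frame(X, check.names = TRUE)
  w <- rep(1 / n, n)
  models <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., data = cbind(df, y = y), weights = w,
                        method = "class", control = ctrl)
    pred <- stats::predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 1e-12) {               # perfect stump: it decides alone
      models[[length(models) + 1]] <- fit
      alphas <- c(alphas, 20)
      break
    }
    if (err >= 1 - 1 / K) break       # no better than chance: stop boosting
    a <- log((1 - err) / err) + log(K - 1)
    models[[length(models) + 1]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(a * miss)
    w <- w / sum(w)
  }
  if (length(models) == 0) {          # degenerate: fall back to one stump
    models <- list(rpart::rpart(y ~ ., data = cbind(df, y = y),
                                method = "class", control = ctrl))
    alphas <- 1
  }
  list(models = models, alphas = alphas, levels = levels(y))
}

samme_predict <- function(fit, X) {
  df <- data.frame(X, check.names = TRUE)
  votes <- matrix(0, nrow(df), length(fit$levels))
  for (m in seq_along(fit$models)) {
    pred <- stats::predict(fit$models[[m]], df, type = "class")
    votes <- votes + fit$alphas[m] *
      outer(as.character(pred), fit$levels, "==")
  }
  factor(fit$levels[max.col(votes, ties.method = "first")],
         levels = fit$levels)
}

# train on (Xtr, ytr), predict Xte; `par` is the classifier's tunable
train_predict <- function(classifier, Xtr, ytr, Xte, par = NULL,
                          adaboost_rounds = 50L) {
  switch(classifier,
    KNN = {
      k <- if (is.null(par)) round(sqrt(nrow(Xtr))) else par
      class::knn(Xtr, Xte, ytr, k = max(1L, as.integer(k)))
    },
    NaiveBayes = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      stats::predict(fit, Xte)
    },
    C45 = {
      cp <- if (is.null(par)) 0.01 else par
      dtr <- data.frame(Xtr, check.names = TRUE)
      dte <- data.frame(Xte, check.names = TRUE)
      names(dte) <- names(dtr)
      fit <- rpart::rpart(y ~ ., data = cbind(dtr, y = ytr),
                          method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(cp = cp, xval = 0))
      stats::predict(fit, dte, type = "class")
    },
    AdaBoost = {
      rounds <- if (is.null(par)) adaboost_rounds else as.integer(par)
      fit <- samme_fit(Xtr, ytr, rounds)
      samme_predict(fit, Xte)
    },
    stop("unknown classifier: ", classifier))
}

# default tuning grids (the tree grid is a pruning-strength grid)
default_grid <- function(classifier) {
  switch(classifier,
         KNN = 1:15,
         C45 = seq(0.05, 0.5, by = 0.05),
         NULL)
}

cv_once <- function(X, f, classifier, folds, repeats, seed, par,
                    adaboost_rounds) {
  accs <- numeric(0)
  for (r in seq_len(repeats)) {
    set.seed(seed + 7919L * r)
    fold_of <- stratified_folds(f, folds)
    for (fd in seq_len(folds)) {
      te <- which(fold_of == fd)
      tr <- which(fold_of != fd)
      set.seed(seed + 7919L * r + fd)   # e.g. KNN tie-breaking
      pred <- train_predict(classifier, X[tr, , drop = FALSE], f[tr],
                            X[te, , drop = FALSE], par, adaboost_rounds)
      accs <- c(accs, 100 * mean(as.character(pred) == as.character(f[te])))
    }
  }
  accs
}

#' Repeated stratified cross-validation accuracy
#'
#' Accuracy (fraction of correct multiclass predictions, in percent) under
#' stratified k-fold CV repeated `repeats` times; the mean and standard
#' deviation are taken over all repeats x folds fold-level accuracies.
#' Fully deterministic given `seed`.  The KNN neighbor count defaults to
#' the rounded square root of the training-set size.  When a tuning grid
#' is supplied, the whole CV is run per grid value and the best mean is
#' reported (with the winning value).
#'
#' @param data an [omics_matrix()] (z-scored continuous values).
#' @param labels aligned [class_labels()]; each class needs >= `folds`
#'   samples.
#' @param features character vector of feature ids to use (non-empty).
#' @param classifier one of `"C45"`, `"NaiveBayes"`, `"KNN"`, `"AdaBoost"`.
#' @param folds,repeats CV geometry (default 10 x 10).
#' @param seed integer seed controlling fold assignment and any classifier
#'   randomness.
#' @param tuning `NULL` (fixed default parameter), `TRUE` (the classifier's
#'   default grid: K = 1..15 for KNN, pruning 0.05..0.5 for the tree), or a
#'   numeric vector of grid values.
#' @param adaboost_rounds boosting rounds for AdaBoost stumps (default 50).
#' @return An object of class `"accuracy_estimate"`: classifier, `mean_pct`,
#'   `std_pct`, folds, repeats, seed, tuned parameter (if any) and the raw
#'   fold accuracies.
#' @export
cv_accuracy <- function(data, labels, features = rownames(data),
                        classifier = CLASSIFIERS,
                        folds = 10L, repeats = 10L, seed = 1L,
                        tuning = NULL, adaboost_rounds = 50L) {
  classifier <- match.arg(classifier)
  if (length(features) == 0) stop("empty feature subset")
  missing_f <- setdiff(features, rownames(data))
  if (length(missing_f))
    stop("features absent from data: ", paste(missing_f, collapse = ", "))
  f <- as_factor(labels)
  if (any(table(f) < folds))
    stop("each class needs >= ", folds, " samples for ", folds, "-fold CV")
  X <- t(unclass(data)[features, , drop = FALSE])
  grid <- if (isTRUE(tuning)) default_grid(classifier) else
    if (is.numeric(tuning)) tuning else NULL
  res <- with_seed(seed, {
    if (is.null(grid)) {
      list(accs = cv_once(X, f, classifier, folds, repeats, seed, NULL,
                          adaboost_rounds), par = NULL)
    } else {
      best <- NULL
      for (g in grid) {
        a <- cv_once(X, f, classifier, folds, repeats, seed, g,
                     adaboost_rounds)
        if (is.null(best) || mean(a) > best$mean) {
          best <- list(accs = a, par = g, mean = mean(a))
        }
      }
      best[c("accs", "par")]
    }
  })
  structure(list(classifier = classifier,
                 mean_pct = mean(res$accs),
                 std_pct = stats::sd(res$accs),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), tuned_parameter = res$par,
                 fold_accuracies = res$accs),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("%s: %.2f%% (sd %.2f) over %dx%d-fold CV%s\n",
              x$classifier, x$mean_pct, x$std_pct, x$repeats, x$folds,
              if (!is.null(x$tuned_parameter))
                sprintf(", tuned parameter = %g", x$tuned_parameter) else ""))
  invisible(x)
}

# --- unsupervised criteria --------------------------------------------------

#' Redundancy rate of a feature subset
#'
#' Mean pairwise similarity over all feature pairs:
#' RR = 2 / (d (d - 1)) * sum_\{j > i\} Sim(f_i, f_j), in [0, 1]; lower
#' means less redundant.  `sim = "nmi"` expects discretized rows
#' ([discretize()]); `sim = "pearson"` uses |r| on continuous rows
#' (absolute value, so anticorrelated pairs count as redundant rather than
#' cancelling).
#'
#' @param data matrix with the selected features in rows (a `disc_matrix`
#'   for `"nmi"`, an [omics_matrix()] for `"pearson"`); at least 2 rows.
#' @param sim similarity measure.
#' @return The redundancy rate, a scalar in [0, 1].
#' @export
redundancy_rate <- function(data, sim = c("nmi", "pearson")) {
  sim <- match.arg(sim)
  x <- unclass(data)
  d <- nrow(x)
  if (d < 2) stop("redundancy rate needs >= 2 features")
  if (sim == "pearson") {
    cm <- abs(suppressWarnings(stats::cor(t(x))))
    cm[is.na(cm)] <- 0
    mean(cm[upper.tri(cm)])
  } else {
    tot <- 0
    for (i in seq_len(d - 1))
      for (j in (i + 1):d)
        tot <- tot + normalized_mi(x[i, ], x[j, ])
    2 * tot / (d * (d - 1))
  }
}

#' Representation entropy of a feature subset
#'
#' Shannon entropy (bits) of the normalized eigenvalues of the d x d
#' covariance matrix of the selected features.  Zero when all variance
#' lies along one direction (maximally redundant subset); log2 d when the
#' eigenvalues are all equal (information evenly spread).  Covariance mode
#' is scale-sensitive; `mode = "correlation"` makes the measure invariant
#' to per-feature scaling.
#'
#' @param data matrix with selected features in rows, >= 2 features and
#'   >= 2 samples.
#' @param mode `"covariance"` (default) or `"correlation"`.
#' @return An object of class `"spectrum_summary"`: `eigenvalues`,
#'   `normalized` (summing to 1) and `entropy_bits`.
#' @export
representation_entropy <- function(data, mode = c("covariance",
                                                  "correlation")) {
  mode <- match.arg(mode)
  x <- unclass(data)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 features and >= 2 samples")
  C <- if (mode == "covariance") stats::cov(t(x)) else {
    cc <- suppressWarnings(stats::cor(t(x)))
    if (anyNA(cc)) stop("constant feature: correlation undefined")
    cc
  }
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  if (tot <= 0) stop("all-zero covariance: representation entropy undefined")
  lt <- ev / tot
  nz <- lt > 0
  structure(list(eigenvalues = ev, normalized = lt,
                 entropy_bits = -sum(lt[nz] * log2(lt[nz])),
                 mode = mode),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("representation entropy: %.4f bits (d = %d, max %.4f, %s mode)\n",
              x$entropy_bits, length(x$eigenvalues),
              log2(length(x$eigenvalues)), x$mode))
  invisible(x)
}

# --- bundled evaluation -----------------------------------------------------

#' Evaluate a feature selection under all three criteria
#'
#' @param data_cont z-scored continuous [omics_matrix()] (used by the
#'   classifiers, RR-Pearson and RE).
#' @param data_disc matching `disc_matrix` (used by RR-NMI).
#' @param labels aligned [class_labels()].
#' @param features selected feature ids.
#' @param classifiers subset of C45, NaiveBayes, KNN, AdaBoost.
#' @param folds,repeats,seed,tuning,adaboost_rounds passed to
#'   [cv_accuracy()].
#' @return An object of class `"fs_evaluation"`: per-classifier
#'   `accuracy_estimate`s plus `rr_nmi`, `rr_pearson` and `re`.
#' @export
evaluate_selection <- function(data_cont, data_disc, labels, features,
                               classifiers = CLASSIFIERS,
                               folds = 10L, repeats = 10L, seed = 1L,
                               tuning = NULL, adaboost_rounds = 50L) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  acc <- lapply(classifiers, function(cl)
    cv_accuracy(data_cont, labels, features, cl, folds, repeats, seed,
                tuning, adaboost_rounds))
  names(acc) <- classifiers
  xd <- unclass(data_disc)[features, , drop = FALSE]
  xc <- unclass(data_cont)[features, , drop = FALSE]
  structure(list(accuracy = acc,
                 rr_nmi = redundancy_rate(xd, "nmi"),
                 rr_pearson = redundancy_rate(xc, "pearson"),
                 re = representation_entropy(xc)$entropy_bits,
                 features = features, folds = folds, repeats = repeats,
                 seed = seed),
            class = "fs_evaluation")
}

#' @export
print.fs_evaluation <- function(x, ...) {
  cat(sprintf("fs_evaluation of %d features:\n", length(x$features)))
  for (a in x$accuracy) print(a)
  cat(sprintf("  RR(nmi) = %.4f, RR(pearson) = %.4f, RE = %.4f bits\n",
              x$rr_nmi, x$rr_pearson, x$re))
  invisible(x)
}
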