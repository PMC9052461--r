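# ---------------------------------------------------------------------------
# SVM-RFE with correlation bias reduction (CBR).  Plain SVM-RFE trains a
# linear SVM, scores each surviving feature by its squared weight, and
# eliminates the lowest-scoring batch; with groups of highly correlated
# features the group members share weight mass, each looks individually
# weak, and whole informative groups can be flushed early.  The CBR rule
# defers the elimination of a marked feature whenever it is strongly
# correlated (|r| >= cbr_tau) with an unmarked survivor, unless that would
# empty the batch — then only the single weakest marked feature goes.
# ---------------------------------------------------------------------------

# one-vs-rest linear SVM weight-square scores for the surviving features;
# rows of `x` are features.  Features are standardized within each call so
# weight magnitudes stay comparable across iterations.
svm_weight_scores <- function(x, f, cost) {
  xs <- t(scale(t(x)))        # feature-wise standardization (n-1 convention)
  xs[is.na(xs)] <- 0          # constant feature within survivors: no signal
  tx <- t(xs)                 # samples x features for e1071
  lv <- levels(f)
  score <- numeric(nrow(x))
  models <- if (length(lv) == 2) lv[1] else lv
  for (cl in models) {
    y <- factor(ifelse(f == cl, "pos", "rest"), levels = c("pos", "rest"))
    fit <- tryCatch(
      e1071::svm(tx, y, kernel = "linear", cost = cost, scale = FALSE),
      error = function(e) stop("linear SVM failed for class '", cl, "': ",
                               conditionMessage(e)))
    w <- drop(crossprod(fit$coefs, fit$SV))
    score <- score + w^2
  }
  score
}

#' SVM-RFE ranking with correlation bias reduction
#'
#' Backward elimination: repeatedly train one-vs-rest linear SVMs on the
#' surviving features, score feature i by the sum over class models of its
#' squared weight, and eliminate the lowest-scoring `rfe_step` features,
#' subject to the CBR deferral rule described above.  Elimination stops
#' when `params$k` features survive.  The final ranking lists survivors
#' first (by final score, descending), then eliminated features in reverse
#' elimination order.  With `cbr_tau = 1` the rule never fires and the
#' procedure is textbook SVM-RFE.
#'
#' @param data an [omics_matrix()] of z-scored continuous values.
#' @param labels aligned [class_labels()].
#' @param params [criterion_params()]; fields `k`, `cbr_tau`, `rfe_step`
#'   (`NULL` = ceiling of 10\% of survivors) and `svm_cost` are used.
#' @return An `fs_result`; `$trace` covers the k survivors, `$ranking` the
#'   full ranked feature list, and `$elimination` the per-iteration audit
#'   trail (survivors, scores, eliminated, deferred).
#' @export
svm_rfe_cbr_rank <- function(data, labels, params = criterion_params()) {
  x <- unclass(data)
  if (!identical(colnames(x), names(labels)))
    stop("data samples and labels are not aligned")
  f <- as_factor(labels)
  if (nlevels(f) < 2) stop("need >= 2 classes")
  d <- nrow(x)
  k <- min(params$k, d)
  # pairwise |r| is constant across iterations: compute once
  cors <- abs(suppressWarnings(stats::cor(t(x))))
  cors[is.na(cors)] <- 0
  diag(cors) <- 0
  surv <- seq_len(d)
  elim_order <- integer(0)              # first eliminated ... last eliminated
  eliminated_trace <- list()
  it <- 0L
  score <- rep(NA_real_, d)
  while (length(surv) > k) {
    it <- it + 1L
    sc <- svm_weight_scores(x[surv, , drop = FALSE], f, params$svm_cost)
    score[surv] <- sc
    step <- if (is.null(params$rfe_step)) ceiling(0.1 * length(surv)) else
      params$rfe_step
    nelim <- min(step, length(surv) - k)
    ord <- order(sc, surv)              # ascending score; ties: lowest index
    marked <- surv[ord[seq_len(nelim)]]
    unmarked <- setdiff(surv, marked)
    defer <- vapply(marked, function(i)
      length(unmarked) > 0 && max(cors[i, unmarked]) >= params$cbr_tau,
      logical(1))
    if (all(defer)) {
      # deferral would empty the batch: drop the single weakest marked one
      drop_now <- marked[1]
      deferred <- setdiff(marked, drop_now)
    } else {
      drop_now <- marked[!defer]
      deferred <- marked[defer]
    }
    # batch members leave in ascending-score order
    drop_now <- drop_now[order(score[drop_now], drop_now)]
    eliminated_trace[[it]] <- list(
      survivors = rownames(x)[surv], scores = stats::setNames(sc, rownames(x)[surv]),
      eliminated = rownames(x)[drop_now], deferred = rownames(x)[deferred])
    elim_order <- c(elim_order, drop_now)
    surv <- setdiff(surv, drop_now)
  }
  # final scores for the survivors
  sc <- svm_weight_scores(x[surv, , drop = FALSE], f, params$svm_cost)
  score[surv] <- sc
  surv_ranked <- surv[order(-sc, surv)]
  ranking <- c(surv_ranked, rev(elim_order))
  trace <- data.frame(rank = seq_len(k),
                      feature_id = rownames(x)[surv_ranked],
                      relevance = score[surv_ranked], redundancy = 0,
                      score = score[surv_ranked], stringsAsFactors = FALSE)
  new_fs_result("SVM_RFE_CBR", params, trace$feature_id, trace,
                universe = rownames(x),
                extra = list(ranking = rownames(x)[ranking],
                             elimination = eliminated_trace))
}
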