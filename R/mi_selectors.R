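# ---------------------------------------------------------------------------
# Greedy forward selection under incremental mutual-information criteria.
# Every criterion has the shape  relevance(f_i) - redundancy(f_i | S):
#
#   MIFS     I(f_i;C) - beta * sum_{s in S} I(f_s;f_i)
#   MIFS-U   I(f_i;C) - beta * sum_{s in S} [I(f_s;C)/H(f_s)] I(f_i;f_s)
#   mRMR     I(f_i;C) - (1/|S|) sum_{s in S} I(f_i;f_s)
#   NMIFS    I(f_i;C) - (1/|S|) sum_{s in S} NMI(f_i;f_s)
#   INMIFS   NMI(C;f_i) - (1/|S|) sum_{s in S} NMI(f_s;f_i)
#   VWMRmR   NMI(C;f_i) - (1 + w|S|/k) (1/|S|) sum_{s in S} NMI(f_i;f_s)
#
# For |S| = 0 every criterion is its relevance term alone.  MIFS/MIFS-U/
# NMIFS are kept as reference baselines; the compared set is mRMR, INMIFS,
# VWMRmR (plus DFS and SVM-RFE-CBR from their own modules).
# ---------------------------------------------------------------------------

MI_METHODS <- c("MIFS", "MIFS_U", "mRMR", "NMIFS", "INMIFS", "VWMRmR")
ALL_METHODS <- c(MI_METHODS, "DFS", "SVM_RFE_CBR")

# which criteria normalize the relevance / redundancy terms
uses_nmi_relevance <- function(method) method %in% c("INMIFS", "VWMRmR")
uses_nmi_redundancy <- function(method) method %in% c("NMIFS", "INMIFS",
                                                      "VWMRmR")

#' Criterion and selector parameters
#'
#' One bag of tunables shared by all selectors; each selector reads only
#' the fields it uses.
#'
#' @param beta redundancy weight for MIFS/MIFS-U (default 0.5, the
#'   mid-range of published usage; these two criteria are baselines).
#' @param w VWMRmR redundancy ramp weight (>= 0, default 1): the redundancy
#'   multiplier grows as 1 + w|S|/k while the selected set S fills toward k.
#' @param k target subset size (default 50 features).
#' @param dfs_p l2,p sparsity exponent for DFS, 0 < p <= 2 (default 1, the
#'   l2,1 row-sparsity case).
#' @param dfs_reg DFS regularization weight (> 0).
#' @param dfs_eps ridge guard added to the within-class scatter.
#' @param dfs_tol,dfs_max_iter DFS convergence controls.
#' @param cbr_tau absolute-correlation threshold above which a feature
#'   marked for elimination is deferred (correlation bias reduction).
#' @param rfe_step features eliminated per RFE iteration; `NULL` means
#'   ceiling(10\% of current survivors).
#' @param svm_cost linear-SVM cost parameter C.
#' @return A list of class `"criterion_params"`.
#' @export
criterion_params <- function(beta = 0.5, w = 1.0, k = 50L,
                             dfs_p = 1.0, dfs_reg = 1.0, dfs_eps = 1e-8,
                             dfs_tol = 1e-6, dfs_max_iter = 200L,
                             cbr_tau = 0.85, rfe_step = NULL,
                             svm_cost = 1.0) {
  stopifnot(beta >= 0, w >= 0, k >= 1,
            dfs_p > 0, dfs_p <= 2, dfs_reg > 0,
            cbr_tau >= 0, cbr_tau <= 1,
            is.null(rfe_step) || rfe_step >= 1,
            svm_cost > 0)
  structure(list(beta = beta, w = w, k = as.integer(k),
                 dfs_p = dfs_p, dfs_reg = dfs_reg, dfs_eps = dfs_eps,
                 dfs_tol = dfs_tol, dfs_max_iter = as.integer(dfs_max_iter),
                 cbr_tau = cbr_tau, rfe_step = rfe_step,
                 svm_cost = svm_cost),
            class = "criterion_params")
}

# shared result container ----------------------------------------------------

new_fs_result <- function(method, params, selected, trace, universe,
                          extra = list()) {
  stopifnot(!anyDuplicated(selected), nrow(trace) == length(selected))
  structure(c(list(method = method, params = params,
                   selected = selected, trace = trace,
                   universe = universe), extra),
            class = "fs_result")
}

#' @export
print.fs_result <- function(x, n = 10, ...) {
  cat(sprintf("fs_result: %s, %d of %d features selected\n",
              x$method, length(x$selected), length(x$universe)))
  print(utils::head(x$trace, n), row.names = FALSE)
  if (nrow(x$trace) > n) cat("...\n")
  invisible(x)
}

#' @export
summary.fs_result <- function(object, ...) {
  cat(sprintf("Feature selection by %s (k = %d)\n", object$method,
              length(object$selected)))
  print(object$trace, row.names = FALSE)
  invisible(object$trace)
}

#' @export
plot.fs_result <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$rank, tr$score, type = "b", pch = 16,
                 xlab = "selection step", ylab = "criterion score",
                 main = sprintf("%s selection trace", x$method), ...)
  invisible(x)
}

#' Write a selection result as TSV
#' @param x an `fs_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(x, path) {
  utils::write.table(x$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# criterion machinery --------------------------------------------------------

# relevance of every feature with the class, raw I or normalized
relevance_vector <- function(disc, cls, normalized) {
  fun <- if (normalized) normalized_mi else mutual_information
  vapply(seq_len(nrow(disc)), function(i) fun(disc[i, ], cls), numeric(1))
}

# redundancy term of candidate `cand` (index) given selected indices `sel`;
# `red` is the |sel| x d matrix of pairwise I or NMI values
redundancy_term <- function(method, cand, sel, red, params, relC, hS) {
  if (length(sel) == 0) return(0)
  v <- red[seq_along(sel), cand]
  switch(method,
    MIFS = params$beta * sum(v),
    MIFS_U = {
      ok <- hS[sel] > 0
      if (!all(ok))
        warning("MIFS-U: skipping constant selected feature(s) with H = 0")
      params$beta * sum((relC[sel[ok]] / hS[sel[ok]]) * v[ok])
    },
    mRMR = mean(v),
    NMIFS = mean(v),
    INMIFS = mean(v),
    VWMRmR = (1 + params$w * length(sel) / params$k) * mean(v),
    stop("unknown method: ", method))
}

#' Score one candidate feature under a selection criterion
#'
#' Evaluates the incremental criterion value of adding `candidate` to the
#' already-selected set.  With an empty selected set every criterion
#' reduces to its relevance term.
#'
#' @param method one of `"MIFS"`, `"MIFS_U"`, `"mRMR"`, `"NMIFS"`,
#'   `"INMIFS"`, `"VWMRmR"`.
#' @param candidate feature id (or row index) of the candidate.
#' @param selected character vector of already-selected feature ids (or
#'   indices); must not contain the candidate.
#' @param data a `disc_matrix` from [discretize()].
#' @param labels aligned [class_labels()].
#' @param params [criterion_params()].
#' @return The criterion score (relevance minus redundancy).
#' @export
score_candidate <- function(method, candidate, selected, data, labels,
                            params = criterion_params()) {
  method <- match.arg(method, MI_METHODS)
  idx <- function(f) if (is.character(f)) match(f, rownames(data)) else
    as.integer(f)
  ci <- idx(candidate)
  si <- if (length(selected)) idx(selected) else integer(0)
  if (anyNA(c(ci, si))) stop("unknown feature id")
  if (ci %in% si) stop("candidate already selected")
  cls <- as.integer(as_factor(labels))
  fun_red <- if (uses_nmi_redundancy(method)) normalized_mi else
    mutual_information
  rel <- if (uses_nmi_relevance(method)) normalized_mi(data[ci, ], cls) else
    mutual_information(data[ci, ], cls)
  red <- matrix(0, nrow = length(si), ncol = nrow(data))
  for (j in seq_along(si)) red[j, ci] <- fun_red(data[si[j], ], data[ci, ])
  relC <- vapply(seq_len(nrow(data)), function(i)
    mutual_information(data[i, ], cls), numeric(1))
  hS <- vapply(seq_len(nrow(data)), function(i) entropy_bits(data[i, ]),
               numeric(1))
  rel - redundancy_term(method, ci, si, red, params, relC, hS)
}

#' Greedy forward selection under a mutual-information criterion
#'
#' Step 1 picks the feature with maximal (normalized, where the criterion
#' normalizes relevance) class relevance; each subsequent step picks the
#' argmax of the criterion over the remaining features.  Ties are broken by
#' lowest feature index, so the result is fully deterministic.  Pairwise
#' MI/NMI values against selected features are cached across steps.
#'
#' @param method one of the six criteria (see [score_candidate()]).
#' @param data a `disc_matrix` (features x samples, states -1/0/1).
#' @param labels aligned [class_labels()].
#' @param params [criterion_params()]; `params$k` features are selected
#'   (capped at the number of available features).
#' @return An `fs_result` with the ordered selection and a per-step trace
#'   of (relevance, redundancy, score).
#' @export
greedy_select <- function(method, data, labels,
                          params = criterion_params()) {
  method <- match.arg(method, MI_METHODS)
  d <- nrow(data)
  if (d == 0) stop("empty feature set")
  if (params$k < 1) stop("k must be >= 1")
  if (!identical(colnames(data), names(labels)))
    stop("data samples and labels are not aligned")
  k <- min(params$k, d)
  cls <- as.integer(as_factor(labels))
  fun_red <- if (uses_nmi_redundancy(method)) normalized_mi else
    mutual_information
  rel <- relevance_vector(data, cls, uses_nmi_relevance(method))
  relC <- if (method == "MIFS_U")
    relevance_vector(data, cls, FALSE) else rel
  hS <- vapply(seq_len(d), function(i) entropy_bits(data[i, ]), numeric(1))

  sel <- integer(0)
  remaining <- rep(TRUE, d)
  red <- matrix(NA_real_, nrow = k, ncol = d)  # red[j, ] = pairwise vs sel[j]
  trace <- data.frame(rank = seq_len(k), feature_id = character(k),
                      relevance = numeric(k), redundancy = numeric(k),
                      score = numeric(k), stringsAsFactors = FALSE)

  for (step in seq_len(k)) {
    cand <- which(remaining)
    if (step == 1) {
      scores <- rel[cand]
      reds <- numeric(length(cand))
    } else {
      reds <- vapply(cand, function(ci)
        redundancy_term(method, ci, sel, red, params, relC, hS), numeric(1))
      scores <- rel[cand] - reds
    }
    # ties (scores equal up to fp rounding) break to the lowest feature index
    best <- cand[which(scores >= max(scores) - 1e-9)[1]]
    pos <- match(best, cand)
    trace$feature_id[step] <- rownames(data)[best]
    trace$relevance[step] <- rel[best]
    trace$redundancy[step] <- reds[pos]
    trace$score[step] <- scores[pos]
    sel <- c(sel, best)
    remaining[best] <- FALSE
    if (step < k) {
      xb <- data[best, ]
      red[step, ] <- vapply(seq_len(d), function(i)
        if (remaining[i]) fun_red(xb, data[i, ]) else 0, numeric(1))
    }
  }
  new_fs_result(method, params, trace$feature_id, trace,
                universe = rownames(data))
}
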