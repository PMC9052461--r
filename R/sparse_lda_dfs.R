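# ---------------------------------------------------------------------------
# Discriminative feature selection (DFS): linear discriminant analysis with
# an l2,p row-sparsity penalty on the projection matrix W.  The objective
#
#     J(W) = tr( W' (Sw + eps I) W ) + reg * sum_i (||w_i||^2 + eps)^{p/2}
#     s.t.  W' Sb W = I
#
# is minimized by alternating (a) a generalized eigenproblem for W with the
# diagonal reweighting matrix D fixed, and (b) the IRLS update
# d_i = (p/2) ||w_i||^{p-2}.  Because each (a)-step globally minimizes the
# majorizing surrogate under a constraint set that does not depend on D,
# the objective is non-increasing over iterations for 0 < p <= 2.
# Features are ranked by the row norms ||w_i||: a row driven to zero
# contributes nothing to the discriminant and is discarded.  Ranking is
# simultaneous (not greedy), which is what lets the sparsity penalty
# suppress redundant copies of informative features.
# ---------------------------------------------------------------------------

#' Between- and within-class scatter matrices
#'
#' @param data an [omics_matrix()] (features x samples), normally z-scored.
#' @param labels aligned [class_labels()].
#' @return A list of class `"scatter_pair"` with `Sb`, `Sw` (d x d,
#'   symmetric PSD; `Sb + Sw` equals the total scatter) and `class_sizes`.
#' @export
scatter_matrices <- function(data, labels) {
  x <- unclass(data)
  if (!identical(colnames(x), names(labels)))
    stop("data samples and labels are not aligned")
  f <- as_factor(labels)
  sizes <- table(f)
  if (any(sizes == 0)) stop("class with 0 samples")
  grand <- rowMeans(x)
  d <- nrow(x)
  Sb <- matrix(0, d, d)
  Sw <- matrix(0, d, d)
  for (lv in levels(f)) {
    idx <- which(f == lv)
    mu_c <- rowMeans(x[, idx, drop = FALSE])
    dm <- mu_c - grand
    Sb <- Sb + length(idx) * tcrossprod(dm)
    xc <- x[, idx, drop = FALSE] - mu_c
    Sw <- Sw + tcrossprod(xc)
  }
  dimnames(Sb) <- dimnames(Sw) <- list(rownames(x), rownames(x))
  structure(list(Sb = Sb, Sw = Sw, class_sizes = sizes),
            class = "scatter_pair")
}

# top-m generalized eigenvectors of Sb v = lambda M v, M symmetric pd
gen_eig_top <- function(Sb, M, m) {
  R <- chol(M)
  # symmetric transform: R^{-T} Sb R^{-1}
  A <- backsolve(R, t(backsolve(R, t(Sb), transpose = TRUE)),
                 transpose = TRUE)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  V <- backsolve(R, e$vectors[, seq_len(m), drop = FALSE])
  list(vectors = V, values = e$values[seq_len(m)])
}

#' Rank features by sparse-LDA discriminative weight
#'
#' Fits the l2,p-regularized LDA projection described above and ranks all
#' features by the Euclidean norm of their projection row, descending; the
#' top `params$k` form the selection.  The per-iteration objective is
#' monitored and is non-increasing; failure to converge within
#' `dfs_max_iter` returns the best iterate with a warning.
#'
#' @param data an [omics_matrix()] of z-scored continuous values.
#' @param labels aligned [class_labels()].
#' @param params [criterion_params()]; fields `dfs_p`, `dfs_reg`,
#'   `dfs_eps`, `dfs_tol`, `dfs_max_iter`, `k` are used.
#' @return An `fs_result`; `$trace` holds the per-feature row norms of the
#'   ranked features, `$objective` the iteration trace, `$converged` a flag,
#'   and `$row_norms` the full named row-norm vector.
#' @export
dfs_rank <- function(data, labels, params = criterion_params()) {
  p <- params$dfs_p
  if (p <= 0 || p > 2) stop("dfs_p must satisfy 0 < p <= 2")
  if (params$dfs_reg <= 0) stop("dfs_reg must be > 0")
  x <- unclass(data)
  d <- nrow(x)
  sc <- scatter_matrices(data, labels)
  m <- max(1L, nlevels(as_factor(labels)) - 1L)
  eps <- params$dfs_eps
  Swr <- sc$Sw + diag(eps, d)
  Dg <- rep(1, d)
  obj <- numeric(0)
  W_best <- NULL
  converged <- FALSE
  for (it in seq_len(params$dfs_max_iter)) {
    M <- Swr + params$dfs_reg * diag(Dg, d)
    ge <- gen_eig_top(sc$Sb, M, m)
    lam <- pmax(ge$values, 0)
    W <- ge$vectors
    # scale columns to meet W' Sb W = I where the eigenvalue allows it
    for (j in seq_len(m)) {
      q <- drop(crossprod(W[, j], sc$Sb %*% W[, j]))
      if (q > 1e-12) W[, j] <- W[, j] / sqrt(q)
    }
    rn2 <- rowSums(W^2)
    J <- sum(diag(crossprod(W, Swr %*% W))) +
      params$dfs_reg * sum((rn2 + eps)^(p / 2))
    obj <- c(obj, J)
    W_best <- W
    Dg <- (p / 2) * (rn2 + eps)^((p - 2) / 2)
    if (it > 1 && abs(obj[it - 1] - J) <= params$dfs_tol * max(1, abs(obj[it - 1]))) {
      converged <- TRUE
      break
    }
    if (p == 2) { converged <- TRUE; break }  # D is constant: one step solves it
  }
  if (!converged)
    warning("dfs_rank: not converged after ", params$dfs_max_iter,
            " iterations; returning best iterate")
  rown <- sqrt(rowSums(W_best^2))
  names(rown) <- rownames(x)
  ord <- order(-rown, seq_len(d))   # ties: lowest original index first
  k <- min(params$k, d)
  top <- ord[seq_len(k)]
  trace <- data.frame(rank = seq_len(k), feature_id = rownames(x)[top],
                      relevance = rown[top], redundancy = 0,
                      score = rown[top], stringsAsFactors = FALSE)
  new_fs_result("DFS", params, trace$feature_id, trace,
                universe = rownames(x),
                extra = list(row_norms = rown, objective = obj,
                             converged = converged))
}
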