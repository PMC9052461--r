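# ---------------------------------------------------------------------------
# Cross-method signature intersection: features that every selector agrees
# on form the signature; the full Venn-region decomposition shows where the
# methods diverge.
# ---------------------------------------------------------------------------

#' Intersect top-feature lists across selection methods
#'
#' Computes the strict all-methods intersection (the signature core), the
#' per-feature membership counts, and the count of every Venn region over
#' the 2^m - 1 non-empty method subsets.  A majority-vote core (features
#' present in more than half of the lists) is also reported but the strict
#' intersection is the signature.
#'
#' @param results a named list (>= 2 elements) of `fs_result` objects or
#'   plain character vectors of selected feature ids.  `fs_result` inputs
#'   must share the same feature universe.
#' @return An object of class `"signature_set"`: `methods`, `core`,
#'   `majority`, `membership` (logical feature x method matrix over the
#'   union), and `regions` (data.frame of region label / count).
#' @export
intersect_signatures <- function(results) {
  if (length(results) < 2) stop("need >= 2 selection results")
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- vapply(seq_along(results), function(i) {
      r <- results[[i]]
      if (inherits(r, "fs_result")) r$method else paste0("method", i)
    }, character(1))
  lists <- lapply(results, function(r)
    if (inherits(r, "fs_result")) r$selected else as.character(r))
  universes <- lapply(results, function(r)
    if (inherits(r, "fs_result")) r$universe else NULL)
  known <- Filter(Negate(is.null), universes)
  if (length(known) > 1) {
    ref <- sort(known[[1]])
    for (u in known[-1])
      if (!identical(sort(u), ref))
        stop("selection results come from different feature universes")
  }
  m <- length(lists)
  universe <- sort(unique(unlist(lists)))
  membership <- vapply(lists, function(l) universe %in% l,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(lists)))
  core <- universe[rowSums(membership) == m]
  majority <- universe[rowSums(membership) > m / 2]
  # every non-empty subset of methods is a Venn region
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1, , drop = FALSE]
  region_label <- apply(subsets, 1, function(s)
    paste(names(lists)[as.logical(s)], collapse = "&"))
  region_count <- apply(subsets, 1, function(s)
    sum(apply(membership, 1, function(r) all(r == as.logical(s)))))
  regions <- data.frame(region = region_label, count = region_count,
                        n_methods = rowSums(subsets),
                        stringsAsFactors = FALSE, row.names = NULL)
  regions <- regions[order(-regions$n_methods, regions$region), ]
  rownames(regions) <- NULL
  structure(list(methods = names(lists), core = core, majority = majority,
                 membership = membership, regions = regions),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set over %d methods (%s)\n", length(x$methods),
              paste(x$methods, collapse = ", ")))
  cat(sprintf("  union: %d features; core (all methods): %d\n",
              nrow(x$membership), length(x$core)))
  if (length(x$core))
    cat("  core features:", paste(x$core, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.signature_set <- function(x, ...) {
  # overlap-degree barplot (a Venn diagram is unreadable beyond 3 sets)
  tab <- table(factor(rowSums(x$membership), levels = seq_along(x$methods)))
  graphics::barplot(tab, xlab = "number of methods containing the feature",
                    ylab = "features",
                    main = "cross-method feature overlap", ...)
  invisible(x)
}

#' Write a signature set as TSV
#'
#' One row per feature in the union with the number of methods containing
#' it, its Venn-region label, and a flag for core membership.
#'
#' @param x a `signature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_set <- function(x, path) {
  region <- apply(x$membership, 1, function(r)
    paste(x$methods[r], collapse = "&"))
  df <- data.frame(feature_id = rownames(x$membership),
                   n_methods = rowSums(x$membership),
                   region = region,
                   in_core = rownames(x$membership) %in% x$core,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_methods, df$feature_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Win-draw-loss tally of one method against the others
#'
#' Compares per-classifier mean CV accuracies of `method` against every
#' other method in an evaluation report: a win is a strictly higher mean,
#' a draw an equal one (at `tol`).
#'
#' @param evaluations named list of `fs_evaluation` objects (one per
#'   method).
#' @param method name of the reference method.
#' @param tol equality tolerance on mean accuracy (percentage points).
#' @return data.frame with one row per opposing method: wins, draws,
#'   losses over the shared classifiers.
#' @export
wdl_table <- function(evaluations, method, tol = 1e-9) {
  if (!method %in% names(evaluations)) stop("unknown method: ", method)
  ref <- evaluations[[method]]
  others <- setdiff(names(evaluations), method)
  rows <- lapply(others, function(o) {
    cls <- intersect(names(ref$accuracy), names(evaluations[[o]]$accuracy))
    a <- vapply(cls, function(c) ref$accuracy[[c]]$mean_pct, numeric(1))
    b <- vapply(cls, function(c) evaluations[[o]]$accuracy[[c]]$mean_pct,
                numeric(1))
    data.frame(opponent = o, wins = sum(a > b + tol),
               draws = sum(abs(a - b) <= tol), losses = sum(a < b - tol),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
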