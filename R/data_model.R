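#' omicfs: supervised feature selection and benchmarking for multi-omics data
#'
#' High-dimensional omics profiles (gene or exon expression, DNA methylation,
#' copy-number scores, pathway activities) carry hundreds to thousands of
#' continuous features per sample, most of them irrelevant or redundant for
#' predicting a clinical class such as cytogenetic risk.  omicfs implements a
#' family of supervised feature selectors over such data and a common
#' benchmarking harness so that competing selectors can be compared on equal
#' footing:
#'
#' \itemize{
#'   \item greedy forward selection under mutual-information criteria
#'     (MIFS, MIFS-U, mRMR, NMIFS, INMIFS, VWMRmR) on three-state
#'     discretized data — see [greedy_select()];
#'   \item discriminative feature selection (DFS): sparse LDA with an
#'     l2,p row-sparsity penalty — see [dfs_rank()];
#'   \item SVM-RFE with correlation bias reduction — see [svm_rfe_cbr_rank()];
#'   \item evaluation by repeated stratified CV accuracy, redundancy rate
#'     and representation entropy — see [cv_accuracy()], [redundancy_rate()],
#'     [representation_entropy()];
#'   \item cross-method signature intersection — see [intersect_signatures()];
#'   \item a seeded synthetic generator with planted ground truth — see
#'     [generate_synthetic()]; and an end-to-end driver, [run_pipeline()].
#' }
#'
#' @name omicfs-package
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Core containers.  An omics matrix is a plain numeric matrix, features in
# rows and samples in columns, carrying unique dimnames; class labels are a
# factor named by sample id.  Both get light S3 classes so that validity can
# be enforced at construction and printing stays informative.
# ---------------------------------------------------------------------------

#' Construct an omics matrix (features x samples)
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids character vectors of unique identifiers;
#'   taken from `dimnames(values)` when omitted.
#' @return A numeric matrix of class `"omics_matrix"` with features as
#'   rownames and samples as colnames.  All values must be finite; missing
#'   values are a hard error (no imputation is performed anywhere in omicfs).
#' @examples
#' m <- omics_matrix(matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))))
#' dim(m)
#' @export
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("length(feature_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 feature_ids[bad[1]], sample_ids[bad[2]]))
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples\n", nrow(x), ncol(x)))
  k <- min(5L, nrow(x)); s <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(s), drop = FALSE], ...)
  if (nrow(x) > k || ncol(x) > s) cat("...\n")
  invisible(x)
}

#' Construct per-sample class labels
#'
#' @param labels factor or character vector of class assignments, one per
#'   sample.
#' @param sample_ids character vector of unique sample identifiers; taken
#'   from `names(labels)` when omitted.
#' @return A factor of class `"class_labels"` named by sample id.  Every
#'   class level has at least one sample and there are at least two levels.
#' @examples
#' class_labels(c(s1 = "poor", s2 = "favorable", s3 = "poor"))
#' @export
class_labels <- function(labels, sample_ids = names(labels)) {
  if (is.null(sample_ids)) stop("sample identifiers are required")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(labels))
    stop("length(sample_ids) != length(labels)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in labels")
  if (anyNA(labels)) stop("missing class label for sample(s): ",
                          paste(sample_ids[is.na(labels)], collapse = ", "))
  f <- factor(labels)
  f <- droplevels(f)
  if (nlevels(f) < 2) stop("need at least 2 classes, got ", nlevels(f))
  names(f) <- sample_ids
  structure(f, class = c("class_labels", "factor"))
}

#' @export
print.class_labels <- function(x, ...) {
  cat(sprintf("class_labels: %d samples, %d classes\n", length(x), nlevels(x)))
  print(table(unclass(x)))
  invisible(x)
}

# internal: strip class so base factor methods apply cleanly
as_factor <- function(labels) factor(unclass(labels), labels = levels(labels))

# ---------------------------------------------------------------------------
# Delimited-text I/O.  Canonical on-disk orientation is features in rows,
# samples in columns (the layout of Xena-style profile dumps); a flag accepts
# the transpose.  Delimiter is inferred from the extension (.csv -> comma,
# anything else -> tab) and can be overridden.
# ---------------------------------------------------------------------------

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature matrix from delimited text
#'
#' Expects one header row and one leading identifier column.  Every data
#' cell must parse as a finite number; missing or non-numeric cells are a
#' hard error reported with their feature and sample.
#'
#' @param path file path to a TSV/CSV table.
#' @param orientation `"features_in_rows"` (default, the canonical layout)
#'   or `"samples_in_rows"` for the transpose.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return An [omics_matrix()] in features x samples orientation.
#' @export
read_omics_matrix <- function(path,
                              orientation = c("features_in_rows",
                                              "samples_in_rows"),
                              sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- infer_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected an identifier column plus data columns")
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf(
      "non-numeric or missing cell '%s' at row id '%s', column '%s' in %s",
      mat[bad[1], bad[2]], ids[bad[1]], colnames(mat)[bad[2]], path))
  }
  dimnames(num) <- list(ids, colnames(mat))
  if (orientation == "samples_in_rows") num <- t(num)
  omics_matrix(num)
}

#' Write an omics matrix as delimited text
#'
#' Values are written at 12 significant digits so that a read/write round
#' trip is the identity for all practical purposes.
#'
#' @param x an [omics_matrix()].
#' @param path output path; `.csv` selects comma separation, anything else tab.
#' @param sep optional separator override.
#' @param id_col name for the identifier column header.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path, sep = NULL, id_col = "feature_id") {
  sep <- infer_sep(path, sep)
  df <- data.frame(id = rownames(x),
                   signif(unclass(x), 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read class labels from a two-column table
#'
#' @param path TSV/CSV file with columns (sample_id, class) and a header row.
#' @param sep optional separator override.
#' @return A [class_labels()] object.
#' @export
read_class_labels <- function(path, sep = NULL) {
  sep <- infer_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected columns (sample_id, class)")
  class_labels(df[[2]], sample_ids = df[[1]])
}

#' Write class labels as a two-column TSV
#' @param x a [class_labels()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_class_labels <- function(x, path) {
  utils::write.table(
    data.frame(sample_id = names(x), class = as.character(x)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sample alignment.
# ---------------------------------------------------------------------------

#' Align a matrix and its labels on their shared samples
#'
#' Restricts both objects to the intersection of their sample identifiers,
#' in sorted lexicographic order.  Sorting makes downstream seeded
#' cross-validation reproducible regardless of input file order.  The
#' operation is idempotent.
#'
#' @param matrix an [omics_matrix()].
#' @param labels a [class_labels()] object.
#' @return `list(matrix =, labels =)` restricted to the common samples.
#' @export
align_samples <- function(matrix, labels) {
  common <- sort(intersect(colnames(matrix), names(labels)))
  if (length(common) == 0)
    stop("no samples shared between matrix and labels")
  m <- omics_matrix(unclass(matrix)[, common, drop = FALSE])
  lab_chr <- as.character(labels)
  l <- class_labels(lab_chr[match(common, names(labels))],
                    sample_ids = common)
  list(matrix = m, labels = l)
}
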