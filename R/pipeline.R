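# ---------------------------------------------------------------------------
# End-to-end driver: align -> drop constants -> z-score -> differential
# filter -> discretize -> run the selectors -> evaluate each selection
# under all three criteria -> intersect signatures -> report.  MI-based
# selectors and RR(nmi) consume the discretized matrix; DFS, SVM-RFE-CBR,
# the classifiers, RR(pearson) and RE consume the continuous z-scored one.
# ---------------------------------------------------------------------------

#' Dispatch a feature selector by name
#'
#' @param method one of MIFS, MIFS_U, mRMR, NMIFS, INMIFS, VWMRmR (run on
#'   the discretized matrix), DFS or SVM_RFE_CBR (run on the continuous
#'   z-scored matrix).
#' @param data_cont z-scored [omics_matrix()].
#' @param data_disc matching `disc_matrix`.
#' @param labels aligned [class_labels()].
#' @param params [criterion_params()].
#' @return An `fs_result`.
#' @export
feature_select <- function(method, data_cont, data_disc, labels,
                           params = criterion_params()) {
  method <- match.arg(method, ALL_METHODS)
  if (method %in% MI_METHODS) greedy_select(method, data_disc, labels, params)
  else if (method == "DFS") dfs_rank(data_cont, labels, params)
  else svm_rfe_cbr_rank(data_cont, labels, params)
}

#' Pipeline configuration
#'
#' @param input either a [synthetic_spec()] or a
#'   `list(matrix = <path>, labels = <path>)` of delimited-text inputs.
#' @param methods selector names to run (default the five compared
#'   methods: mRMR, INMIFS, DFS, SVM_RFE_CBR, VWMRmR).
#' @param alpha differential-filter significance threshold.
#' @param d0 variance-moderation prior weight for the filter (0 = plain
#'   ANOVA).
#' @param params [criterion_params()] shared by all selectors (`params$k`
#'   is the subset size).
#' @param classifiers classifiers for [cv_accuracy()].
#' @param folds,repeats CV geometry.
#' @param tuning tuning argument forwarded to [cv_accuracy()].
#' @param adaboost_rounds boosting rounds.
#' @param seed master seed for CV fold assignment.
#' @param orientation matrix file orientation (see [read_omics_matrix()]).
#' @param out_dir if non-NULL, all stage artifacts are written there.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input,
                            methods = c("mRMR", "INMIFS", "DFS",
                                        "SVM_RFE_CBR", "VWMRmR"),
                            alpha = 0.05, d0 = 0,
                            params = criterion_params(),
                            classifiers = CLASSIFIERS,
                            folds = 10L, repeats = 10L, tuning = NULL,
                            adaboost_rounds = 50L,
                            seed = 1L, orientation = "features_in_rows",
                            out_dir = NULL) {
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  classifiers <- match.arg(classifiers, CLASSIFIERS, several.ok = TRUE)
  stopifnot(params$k >= 1, folds >= 2)
  structure(list(input = input, methods = methods, alpha = alpha, d0 = d0,
                 params = params, classifiers = classifiers,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 tuning = tuning, adaboost_rounds = adaboost_rounds,
                 seed = as.integer(seed), orientation = orientation,
                 out_dir = out_dir),
            class = "pipeline_config")
}

load_pipeline_input <- function(config) {
  inp <- config$input
  if (inherits(inp, "synthetic_spec")) {
    d <- generate_synthetic(inp)
    list(matrix = d$matrix, labels = d$labels, truth = d$truth,
         source = sprintf("synthetic(seed=%d)", inp$seed))
  } else if (is.list(inp) && !is.null(inp$matrix) && !is.null(inp$labels)) {
    list(matrix = read_omics_matrix(inp$matrix,
                                    orientation = config$orientation),
         labels = read_class_labels(inp$labels), truth = NULL,
         source = inp$matrix)
  } else stop("input must be a synthetic_spec or list(matrix=, labels=)")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full selection-and-evaluation pipeline
#'
#' Executes the stages in order, halting with the stage name on any error.
#' When `config$out_dir` is set, every stage artifact (normalized and
#' discretized matrices, filter table, per-method ranking TSVs, signature
#' TSV, JSON report) is written there.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `"omicfs_report"`: `selections` (named
#'   `fs_result`s), `evaluations` (named `fs_evaluation`s), `signatures`
#'   (a `signature_set`), `filter` (the differential screen), `truth`
#'   (ground truth when the input was synthetic) and `provenance` (all
#'   parameters and seeds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dat <- pipeline_stage("load", load_pipeline_input(config))
  ali <- pipeline_stage("align", align_samples(dat$matrix, dat$labels))
  x <- pipeline_stage("normalize", {
    m <- drop_constant_features(ali$matrix)
    zscore_normalize(m)
  })
  filt <- pipeline_stage("differential_filter",
                         differential_filter(x, ali$labels,
                                             alpha = config$alpha,
                                             d0 = config$d0))
  kept <- filt$feature_id[filt$kept]
  if (length(kept) == 0)
    stop("pipeline stage 'differential_filter' failed: no features pass alpha = ",
         config$alpha, call. = FALSE)
  xk <- omics_matrix(unclass(x)[kept, , drop = FALSE])
  disc <- pipeline_stage("discretize", discretize(xk))

  selections <- list()
  for (m in config$methods)
    selections[[m]] <- pipeline_stage(paste0("select:", m),
      feature_select(m, xk, disc, ali$labels, config$params))

  evaluations <- list()
  for (m in config$methods)
    evaluations[[m]] <- pipeline_stage(paste0("evaluate:", m),
      evaluate_selection(xk, disc, ali$labels, selections[[m]]$selected,
                         classifiers = config$classifiers,
                         folds = config$folds, repeats = config$repeats,
                         seed = config$seed, tuning = config$tuning,
                         adaboost_rounds = config$adaboost_rounds))

  sigs <- if (length(selections) >= 2)
    pipeline_stage("signatures", intersect_signatures(selections)) else NULL

  provenance <- list(
    source = dat$source, n_samples = ncol(xk),
    n_features_input = nrow(dat$matrix), n_features_kept = length(kept),
    alpha = config$alpha, d0 = config$d0, k = config$params$k,
    beta = config$params$beta, w = config$params$w,
    dfs_p = config$params$dfs_p, dfs_reg = config$params$dfs_reg,
    cbr_tau = config$params$cbr_tau, svm_cost = config$params$svm_cost,
    methods = config$methods, classifiers = config$classifiers,
    folds = config$folds, repeats = config$repeats, seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  report <- structure(list(selections = selections,
                           evaluations = evaluations,
                           signatures = sigs, filter = filt,
                           truth = dat$truth, provenance = provenance),
                      class = "omicfs_report")
  if (!is.null(config$out_dir))
    pipeline_stage("write", write_report(report, xk, disc, config$out_dir))
  report
}

#' Write all pipeline artifacts to a directory
#'
#' @param report an `omicfs_report`.
#' @param x_norm,x_disc the normalized and discretized matrices (written
#'   alongside; pass `NULL` to skip).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, x_norm = NULL, x_disc = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(x_norm)) write_omics_matrix(x_norm,
                                           file.path(dir, "normalized.tsv"))
  if (!is.null(x_disc))
    utils::write.table(
      data.frame(feature_id = rownames(x_disc), unclass(x_disc),
                 check.names = FALSE),
      file.path(dir, "discretized.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  write_differential_result(report$filter, file.path(dir, "filter.tsv"))
  for (m in names(report$selections))
    write_selection_result(report$selections[[m]],
                           file.path(dir, sprintf("selection_%s.tsv", m)))
  if (!is.null(report$signatures))
    write_signature_set(report$signatures, file.path(dir, "signatures.tsv"))
  jsonlite::write_json(report_as_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# JSON-ready summary of a report
report_as_list <- function(report) {
  evals <- lapply(report$evaluations, function(e) {
    list(accuracy = lapply(e$accuracy, function(a)
      list(mean_pct = a$mean_pct, std_pct = a$std_pct,
           tuned_parameter = a$tuned_parameter)),
      rr_nmi = e$rr_nmi, rr_pearson = e$rr_pearson, re = e$re)
  })
  list(provenance = report$provenance,
       selected = lapply(report$selections, function(s) s$selected),
       evaluations = evals,
       signature_core = if (!is.null(report$signatures))
         report$signatures$core else NULL)
}

#' @export
print.omicfs_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("omicfs_report: %s | %d samples, %d/%d features kept (alpha = %g)\n",
              p$source, p$n_samples, p$n_features_kept, p$n_features_input,
              p$alpha))
  cat(sprintf("  methods: %s (k = %d); classifiers: %s; CV %dx%d, seed %d\n",
              paste(p$methods, collapse = ", "), p$k,
              paste(p$classifiers, collapse = ", "), p$repeats, p$folds,
              p$seed))
  for (m in names(x$evaluations)) {
    e <- x$evaluations[[m]]
    accs <- vapply(e$accuracy, function(a)
      sprintf("%s %.2f(%.2f)", a$classifier, a$mean_pct, a$std_pct),
      character(1))
    cat(sprintf("  %-12s %s | RRnmi %.4f RRpc %.4f RE %.4f\n", m,
                paste(accs, collapse = " "), e$rr_nmi, e$rr_pearson, e$re))
  }
  if (!is.null(x$signatures))
    cat(sprintf("  signature core: %d feature(s)%s\n",
                length(x$signatures$core),
                if (length(x$signatures$core) &&
                    length(x$signatures$core) <= 12)
                  paste0(" [", paste(x$signatures$core, collapse = ", "), "]")
                else ""))
  invisible(x)
}

#' @export
summary.omicfs_report <- function(object, ...) {
  rows <- list()
  for (m in names(object$evaluations)) {
    e <- object$evaluations[[m]]
    for (a in e$accuracy)
      rows[[length(rows) + 1]] <- data.frame(
        method = m, classifier = a$classifier, mean_pct = a$mean_pct,
        std_pct = a$std_pct, rr_nmi = e$rr_nmi, rr_pearson = e$rr_pearson,
        re = e$re, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
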