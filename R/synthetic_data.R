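# ---------------------------------------------------------------------------
# Seeded synthetic multi-omics generator.  Emulates the shape of a single
# omics profile: a few hundred to a thousand continuous features over ~161
# samples in three imbalanced classes, of which a minority carry class
# signal, some are noisy copies of informative parents, and the rest are
# class-independent noise.  The planted partition is returned as ground
# truth so selector recovery can be scored exactly.
# ---------------------------------------------------------------------------

#' Specification for a synthetic multi-omics dataset
#'
#' Defaults mirror the shape of a TCGA LAML omics profile: 161 samples in
#' three prognosis classes of 31/96/34, around a thousand features of which
#' a minority are informative.
#'
#' @param class_sizes integer vector of per-class sample counts (default
#'   `c(31, 96, 34)`); `n_samples` is their sum.
#' @param class_names names for the classes.
#' @param n_informative features whose class means differ (default 50).
#' @param n_redundant noisy copies of informative parents (default 50).
#' @param n_noise class-independent features (default 900).
#' @param effect_size class-mean shift in within-class-sigma units
#'   (default 1).
#' @param redundancy_r target Pearson correlation of each redundant copy
#'   with its parent, in [0, 1).
#' @param noise `"gaussian"` or `"t"`; heavy-tailed noise (Student t,
#'   `t_df` degrees of freedom) stresses the discretization.
#' @param t_df degrees of freedom for `noise = "t"` (default 3).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(class_sizes = c(31L, 96L, 34L),
                           class_names = paste0("class", seq_along(class_sizes)),
                           n_informative = 50L, n_redundant = 50L,
                           n_noise = 900L, effect_size = 1.0,
                           redundancy_r = 0.9,
                           noise = c("gaussian", "t"), t_df = 3,
                           seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(length(class_sizes) >= 2, all(class_sizes >= 1),
            length(class_names) == length(class_sizes),
            n_informative >= 0, n_redundant >= 0, n_noise >= 0,
            redundancy_r >= 0, redundancy_r < 1, effect_size >= 0)
  if (n_redundant > 0 && n_informative == 0)
    stop("redundant features need informative parents")
  structure(list(class_sizes = as.integer(class_sizes),
                 class_names = as.character(class_names),
                 n_samples = sum(as.integer(class_sizes)),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 effect_size = effect_size, redundancy_r = redundancy_r,
                 noise = noise, t_df = t_df, seed = as.integer(seed)),
            class = "synthetic_spec")
}

rnoise <- function(n, spec) {
  if (spec$noise == "gaussian") stats::rnorm(n)
  else stats::rt(n, df = spec$t_df) / sqrt(spec$t_df / (spec$t_df - 2))
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Informative features are Gaussian with per-class mean shifts: each
#' informative feature gets the class-mean pattern
#' `effect_size * (a random permutation of K equally spaced values in
#' [-1, 1])` over unit within-class noise.  Redundant features are
#' standardized copies of a cyclically-assigned informative parent mixed
#' with fresh noise so the parent-copy correlation is `redundancy_r` in
#' expectation.  Noise features are class-independent.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `matrix` (an [omics_matrix()]), `labels`
#'   ([class_labels()]) and `truth` (class `"ground_truth"`:
#'   `informative_ids`, `redundant_ids`, `parent_of` named map,
#'   `noise_ids`).
#' @examples
#' d <- generate_synthetic(synthetic_spec(n_informative = 5, n_redundant = 2,
#'                                        n_noise = 10, seed = 7))
#' dim(d$matrix)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    K <- length(spec$class_sizes)
    n <- spec$n_samples
    y <- rep(spec$class_names, spec$class_sizes)
    sample_ids <- sprintf("s%03d", seq_len(n))
    pattern_base <- seq(-1, 1, length.out = K)

    inf_ids <- if (spec$n_informative > 0)
      sprintf("inf%04d", seq_len(spec$n_informative)) else character(0)
    red_ids <- if (spec$n_redundant > 0)
      sprintf("red%04d", seq_len(spec$n_redundant)) else character(0)
    noise_ids <- if (spec$n_noise > 0)
      sprintf("noise%04d", seq_len(spec$n_noise)) else character(0)

    rows <- list()
    for (j in seq_len(spec$n_informative)) {
      mu <- spec$effect_size * sample(pattern_base)
      rows[[inf_ids[j]]] <- mu[match(y, spec$class_names)] + rnoise(n, spec)
    }
    parent_of <- character(0)
    r <- spec$redundancy_r
    for (j in seq_len(spec$n_redundant)) {
      p <- inf_ids[(j - 1L) %% spec$n_informative + 1L]
      parent_of[red_ids[j]] <- p
      pz <- as.numeric(scale(rows[[p]]))
      rows[[red_ids[j]]] <- r * pz + sqrt(1 - r^2) * rnoise(n, spec)
    }
    for (j in seq_len(spec$n_noise))
      rows[[noise_ids[j]]] <- rnoise(n, spec)

    values <- do.call(rbind, rows)
    colnames(values) <- sample_ids
    truth <- structure(list(informative_ids = inf_ids,
                            redundant_ids = red_ids,
                            parent_of = parent_of,
                            noise_ids = noise_ids),
                       class = "ground_truth")
    list(matrix = omics_matrix(values),
         labels = class_labels(y, sample_ids = sample_ids),
         truth = truth)
  })
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %d samples (%s), %d informative + %d redundant + %d noise, effect %.2f sigma, r = %.2f, %s noise, seed %d\n",
    x$n_samples, paste(x$class_sizes, collapse = "/"), x$n_informative,
    x$n_redundant, x$n_noise, x$effect_size, x$redundancy_r, x$noise,
    x$seed))
  invisible(x)
}

#' Write a synthetic dataset (matrix, labels, ground truth) as TSV files
#'
#' @param data result of [generate_synthetic()].
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_matrix(data$matrix, file.path(dir, "matrix.tsv"))
  write_class_labels(data$labels, file.path(dir, "labels.tsv"))
  tr <- data$truth
  df <- data.frame(
    feature_id = c(tr$informative_ids, tr$redundant_ids, tr$noise_ids),
    role = c(rep("informative", length(tr$informative_ids)),
             rep("redundant", length(tr$redundant_ids)),
             rep("noise", length(tr$noise_ids))),
    parent = c(rep(NA, length(tr$informative_ids)),
               unname(tr$parent_of[tr$redundant_ids]),
               rep(NA, length(tr$noise_ids))),
    stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Count recovered informative features in a selection
#'
#' A selected redundant copy credits its parent; each planted informative
#' feature is counted at most once.
#'
#' @param selected character vector of selected feature ids (e.g. the top
#'   slice of an `fs_result$selected`).
#' @param truth a `ground_truth` object.
#' @return Integer count of distinct informative features recovered.
#' @export
count_recovered <- function(selected, truth) {
  hits <- selected
  is_red <- hits %in% truth$redundant_ids
  hits[is_red] <- truth$parent_of[hits[is_red]]
  length(intersect(unique(hits), truth$informative_ids))
}
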