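---
title: "Benchmarking supervised feature selection on multi-omics profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking supervised feature selection on multi-omics profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicfs)
```

## The problem

An omics profile is a continuous feature × sample matrix — expression
levels, methylation scores, copy-number estimates, pathway activities —
with a categorical clinical label per sample, typically a few imbalanced
classes over one or two hundred samples and hundreds to thousands of
features. Only a minority of features carry class signal, and informative
features often come in correlated groups (probes on the same gene, genes in
the same pathway). A useful selected subset must therefore be small,
predictive, *and* internally non-redundant. `omicfs` implements a family of
selectors that trade these goals off differently, and a shared evaluation
harness so their outputs can be compared rather than trusted individually.

## Preprocessing

**Normalization.** Each feature row is z-scored: $x^{norm} = (x - \mu)/\sigma$
with $\mu,\sigma$ over all samples of that feature. We use the population
convention (divisor $n$) by default; `population = FALSE` switches to
$n-1$. The two differ by a constant per-feature factor and do not change
any downstream ranking; the convention is exposed because the discretization
boundary sits exactly at $\pm\sigma$. Constant features are undefined under
this map and are dropped by the pipeline with a warning before
normalization.

**Differential screen.** Features are screened by a per-feature one-way
ANOVA F test across the classes; those with $p < \alpha$ (default 0.05,
no multiple-testing correction — the screen is a pre-filter, not an
inferential endpoint) proceed. An optional moderated variant shrinks the
per-feature within-class variances toward a common prior with weight `d0`
(the empirical-Bayes style used for small-sample expression studies;
`d0 = 0`, plain ANOVA, is the default). The moderated statistic follows the
standard form $s^2_{post} = (d_0 \bar{s}^2 + d_2 s^2)/(d_0 + d_2)$ with
$F = MS_B / s^2_{post}$ on $(K-1,\, d_2 + d_0)$ degrees of freedom; the test
suite verifies it reproduces limma's moderated F exactly when given limma's
fitted prior.

**Discretization.** For mutual-information estimation each feature is
mapped to three states: values below $\mu - \sigma$ become $-1$, above
$\mu + \sigma$ become $+1$, else $0$. On z-scored input the cut points are
$\pm 1$. We read the three-state rule as symmetric about the mean — the only
reading that populates all three states after z-scoring — and map exact
boundary values to 0 (strict inequalities). Under Gaussian data this puts
roughly 16/68/16% of samples in the three states, so all three are well
populated at $n \approx 161$.

## Information theory

Entropy, joint entropy, mutual information (MI) and normalized MI are
plug-in (maximum-likelihood) estimates on the discretized states, with no
smoothing or bias correction: at $n \sim 161$ samples and at most 3×3
contingency tables, plug-in bias is small relative to the criterion gaps
that drive selection. **All logarithms are base 2.** The choice is forced by
the representation-entropy scale: RE values reported for 50-feature subsets
on real profiles reach ≈ 4.8–4.9, which exceeds the natural-log ceiling
$\ln 50 \approx 3.91$ but respects $\log_2 50 \approx 5.64$; MI uses the
same base for internal consistency. Normalized MI is
$\hat{I}(x;y) = I(x;y)/\min(H(x), H(y)) \in [0,1]$, with the $0/0$ case
(either variable constant) defined as 0: a constant feature carries no
information.

## The selection criteria

Six greedy forward criteria share the shape *relevance − redundancy*; each
step adds the remaining feature maximizing the criterion (see the README
table for the formulas). Design points:

* **Relevance normalization.** mRMR and NMIFS use raw $I(f;C)$ relevance;
  INMIFS and VWMRmR normalize both terms. Where a criterion mixes raw and
  normalized terms that is deliberate — it is the imbalance INMIFS was
  designed to fix.
* **Defaults.** $\beta = 0.5$ for MIFS/MIFS-U (mid-range of published
  usage; these two are baselines, not compared methods). $w = 1$ for
  VWMRmR: the parameter is user-specified by design, so it is exposed in
  every configuration surface and logged in every report; $w = 0$ recovers
  INMIFS exactly (a tested identity). $k = 50$ selected features.
* **Ties.** Scores equal up to $10^{-9}$ are treated as tied and break to
  the lowest original feature index, making selection fully deterministic
  and reproducible across platforms.
* **Caching.** Pairwise MI/NMI against selected features is computed once
  per selected feature and reused; tests assert cache values equal direct
  recomputation.

**DFS** (discriminative feature selection) is not greedy: it scores all
features at once by fitting a row-sparse LDA projection, minimizing
$\mathrm{tr}(W^\top (S_w + \varepsilon I) W) + \lambda \sum_i (\|w_i\|^2 +
\varepsilon)^{p/2}$ subject to $W^\top S_b W = I$, by alternating a
generalized eigenproblem (reweighting matrix fixed) with the IRLS update
$d_i = (p/2)\|w_i\|^{p-2}$. Because the eigen step globally minimizes the
majorizing surrogate under a constraint set independent of the weights, the
objective is non-increasing for $0 < p \le 2$ (asserted on every test run).
Features are ranked by projection-row norm. Defaults: $p = 1$ (the l2,1
row-sparsity case that defines the method; $p = 2$ gives ridge-LDA with no
iteration), $\lambda = 1$, ridge guard $\varepsilon = 10^{-8}$ (within-class
scatter is singular whenever features outnumber samples), relative tolerance
$10^{-6}$, 200 iterations max with a warning flag on non-convergence. The
simultaneous ranking is what lets the sparsity penalty suppress redundant
copies: a duplicated informative feature measurably shrinks the original's
row norm (tested).

**SVM-RFE-CBR.** Backward elimination by linear-SVM weights: train
one-vs-rest linear SVMs (hinge loss, C = 1 — the package's SVM
configuration) on the surviving features, score feature $i$ by
$c_i = \sum_{\text{models}} w_i^2$, and eliminate the lowest-scoring batch
(default: 10% of survivors, ceiling). Features are standardized within each
training call so weight magnitudes stay comparable. The correlation-bias
problem: members of a highly correlated group split their weight, each
looks individually weak, and whole informative groups get flushed early.
Our concrete correction — this package's own instantiation of the
qualitative idea — defers a marked feature whenever its absolute Pearson
correlation with any *unmarked* survivor is at least `cbr_tau`
(default 0.85), unless deferral would empty the batch, in which case only
the single weakest marked feature is eliminated. With `cbr_tau = 1` the rule
never fires and the procedure is textbook SVM-RFE (a tested regression
identity). The final ranking lists survivors by final score, then the
eliminated features in reverse elimination order; the full per-iteration
audit trail (survivors, scores, eliminated, deferred) is retained.

## Evaluation criteria

**Accuracy.** Stratified $k$-fold CV (default 10 folds, class proportions
preserved to within one sample per fold) repeated 10 times; accuracy is the
plain multiclass fraction of correct predictions in percent, and the
reported mean/sd are over all repeats × folds fold-level accuracies.
Everything is derived from one integer seed, and identical seeds give
bit-identical estimates (tested). Classifiers:

* *decision tree* — `rpart` with entropy (information) splits; its
  pruning-strength parameter can be tuned over the grid 0.05–0.5 in steps
  of 0.05 (a C4.5-style confidence-like control; exact Weka C4.5 behavior
  is not a goal);
* *Gaussian naive Bayes* — class-conditional normal densities
  (`e1071::naiveBayes`);
* *KNN* — K defaults to the rounded square root of the training-set size,
  tunable over 1–15 step 1;
* *AdaBoost* — multiclass SAMME boosting of depth-1 `rpart` stumps,
  50 rounds by default (10 rounds, the Weka default, is a reasonable
  faster preset).

When a tuning grid is supplied the whole CV is run per grid value and the
best mean is reported together with the winning value — the "best tuned
score" protocol.

**Redundancy rate** averages pairwise similarity over all $\binom{d}{2}$
pairs of the subset. The NMI variant runs on the discretized rows (NMI is a
discrete-variable measure); the Pearson variant on the continuous z-scored
rows, using $|r|$ — with signed $r$, anticorrelated pairs (which are just as
redundant) would cancel and RR could leave $[0,1]$.

**Representation entropy** eigendecomposes the $d \times d$ covariance of
the subset (continuous z-scored rows), normalizes the eigenvalues to sum
to one and takes Shannon entropy in bits: 0 when one direction carries all
variance, $\log_2 d$ when variance is spread evenly. Tiny negative
eigenvalues from finite-precision symmetric eigendecomposition are clamped
at zero. Covariance mode is the default and is scale-sensitive (the input
is z-scored, which largely neutralizes this); correlation mode is available
and is invariant to per-feature scaling.

**Signatures.** The signature is the strict all-methods intersection of the
top-$k$ lists; all $2^m - 1$ Venn-region counts are computed for the
overlap structure, and a majority-vote set is reported as a secondary,
looser consensus (off the signature path by default).

## The synthetic generator

`synthetic_spec()` / `generate_synthetic()` emulate the shape of a single
real omics profile: 161 samples in three imbalanced classes (31/96/34 by
default), with three planted feature roles. *Informative* features get a
per-class mean pattern — a random permutation of $K$ equally spaced values
in $[-1, 1]$ scaled by `effect_size` (in within-class-σ units) — over unit
Gaussian noise. *Redundant* features are standardized copies of a
cyclically assigned informative parent mixed with fresh noise to hit a
target parent–copy correlation (`redundancy_r`, default 0.9) in
expectation. *Noise* features are class-independent; a Student-t option
(df = 3, variance-standardized) stresses the discretization with heavy
tails. Defaults plant 50 informative + 50 redundant among 900 noise
features (≈1000 total, the realistic scale for a filtered profile) at
effect 1.0σ. Everything is bit-reproducible from the seed.

What the generator does *not* emulate: bounded methylation beta-value
distributions, segmented copy-number structure, count-like skew,
batch effects, or missingness. Passing recovery tests on this generator
therefore demonstrates correct mechanics of the selectors (relevance
detection, redundancy avoidance, planted-signal recovery), not performance
on any real cohort.

One behavioral note uncovered by the recovery tests: with only three
classes, informative features sharing a class-mean pattern become strongly
correlated as the effect size grows (two same-pattern features at 3σ
correlate ≈ 0.87). Redundancy-penalizing criteria — VWMRmR especially, whose
penalty ramps up as the subset fills — will then legitimately trade a
near-duplicate informative feature for an uncorrelated noise feature. This
is the criterion doing its job, and it is why recovery fixtures that expect
*every* method to return the planted set exactly are built at moderate
effect sizes where planted features are not near-duplicates of each other.

## Pipeline and numerical choices

The driver runs: align (samples sorted lexicographically, for seeded-CV
reproducibility) → drop constants → z-score → differential screen →
discretize → selectors (MI family on the discretized matrix; DFS and
SVM-RFE-CBR on the continuous one) → evaluation (RR-NMI on discretized,
RR-Pearson/RE/classifiers on continuous) → signature intersection. Any
stage error halts the run with the stage name; no partial silent results.
Reports carry full parameter provenance (α, k, β, w, DFS and CBR settings,
seeds, fold geometry).

Degenerate inputs are handled explicitly: missing values are a hard load
error (no imputation anywhere); constant features are dropped before
normalization and contribute NMI 0 by the 0/0 convention; a class with
fewer than two samples fails the screen; perfect separation yields
$F = \infty$, $p = 0$; MI is clamped at 0 against $-10^{-12}$ rounding;
all-zero covariance is an error for RE.

Test problem sizes are deliberately small-but-representative: oracle
equivalence runs 10⁴ random vectors (information theory) and 200 random
instances at $d \le 10$ (greedy selection, against an exhaustive per-step
argmax oracle); recovery runs the full 161-sample, 424-feature benchmark
shape; the end-to-end fixtures use a few hundred features so the whole
suite completes in a couple of minutes.

## Known limitations

* MI estimation is plug-in on three states; continuous (k-NN/kernel) MI
  estimators are out of scope.
* The SVM uses standard hinge loss; squared-hinge variants of RFE will
  rank near-margin features slightly differently.
* The decision tree is an entropy/cp approximation of C4.5, not a
  gain-ratio/pessimistic-pruning clone; AdaBoost is SAMME, not Weka's
  AdaBoostM1 resampling variant.
* Covariance-mode RE is scale-sensitive by construction; use correlation
  mode if inputs are not z-scored.
* The CBR deferral rule is this package's concrete instantiation of a
  qualitatively described idea; its batch/threshold defaults
  (`cbr_tau = 0.85`, 10% steps) are exposed rather than canonical.
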