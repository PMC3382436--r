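---
title: "Set-level classification of gene expression samples: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-level classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In predictive classification of gene expression data, each sample is usually
represented by the expressions of all interrogated genes and a learner (an
SVM, k-NN, naive Bayes, a decision tree) separates the two phenotype classes
in that very high-dimensional space. The *set-level* alternative replaces the
per-gene features by a handful of features derived from a priori-defined gene
sets — pathways, curated signatures, ontology terms. Each set contributes a
single per-sample value that aggregates its member genes' expressions, so the
learned classifier reads as statements about biological processes rather than
individual probes. `setlevel` implements the full set-level learning
workflow — gene-set ranking, rank-based selection, expression aggregation,
classifier learning — together with the factorial evaluation harness,
statistical comparison machinery, randomized control collections, and a
synthetic benchmark generator that makes every stage testable without any
external data.

The core entry point is the classic modelling idiom: `setlevel()` fits a
classifier on a training `expression_dataset` plus a `gene_set_collection`
and returns an object with `print()`, `summary()` and `predict()` methods;
`run_workflow()` wraps it in stratified 10-fold cross-validation, and
`run_factorial()` sweeps factor grids.

## Gene-set ranking statistics

All three dedicated statistics consume a genes-by-samples matrix of
normalized expressions with binary labels (class 0 is always the
lexicographically smaller class string) and share one phenotype-permutation
engine: class labels are permuted as whole vectors (class sizes preserved),
the statistic is recomputed per permutation, and the add-one empirical
p-value $(b+1)/(B+1)$ is reported, which can never be zero. One permutation
draw is shared across all sets of a collection, as is standard, so that
set-to-set comparisons see the same null labelings; `permutation_pvalue()`
also offers exact enumeration of all balanced labelings for small samples.

**GSEA.** Genes are sorted by descending signal-to-noise ratio
$(\bar e_0 - \bar e_1)/(s_0 + s_1)$ (standard deviations with denominator
$n-1$; zero-variance genes receive $0$ or a $\pm 10^6$ cap depending on
whether the class means agree). Walking the sorted list, member genes add
$|s|^w / N_R$ (with $N_R$ the sum of $|s|^w$ over members) and non-members
subtract $1/(p - N_H)$; the enrichment score is the signed maximum deviation
of this running sum and lies in $[-1, 1]$. The weight exponent defaults to
$w = 1$ (the weighted variant); $w$ is exposed because the unweighted
$w = 0$ form is equally defensible. The implementation evaluates the walk in
closed form at hit-adjacent positions only (between hits the walk is
linear), which is algebraically identical to the literal step-by-step walk —
the test suite asserts exact agreement with a brute-force walk oracle — and
makes collection-scale permutation testing cheap. Because the statistic is
signed, permutation extremity is judged on $|ES|$.

**SAM-GS.** The Euclidean distance between the two class centroids in the
subspace spanned by the set's effective genes. This is the literal
centroid-distance form; the moderated sum-of-squares variant with a
variance-stabilizing fudge factor found elsewhere in the literature is a
possible extension, not what this package computes. The statistic is
nonnegative and scales linearly with the data.

**Global test.** The score-statistic form of the random-effects regression
test: with the effective-set submatrix standardized per gene (zero-variance
genes dropped) into the $N \times m$ matrix $X$ and centered labels
$z = y - \bar y$, $Q = z^\top X X^\top z / m$. We deliberately attach
permutation rather than asymptotic p-values so that all three methods share
one null machinery and differences between them reflect the statistics, not
the null approximations.

Ranking sorts by (p ascending, $|$statistic$|$ descending, set name
ascending) — fully deterministic, and the magnitude tie-break matters in
practice because permutation p-values are discrete at resolution $1/(B+1)$.
Sets with empty effective sets are dropped with a warning; for GSEA a set
covering *all* measured genes is likewise unusable (no misses to walk).
Ranking always happens inside the cross-validation loop, on the training
fold only; ranking once on the full dataset would leak test information and
is not offered.

## Aggregation

`fit_aggregation()` learns per-set state on training samples only and
applies it unchanged to any sample:

* **AVG** — the arithmetic mean over the effective genes; stateless apart
  from the gene list.
* **SVD** — samples are centered with *training* per-gene means and
  projected onto the first right-singular direction of the centered training
  submatrix. The direction is normalized and its sign fixed so the
  largest-magnitude loading is positive, making results reproducible across
  linear-algebra back-ends. Training projections are mean-zero and have
  variance equal to the leading covariance eigenvalue (both asserted in
  tests).
* **SetSig** — the sample's Pearson correlations with each training sample
  over the set's genes are split by training class, and the pooled-variance
  Student t statistic contrasts the two correlation populations (positive =
  correlates rather with class 0). Two toggles are genuinely open in the
  literature, so both are exposed: pooled vs Welch variance (we default to
  the pooled Student form, matching the technique's usual statement) and
  self-exclusion. Self-exclusion defaults to on: when a training sample is
  evaluated against a model containing itself, its self-correlation of 1
  would bias its own class's population, so that reference is dropped
  (matched by sample identifier). A zero pooled variance yields 0 under
  equal means and $\pm 10^6$ otherwise; a zero-variance sample vector is an
  error, since its correlations are undefined.
* **NONE** — no aggregation: the deduplicated union of the selected sets'
  effective genes, each gene passed through as its own feature (the control
  case for measuring what aggregation itself costs).

SetSig needs effective sets of at least 3 genes and at least 2 references
per class after exclusion; SVD needs at least 2 training samples.

## Generic selection and learners

Information gain uses the single best binary split, with thresholds at
midpoints of consecutive distinct sorted values and base-2 entropy — the
simplest scheme consistent with the usual one-line description of the
heuristic; multi-interval MDL discretization was deliberately not adopted.
SVM-RFE trains a linear soft-margin SVM ($C = 1$) on standardized surviving
features and repeatedly removes the smallest-$|w|$ features; the chunked
schedule removes $\max(1, \lfloor F \cdot 2^{-i} \rfloor)$ features at
iteration $i$, accepting the known caveat that chunking may degrade the
ranking slightly. Ties on $|w|$ break by feature index. When these generic
scorers rank *sets*, aggregation must come first, since they score a feature
by its single per-sample value; `rank_sets_generic()` enforces this
ordering.

The five learners are thin wrappers over established implementations:
`e1071::svm` (linear kernel, $C = 1$, features standardized with training
statistics), `class::knn` (1-NN and 3-NN, Euclidean metric, raw features),
`e1071::naiveBayes` (Gaussian, raw features) and `rpart` (CART-style pruned
tree at its defaults). Bit-compatibility with any particular Java/WEKA
implementation is explicitly not attempted — the harness's conclusions are
relative comparisons under a fixed learner, which such implementation
differences do not disturb. k-NN distance ties are broken by the library;
with continuous features they have probability zero.

## The evaluation harness

`stratified_folds()` deals each class's shuffled samples round-robin (the
second class's deal rotated for overall balance), so every fold's class
count is within one sample of an even split; folds depend only on (seed,
dataset id), never on the configuration, which is what makes records
fold-matched for paired comparisons. `run_workflow()` executes
rank-select-aggregate-learn-test per fold; `run_baseline()` runs the
gene-level comparator (all genes, or the top-k genes by IG/SVM-RFE selected
per training fold; k = 22 and k = 228 are offered as the presets matching
the typical unique-gene content of one-set and ten-set representations).
`run_factorial()` shares each fold's ranking across every configuration
downstream of it and derives all sub-seeds deterministically from one master
seed, so a rerun reproduces every accuracy exactly.

Comparisons use the paired Wilcoxon signed-rank test on fold-averaged
accuracies of records matched on all factors but the tested one. Zero
differences are dropped (one documented convention among several); the
exact distribution is used up to 25 zero-free pairs without ties in
$|d|$, the continuity-corrected normal approximation otherwise. Families of
pairwise tests are adjusted by Bonferroni-Dunn, $p_{adj} = \min(1, p m)$.
`median_ranking_table()` pools fold-averaged accuracies across datasets and
learners (quantiles by linear interpolation, IQR $= Q_3 - Q_1$);
`subrank_table()` instead ranks combinations within each (dataset, learner)
cell — average rank on ties — and averages the cell ranks, avoiding pooled
accuracy mixtures. In a complete design the grand mean of average sub-ranks
is $(n_{combos}+1)/2$, a conservation law the tests assert.
`gene_set_group_stats()` reports, per group of sets, nominal size, effective
size (members actually measured) and the number of principal components
capturing 50% and 90% of the set's expression variance, with Mann-Whitney U
tests between groups; its Bonferroni family size is stated in the output
(pairs × metrics) rather than guessed.

Randomized control collections are built by sampling, for each genuine set,
the same number of genes without replacement and uniformly from the pooled
gene universe of the genuine collection. Draws are independent across sets:
a gene may recur in several random sets, exactly as it may in the genuine
collection; degree-preserving randomization is out of scope.

## The synthetic benchmark

`generate_synthetic()` draws member genes of each set from a shared latent
factor, $x = \sqrt{\rho}\, z_{set} + \sqrt{1-\rho}\,\varepsilon$, scaled by
$\sigma$ — chosen over arbitrary covariances because the equicorrelation is
exact and checkable in closed form — and adds a mean shift $\delta$ to
class-1 samples on the member genes of the designated signal sets. Genes
outside every set are i.i.d. $N(0, \sigma^2)$. The defaults are the
package's benchmark study conditions, fixed once: 30 + 30 samples, 100 sets
of 10-20 genes (disjoint blocks plus 100 background genes), 3 signal sets,
$\delta = 1.5$ expression units, $\rho = 0.3$, $\sigma = 1$. These were
chosen to represent a moderately easy two-class expression problem: per-gene
effect $\delta/\sigma = 1.5$ is realistic for strongly differential genes,
$\rho = 0.3$ is a typical within-pathway co-expression level, and 3 signal
sets among 100 keep ranking non-trivial. A variance-shift signal option
exists but no validation suite uses it.

What the simulator deliberately does *not* emulate: probe effects, batch
effects, heavy-tailed noise, set overlap (off by default), and
between-class covariance changes. Passing validation on this generator
therefore demonstrates correctness of the machinery and the expected
qualitative ordering of methods under clean planted signal — not performance
claims about any real microarray compendium.

## Validation problem sizes

The package validates itself at desk scale, with sizes fixed as part of the
design: type-I calibration uses 500 null sets (5-15 genes, 20 + 20 samples)
at $B = 199$ and requires each method's p-values to sit within
Kolmogorov-Smirnov distance 0.08 of uniform; parameter recovery plants one
20-gene set ($\delta = 1$, $\rho = 0.3$) among 200 size-matched decoys with
30 + 30 samples and requires the global test to rank it first in at least
90% of 50 replicates; the directional benchmark runs five default-condition
datasets through the cross-validated workflow (global-test ranking, SVD
aggregation, three learners) and requires top-ranked sets to beat
bottom-ranked sets and genuine collections to beat randomized ones, each by
a one-sided paired Wilcoxon test at $p < 0.05$, with a negative
least-squares slope of accuracy against rank position. The same
computations, from scratch, constitute `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Permutation p-values use add-one smoothing; $B$ defaults to 999 for
  standalone ranking and 199 inside the workflow (ranks stabilize much
  faster than p-values; the override is a parameter).
* Zero-variance genes: capped scores in the signal-to-noise ratio, dropped
  inside global-test standardization, zero weight in SVM-RFE after
  standardization (constant columns map to zero).
* All caps default to $10^6$ and are arguments, not constants.
* Missing expression values are an error — the framework assumes complete,
  already-normalized matrices, and no normalization is performed.
* Expression matrices are genes-in-rows; the reader rejects rather than
  guesses orientation. Class strings map to 0/1 lexicographically, which
  fixes the SetSig sign convention across runs.
* The GMT description field is carried through reads and writes but never
  used in computation.

## Limitations

Binary phenotypes only (SetSig is defined for two classes; the harness
follows suit). No hyperparameter tuning, no internal cross-validation for
choosing the number of feature sets, no multiple-testing machinery across
sets inside the ranking step (the workflow consumes ranks, not significance
calls), and no pathway-topology-weighted aggregation — member genes enter
each aggregate unweighted.
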