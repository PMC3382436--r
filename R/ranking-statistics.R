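#' Per-gene signal-to-noise association scores
#'
#' For every gene, the signal-to-noise ratio between the two phenotype
#' classes, (mean0 - mean1) / (sd0 + sd1), with standard deviations computed
#' with denominator n-1. This is the gene-level association measure used to
#' sort the gene list before computing GSEA enrichment scores. When both
#' class standard deviations are zero the score is 0 if the class means are
#' equal and +/-cap otherwise.
#'
#' @param dataset an \code{\link{expression_dataset}}; both classes must have
#'   at least 2 samples.
#' @param cap magnitude assigned to zero-variance genes with unequal class
#'   means (default 1e6).
#' @return Named numeric vector of per-gene scores, in dataset gene order.
#' @export
gene_level_snr <- function(dataset, cap = 1e6) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (min(table(dataset$labels)) < 2L)
    stop("each class needs at least 2 samples for signal-to-noise scores")
  s <- snr_columns(dataset$values, matrix(dataset$labels, ncol = 1L), cap)[, 1L]
  names(s) <- dataset$genes
  s
}

# Vectorized SNR over several label columns. values: p x N; labmat: N x B of
# 0/1 labels (class sizes identical across columns by construction).
snr_columns <- function(values, labmat, cap = 1e6) {
  n0 <- sum(labmat[, 1L] == 0L)
  n1 <- nrow(labmat) - n0
  A0 <- (labmat == 0L) * 1
  A1 <- 1 - A0
  S0 <- values %*% A0; S1 <- values %*% A1
  M0 <- S0 / n0;       M1 <- S1 / n1
  Q0 <- (values^2) %*% A0
  Q1 <- (values^2) %*% A1
  v0 <- (Q0 - n0 * M0^2) / (n0 - 1)
  v1 <- (Q1 - n1 * M1^2) / (n1 - 1)
  den <- sqrt(pmax(v0, 0)) + sqrt(pmax(v1, 0))
  num <- M0 - M1
  out <- num / den
  zero <- den == 0
  if (any(zero)) out[zero] <- ifelse(num[zero] == 0, 0, sign(num[zero]) * cap)
  out
}

# Enrichment score from hit positions in the phenotype-sorted gene list.
# Closed form of the running-sum walk: within each inter-hit segment the walk
# is linear, so its extremes sit just after a hit (maximum candidates) or just
# before the next hit (minimum candidates). Ties on |deviation| resolve to the
# extreme reached first along the walk, matching a literal step-by-step scan.
# sorted_abs_w: |score|^w of all p genes in sorted order; hpos: sorted hit
# positions.
es_from_positions <- function(sorted_abs_w, hpos, p) {
  nh <- length(hpos)
  if (nh == 0L) stop("empty effective set")
  if (nh == p) stop("effective set covers all genes; miss decrement undefined")
  wts <- sorted_abs_w[hpos]
  nr <- sum(wts)
  wts <- if (nr == 0) rep.int(1 / nh, nh) else wts / nr
  miss <- 1 / (p - nh)
  r_after <- cumsum(wts) - (hpos - seq_len(nh)) * miss
  r_before <- r_after - wts
  i_max <- which.max(r_after)
  i_min <- which.min(r_before)
  pos_max <- hpos[i_max]
  pos_min <- hpos[i_min] - 1L
  if (abs(r_after[i_max]) > abs(r_before[i_min])) return(r_after[i_max])
  if (abs(r_after[i_max]) < abs(r_before[i_min])) return(r_before[i_min])
  if (pos_max <= pos_min) r_after[i_max] else r_before[i_min]
}

# ES of every set (list of gene row-index vectors) for one score vector.
es_for_scores <- function(scores, set_indices, weight_exponent) {
  p <- length(scores)
  o <- order(-scores, seq_len(p))
  pos <- integer(p); pos[o] <- seq_len(p)
  saw <- abs(scores[o])^weight_exponent
  vapply(set_indices, function(idx) {
    es_from_positions(saw, sort.int(pos[idx]), p)
  }, numeric(1L))
}

#' GSEA enrichment score of a gene set
#'
#' The weighted Kolmogorov-Smirnov-like statistic: genes are sorted by
#' descending signal-to-noise association with the phenotype and a running
#' sum is walked down the list, increasing by |score|^w (normalized over the
#' set's hits) at member genes and decreasing by 1/(p - NH) at non-members.
#' The enrichment score is the signed maximum deviation from zero of this
#' walk, and lies in [-1, 1].
#'
#' @param dataset an \code{expression_dataset}.
#' @param gene_set a \code{gene_set}; its effective set must be non-empty and
#'   a proper subset of the dataset's genes.
#' @param weight_exponent weighting exponent w applied to the hit scores
#'   (default 1, the weighted variant; 0 gives the unweighted statistic).
#' @param cap passed to \code{\link{gene_level_snr}}.
#' @return Signed enrichment score.
#' @export
gsea_enrichment_score <- function(dataset, gene_set, weight_exponent = 1, cap = 1e6) {
  eff <- effective_set(gene_set, dataset)
  if (length(eff) == 0L) stop("empty effective set for '", gene_set$name, "'")
  if (length(eff) == length(dataset$genes))
    stop("effective set covers all genes; miss decrement undefined")
  s <- gene_level_snr(dataset, cap = cap)
  es_for_scores(unname(s), list(match(eff, dataset$genes)), weight_exponent)[1L]
}

#' SAM-GS set statistic: between-class centroid distance
#'
#' Views each sample as a point in the subspace spanned by the set's
#' effective genes and returns the Euclidean distance between the class-0 and
#' class-1 centroids in that subspace. Nonnegative; 0 when the class
#' centroids coincide.
#'
#' @param dataset an \code{expression_dataset}.
#' @param gene_set a \code{gene_set} with non-empty effective set.
#' @return The centroid distance.
#' @export
samgs_statistic <- function(dataset, gene_set) {
  eff <- effective_set(gene_set, dataset)
  if (length(eff) == 0L) stop("empty effective set for '", gene_set$name, "'")
  samgs_columns(dataset$values[eff, , drop = FALSE],
                matrix(dataset$labels, ncol = 1L))[1L]
}

# Vectorized centroid distance over label columns. vset: m x N; labmat: N x B.
samgs_columns <- function(vset, labmat) {
  n0 <- sum(labmat[, 1L] == 0L)
  n1 <- nrow(labmat) - n0
  ctr <- (labmat == 0L) / n0 - (labmat == 1L) / n1
  d <- vset %*% ctr
  sqrt(colSums(d^2))
}

#' Global test score statistic of a gene set
#'
#' The score-statistic form of the random-effects regression test for
#' association between a gene set's expression subspace and the class labels:
#' with the effective-set submatrix standardized per gene (mean 0, sd 1 over
#' samples; zero-variance genes dropped) into the N x m matrix X, and
#' centered labels z = y - mean(y), the statistic is
#' Q = z' X X' z / m. Nonnegative; large Q indicates that the regression
#' function fitted in the subspace separates the classes.
#'
#' @param dataset an \code{expression_dataset}.
#' @param gene_set a \code{gene_set}; at least one effective gene must have
#'   nonzero variance.
#' @return The statistic Q.
#' @export
global_test_statistic <- function(dataset, gene_set) {
  xs <- global_standardize(dataset, gene_set)
  global_columns(xs, matrix(dataset$labels, ncol = 1L))[1L]
}

# Standardized effective-set submatrix (genes x samples), zero-variance genes
# dropped; errors when nothing remains.
global_standardize <- function(dataset, gene_set) {
  eff <- effective_set(gene_set, dataset)
  if (length(eff) == 0L) stop("empty effective set for '", gene_set$name, "'")
  v <- dataset$values[eff, , drop = FALSE]
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  keep <- sdv > 0
  if (!any(keep))
    stop("all effective-set genes constant for '", gene_set$name, "'")
  (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
}

# Vectorized Q over label columns. xs: m x N standardized; labmat: N x B.
global_columns <- function(xs, labmat) {
  z <- sweep(labmat, 2L, colMeans(labmat))
  colSums((xs %*% z)^2) / nrow(xs)
}
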