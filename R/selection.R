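#' Information gain of one continuous feature (bits)
#'
#' Expected reduction in class entropy obtained by the best binary split of
#' the samples on the feature: IG = H(Y) - min over thresholds of the
#' weighted conditional entropy, with candidate thresholds at the midpoints
#' of consecutive distinct sorted feature values (C4.5-style single split).
#' Base-2 entropy; a constant feature scores 0. IG is nonnegative, bounded by
#' H(Y), and invariant under strictly monotone transforms of the feature.
#'
#' @param feature_values numeric vector (>= 2 samples).
#' @param labels 0/1 vector with both classes present.
#' @return Information gain in bits.
#' @export
information_gain <- function(feature_values, labels) {
  labels <- as.integer(labels)
  n <- length(feature_values)
  if (n < 2L || length(labels) != n) stop("need >= 2 samples with aligned labels")
  if (length(unique(labels)) < 2L) stop("single-class labels")
  hy <- entropy01(labels)
  o <- order(feature_values)
  x <- feature_values[o]; y <- labels[o]
  cut <- which(diff(x) > 0)            # split after position i
  if (length(cut) == 0L) return(0)
  c1 <- cumsum(y)
  tot1 <- c1[n]
  nl <- cut; n1l <- c1[cut]
  nr <- n - nl; n1r <- tot1 - n1l
  hpart <- function(k, k1) {
    p <- k1 / k
    h <- numeric(length(p))
    ok <- p > 0 & p < 1
    h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
    h
  }
  cond <- (nl / n) * hpart(nl, n1l) + (nr / n) * hpart(nr, n1r)
  max(hy - min(cond), 0)
}

#' Rank features by linear-SVM recursive feature elimination
#'
#' Repeatedly trains a linear soft-margin SVM (cost C = 1) on the surviving
#' features (standardized to training mean 0 / sd 1 once, up front) and
#' eliminates the feature(s) with the smallest absolute hyperplane weight,
#' until none remain. The final ranking is the reverse elimination order:
#' features eliminated last rank first. In chunked mode, iteration i removes
#' floor(F * 2^-i)
#' features (F = the original feature count), at least one per iteration —
#' the usual speed-up for large feature spaces, at the possible expense of
#' some ranking fidelity. Weight ties are broken by feature index (the
#' higher-index feature is eliminated first), so the result is deterministic
#' given the input column order.
#'
#' @param features samples-by-features numeric matrix (>= 2 features).
#' @param labels 0/1 vector with both classes present.
#' @param chunked logical; use the halving removal schedule (default FALSE:
#'   one feature per iteration).
#' @return Integer vector of feature indices, best first, named by the
#'   feature column names when present.
#' @export
svmrfe_rank <- function(features, labels, chunked = FALSE) {
  features <- as.matrix(features)
  if (ncol(features) < 2L) stop("SVM-RFE needs >= 2 features")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("single-class labels")
  mu <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  x <- sweep(features, 2L, mu)
  pos <- sdv > 0
  x[, pos] <- sweep(x[, pos, drop = FALSE], 2L, sdv[pos], "/")
  x[, !pos] <- 0
  f_total <- ncol(x)
  alive <- seq_len(f_total)
  eliminated <- integer(0L)
  y <- factor(labels)
  i <- 0L
  while (length(alive) > 0L) {
    i <- i + 1L
    fit <- e1071::svm(x[, alive, drop = FALSE], y, kernel = "linear",
                      cost = 1, scale = FALSE)
    w <- as.numeric(crossprod(fit$coefs, fit$SV))
    n_rm <- if (chunked) max(1L, as.integer(floor(f_total * 2^(-i)))) else 1L
    n_rm <- min(n_rm, length(alive))
    drop_local <- order(abs(w), -seq_along(alive))[seq_len(n_rm)]
    eliminated <- c(eliminated, alive[drop_local])
    alive <- alive[-drop_local]
  }
  ranking <- rev(eliminated)
  names(ranking) <- colnames(features)[ranking]
  ranking
}

#' Select the top genes by a generic scorer
#'
#' Gene-level generic feature selection on training data: each gene is a
#' feature; genes are ranked by information gain (ties broken by dataset gene
#' order) or by chunked SVM-RFE, and the k best gene identifiers are
#' returned. The presets k = 22 and k = 228 correspond to the median unique
#' gene counts behind single-set and ten-set set-level representations and
#' make gene-level selection comparable to them.
#'
#' @param dataset training \code{expression_dataset} (never the test fold).
#' @param scorer \code{"IG"} or \code{"SVMRFE"}.
#' @param k number of genes to keep (1 <= k <= number of genes).
#' @return Character vector of k gene identifiers, best first.
#' @export
select_top_genes <- function(dataset, scorer = c("IG", "SVMRFE"), k) {
  scorer <- match.arg(scorer)
  stopifnot(inherits(dataset, "expression_dataset"))
  p <- length(dataset$genes)
  if (k <= 0L) stop("k must be positive")
  if (k > p) stop("k exceeds the number of genes")
  if (scorer == "IG") {
    ig <- apply(dataset$values, 1L, information_gain, labels = dataset$labels)
    o <- order(-ig, seq_len(p))
  } else {
    o <- svmrfe_rank(t(dataset$values), dataset$labels, chunked = TRUE)
  }
  dataset$genes[o[seq_len(k)]]
}

#' Rank gene sets by a generic scorer on aggregated features
#'
#' Generic feature selection applied at the set level: because IG and SVM-RFE
#' score a feature by its single value per sample, aggregation must precede
#' ranking here. The aggregation model is fitted on the training data, one
#' feature is built per set, and the set features are ranked by the scorer.
#' The result is a \code{gene_set_ranking} (p-values are not defined for
#' these scorers and are reported as NA), interoperable with every consumer
#' of ranking results.
#'
#' @param dataset training \code{expression_dataset}.
#' @param collection a \code{gene_set_collection}; sets with empty effective
#'   sets are dropped with a warning.
#' @param scorer \code{"IG"} or \code{"SVMRFE"}.
#' @param aggregation_mode \code{"AVG"}, \code{"SVD"} or \code{"SETSIG"}
#'   (\code{NONE} is not meaningful before generic ranking).
#' @return A \code{gene_set_ranking}; for IG the statistic column holds the
#'   information gain (sort key: IG descending, name ascending), for SVM-RFE
#'   the rank is the elimination order and the statistic is NA.
#' @export
rank_sets_generic <- function(dataset, collection, scorer = c("IG", "SVMRFE"),
                              aggregation_mode = c("AVG", "SVD", "SETSIG")) {
  scorer <- match.arg(scorer)
  aggregation_mode <- match.arg(aggregation_mode)
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(collection, "gene_set_collection"))
  eff_len <- vapply(collection$sets, function(s)
    length(effective_set(s, dataset)), integer(1L))
  min_eff <- if (aggregation_mode == "SETSIG") 3L else 1L
  keep <- eff_len >= min_eff
  if (!all(keep))
    warning(sum(!keep), " set(s) dropped (effective set too small)")
  if (!any(keep)) stop("no usable gene set")
  sets <- collection$sets[keep]
  model <- fit_aggregation(dataset, sets, mode = aggregation_mode)
  feats <- build_feature_matrix(model, dataset)
  nm <- colnames(feats)
  if (scorer == "IG") {
    ig <- apply(feats, 2L, information_gain, labels = dataset$labels)
    o <- order(-ig, nm)
    entries <- data.frame(set = nm[o], statistic = unname(ig[o]),
                          p_value = NA_real_, rank = seq_along(o),
                          stringsAsFactors = FALSE)
  } else {
    o <- svmrfe_rank(feats, dataset$labels, chunked = TRUE)
    entries <- data.frame(set = nm[o], statistic = NA_real_,
                          p_value = NA_real_, rank = seq_along(o),
                          stringsAsFactors = FALSE)
  }
  structure(list(method = scorer, entries = entries, n = nrow(entries),
                 n_permutations = 0L, seed = NA_integer_,
                 aggregation = aggregation_mode),
            class = "gene_set_ranking")
}
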