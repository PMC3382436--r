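#' Paired Wilcoxon comparison of two factor alternatives
#'
#' Compares two alternatives of one design factor on fold-averaged
#' accuracies, pairing every two records that agree on all remaining factors
#' (ranking, selection, aggregation, learner, dataset, ...) and differ only
#' in the tested one. The signed-rank test is applied to the paired
#' differences (alternative b minus alternative a); zero differences are
#' dropped (the documented convention), the exact null distribution is used
#' for up to 25 non-zero pairs when no absolute differences tie, and the
#' normal approximation with continuity correction otherwise. Records
#' present on only one side of a pair are excluded.
#'
#' @param records list of \code{accuracy_record}s or a
#'   \code{\link{records_table}} data frame.
#' @param factor name of the tested factor column (e.g. \code{"aggregation"}).
#' @param alt_a,alt_b the two alternatives to compare.
#' @param sided \code{"two.sided"} (default), or \code{"greater"} /
#'   \code{"less"} for the directional hypothesis that b exceeds / trails a.
#' @return An object of class \code{"comparison_report"}: factor, pair,
#'   number of (non-zero) pairs, Wilcoxon statistic, raw p-value (adjusted
#'   p-value slot NA until \code{\link{bonferroni_dunn_adjust}} is applied),
#'   sidedness and the direction of advantage.
#' @export
paired_wilcoxon <- function(records, factor, alt_a, alt_b,
                            sided = c("two.sided", "greater", "less")) {
  sided <- match.arg(sided)
  tab <- if (is.data.frame(records)) records else records_table(records)
  if (!factor %in% names(tab)) stop("unknown factor '", factor, "'")
  keys <- setdiff(names(tab), c(factor, "mean_accuracy"))
  a <- tab[tab[[factor]] == alt_a, , drop = FALSE]
  b <- tab[tab[[factor]] == alt_b, , drop = FALSE]
  m <- merge(a, b, by = keys, suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("no matched pairs for ", alt_a, " vs ", alt_b)
  d <- m$mean_accuracy_b - m$mean_accuracy_a
  d <- d[d != 0]
  if (length(d) == 0L) stop("all differences zero")
  # exact null distribution only where it exists (no tied |differences|)
  use_exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  ht <- stats::wilcox.test(d, mu = 0, alternative = sided,
                           exact = use_exact, correct = TRUE)
  structure(list(factor = factor, alt_a = alt_a, alt_b = alt_b,
                 n_pairs = length(d), statistic = unname(ht$statistic),
                 p_value = ht$p.value, p_adjusted = NA_real_, sided = sided,
                 direction = if (mean(d) > 0) alt_b else alt_a),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Paired Wilcoxon on '", x$factor, "': ", x$alt_b, " vs ", x$alt_a,
      " (", x$sided, ")\n", sep = "")
  cat(sprintf("  n = %d, V = %g, p = %.4g", x$n_pairs, x$statistic, x$p_value))
  if (!is.na(x$p_adjusted)) cat(sprintf(" (adjusted %.4g)", x$p_adjusted))
  cat("\n  advantage:", x$direction, "\n")
  invisible(x)
}

#' Bonferroni-Dunn adjustment of p-values
#'
#' Multiplies each p-value by the number of comparisons in the family and
#' caps at 1: adjusted p = min(1, p * m). Used after pairwise Wilcoxon tests
#' within one factor (m = number of pairwise comparisons).
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @param m family size; must be at least the number of p-values.
#' @return Adjusted p-values.
#' @export
bonferroni_dunn_adjust <- function(p_values, m) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must be >= the number of p-values")
  pmin(1, p_values * m)
}

combo_key <- function(tab) {
  ifelse(tab$ranking == "baseline", "baseline",
         paste(tab$sets, tab$ranking, tab$aggregation, sep = " | "))
}

#' Ranked table of method combinations by median accuracy
#'
#' One row per method combination — (sets forming features, ranking
#' algorithm, aggregation), with baseline records collapsed into a single
#' \code{"baseline"} row — with the median, mean, standard deviation and
#' interquartile range of the fold-averaged accuracies pooled across
#' datasets and learners. Sorted by median, best first. Quantiles use linear
#' interpolation (R type 7); the IQR is Q3 - Q1.
#'
#' @param records list of \code{accuracy_record}s or a records table.
#' @return data.frame with columns combo, n, median, mean, sd, iqr.
#' @export
median_ranking_table <- function(records) {
  tab <- if (is.data.frame(records)) records else records_table(records)
  if (nrow(tab) == 0L) stop("no records")
  tab$combo <- combo_key(tab)
  out <- do.call(rbind, lapply(split(tab, tab$combo), function(g) {
    q <- stats::quantile(g$mean_accuracy, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(combo = g$combo[1L], n = nrow(g),
               median = stats::median(g$mean_accuracy),
               mean = mean(g$mean_accuracy),
               sd = if (nrow(g) > 1L) stats::sd(g$mean_accuracy) else 0,
               iqr = q[2L] - q[1L], stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$median, out$combo), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average sub-rank table of method combinations
#'
#' Ranks the method combinations within every (dataset, learner) cell by
#' fold-averaged accuracy (best = rank 1; ties receive their average rank)
#' and averages each combination's ranks over all cells. This avoids pooling
#' accuracies across datasets. Every combination must be present in every
#' cell; incomplete combinations are reported by name.
#'
#' @param records list of \code{accuracy_record}s or a records table.
#' @return data.frame with columns combo and avg_subrank, sorted ascending
#'   (best first).
#' @export
subrank_table <- function(records) {
  tab <- if (is.data.frame(records)) records else records_table(records)
  if (nrow(tab) == 0L) stop("no records")
  tab$combo <- combo_key(tab)
  tab$cell <- paste(tab$dataset_id, tab$learner, sep = " | ")
  combos <- unique(tab$combo)
  cells <- unique(tab$cell)
  counts <- table(tab$combo, tab$cell)
  bad <- rownames(counts)[rowSums(counts == 1L) != length(cells)]
  if (length(bad))
    stop("combination(s) not present exactly once in every (dataset, learner) ",
         "cell: ", paste(bad, collapse = ", "))
  tab$subrank <- stats::ave(-tab$mean_accuracy, tab$cell,
                            FUN = function(x) rank(x, ties.method = "average"))
  agg <- stats::aggregate(subrank ~ combo, data = tab, FUN = mean)
  names(agg) <- c("combo", "avg_subrank")
  agg <- agg[order(agg$avg_subrank, agg$combo), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Least-squares trend of accuracy against gene-set rank position
#'
#' Ordinary least-squares fit of mean accuracy on the rank position of the
#' gene set(s) forming the features; a negative slope means accuracy decays
#' as lower-ranking sets are used.
#'
#' @param rank_position numeric vector of rank positions (at least two
#'   distinct values).
#' @param accuracy numeric vector of matching accuracies.
#' @return List with \code{slope}, \code{intercept} and the underlying
#'   \code{lm} fit.
#' @export
accuracy_trend <- function(rank_position, accuracy) {
  if (length(unique(rank_position)) < 2L)
    stop("need at least two distinct rank positions")
  fit <- stats::lm(accuracy ~ rank_position)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]), fit = fit)
}

pca_components <- function(dataset, eff_genes, fractions) {
  if (length(eff_genes) == 0L) return(rep(NA_real_, length(fractions)))
  ev <- stats::prcomp(t(dataset$values[eff_genes, , drop = FALSE]),
                      center = TRUE, scale. = FALSE)$sdev^2
  tot <- sum(ev)
  if (tot == 0) return(rep(NA_real_, length(fractions)))
  cs <- cumsum(ev) / tot
  vapply(fractions, function(fr) as.numeric(which(cs >= fr - 1e-12)[1L]),
         numeric(1L))
}

#' Size and dimensionality statistics of gene-set groups
#'
#' For named groups of gene sets (e.g. a full collection vs the subset
#' selected by ranking vs the subset acting in successful classifiers),
#' computes per set the nominal size, the effective size in the dataset, and
#' the number of principal components capturing 50% and 90% of the set's
#' expression variance; reports group means with standard errors and group
#' medians, and tests all group pairs per metric with the Mann-Whitney U
#' test (normal approximation with tie correction), Bonferroni-adjusted with
#' the stated family size m = (number of group pairs) x (number of metrics).
#'
#' @param groups named list of \code{gene_set_collection}s (or lists of
#'   \code{gene_set}s).
#' @param dataset an \code{expression_dataset}.
#' @param fractions variance fractions for the PCA component counts.
#' @return List with \code{per_set} (set-level metrics), \code{table}
#'   (group summaries), \code{tests} (pairwise comparisons with raw and
#'   adjusted p) and \code{bonferroni_m}.
#' @export
gene_set_group_stats <- function(groups, dataset, fractions = c(0.5, 0.9)) {
  stopifnot(length(groups) > 0L, !is.null(names(groups)),
            inherits(dataset, "expression_dataset"))
  per_set <- do.call(rbind, lapply(names(groups), function(gname) {
    coll <- groups[[gname]]
    sets <- if (inherits(coll, "gene_set_collection")) coll$sets else coll
    if (length(sets) == 0L) stop("group '", gname, "' is empty")
    rows <- lapply(sets, function(s) {
      eff <- effective_set(s, dataset)
      pcs <- pca_components(dataset, eff, fractions)
      data.frame(group = gname, set = s$name, nominal_size = length(s$genes),
                 effective_size = length(eff),
                 pca50 = pcs[1L], pca90 = pcs[2L], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (all(is.na(per_set$pca50[per_set$effective_size > 0])) &&
      all(per_set$effective_size == 0))
    stop("all effective sets empty in every group")
  metrics <- c("nominal_size", "effective_size", "pca50", "pca90")
  summarize <- function(g) {
    row <- data.frame(group = g$group[1L], n_sets = nrow(g))
    for (mcol in metrics) {
      x <- g[[mcol]][!is.na(g[[mcol]])]
      row[[paste0(mcol, "_mean")]] <- mean(x)
      row[[paste0(mcol, "_se")]] <- stats::sd(x) / sqrt(length(x))
      row[[paste0(mcol, "_median")]] <- stats::median(x)
    }
    row
  }
  table <- do.call(rbind, lapply(split(per_set, per_set$group), summarize))
  rownames(table) <- NULL
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  m <- length(pairs) * length(metrics)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(metrics, function(mcol) {
      x <- per_set[[mcol]][per_set$group == pr[1L]]
      y <- per_set[[mcol]][per_set$group == pr[2L]]
      ht <- suppressWarnings(stats::wilcox.test(x[!is.na(x)], y[!is.na(y)],
                                                exact = FALSE, correct = TRUE))
      # fully tied tiny groups have zero rank variance -> undefined p
      pv <- if (is.nan(ht$p.value)) NA_real_ else ht$p.value
      data.frame(group_a = pr[1L], group_b = pr[2L], metric = mcol,
                 statistic = unname(ht$statistic), p_value = pv,
                 stringsAsFactors = FALSE)
    }))
  }))
  tests$p_adjusted <- bonferroni_dunn_adjust(tests$p_value, m)
  rownames(tests) <- NULL
  list(per_set = per_set, table = table, tests = tests, bonferroni_m = m)
}

#' Export a comparison report or table as TSV or JSON
#'
#' @param x a \code{comparison_report} or a data.frame report.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
export_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(x, "comparison_report")) x <- as.data.frame(unclass(x)[1:9])
  if (format == "tsv")
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
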