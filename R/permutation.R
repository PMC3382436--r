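# Phenotype-permutation machinery shared by the three set statistics.

# N x B matrix of label-vector permutations (class sizes preserved by
# construction: each column is a permutation of the observed label vector).
perm_label_matrix <- function(labels, n_permutations, seed) {
  rng <- local_rng(seed)
  on.exit(rng())
  n <- length(labels)
  vapply(seq_len(n_permutations), function(b) labels[sample.int(n)],
         integer(n))
}

# All distinct balanced label assignments (columns), observed class sizes
# preserved; used for exact enumeration on small fixtures.
all_label_assignments <- function(labels) {
  n <- length(labels)
  n0 <- sum(labels == 0L)
  idx0 <- utils::combn(n, n0)
  apply(idx0, 2L, function(i) {
    l <- rep.int(1L, n); l[i] <- 0L; l
  })
}

# Statistic values of every set for each label column, one matrix row per set.
# method: "GSEA" | "SAMGS" | "GLOBAL"; set_indices: list of gene row indices.
statistic_columns <- function(values, labmat, method, set_indices,
                              weight_exponent = 1, cap = 1e6) {
  if (method == "GSEA") {
    snr <- snr_columns(values, labmat, cap)
    vapply(seq_len(ncol(labmat)), function(b)
      es_for_scores(snr[, b], set_indices, weight_exponent),
      numeric(length(set_indices)))
  } else if (method == "SAMGS") {
    t(vapply(set_indices, function(idx)
      samgs_columns(values[idx, , drop = FALSE], labmat),
      numeric(ncol(labmat))))
  } else if (method == "GLOBAL") {
    t(vapply(set_indices, function(idx) {
      v <- values[idx, , drop = FALSE]
      mu <- rowMeans(v)
      sdv <- apply(v, 1L, stats::sd)
      keep <- sdv > 0
      if (!any(keep)) stop("all effective-set genes constant")
      xs <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
      global_columns(xs, labmat)
    }, numeric(ncol(labmat))))
  } else stop("unknown method '", method, "'")
}

# Ensure a row-major matrix shape even for a single set / single column.
as_stat_matrix <- function(x, n_sets, n_cols) {
  matrix(x, nrow = n_sets, ncol = n_cols)
}

#' Phenotype-permutation p-value for one gene set
#'
#' Recomputes the chosen set statistic under permutations of the class-label
#' vector (class sizes are preserved because entire label vectors are
#' permuted) and returns the add-one smoothed empirical p-value
#' p = (b + 1) / (B + 1), where b counts permuted statistics at least as
#' extreme as the observed one: |stat| >= |observed| for GSEA (the enrichment
#' score is signed) and stat >= observed for SAM-GS and the Global test (both
#' one-sided nonnegative). With \code{exhaustive = TRUE} all distinct
#' balanced label assignments are enumerated instead and the exact proportion
#' (observed assignment included) is returned.
#'
#' @param statistic one of \code{"GSEA"}, \code{"SAMGS"}, \code{"GLOBAL"}.
#' @param dataset an \code{expression_dataset}.
#' @param gene_set a \code{gene_set}.
#' @param n_permutations number of random label permutations B (>= 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @param exhaustive enumerate all distinct balanced labelings exactly
#'   (small N only).
#' @param weight_exponent GSEA hit-weight exponent.
#' @return List with elements \code{observed} and \code{p}.
#' @export
permutation_pvalue <- function(statistic, dataset, gene_set,
                               n_permutations = 999L, seed = 1L,
                               exhaustive = FALSE, weight_exponent = 1) {
  statistic <- match.arg(statistic, c("GSEA", "SAMGS", "GLOBAL"))
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!exhaustive && n_permutations < 1L) stop("n_permutations must be >= 1")
  eff <- effective_set(gene_set, dataset)
  if (length(eff) == 0L) stop("empty effective set for '", gene_set$name, "'")
  idx <- list(match(eff, dataset$genes))
  labs <- unname(dataset$labels)
  labmat <- if (exhaustive) all_label_assignments(labs)
            else cbind(labs, perm_label_matrix(labs, n_permutations, seed))
  st <- as_stat_matrix(
    statistic_columns(dataset$values, labmat, statistic, idx, weight_exponent),
    1L, ncol(labmat))
  if (exhaustive) {
    # the observed labeling is one of the enumerated assignments; read its
    # statistic from the same computation so the >= comparison is exact
    j_obs <- which(colSums(labmat != labs) == 0L)[1L]
    obs <- st[1L, j_obs]
    extreme <- if (statistic == "GSEA") abs(st[1L, ]) >= abs(obs) else st[1L, ] >= obs
    return(list(observed = obs, p = mean(extreme)))
  }
  obs <- st[1L, 1L]
  perm <- st[1L, -1L]
  b <- if (statistic == "GSEA") sum(abs(perm) >= abs(obs)) else sum(perm >= obs)
  list(observed = obs, p = (b + 1) / (n_permutations + 1))
}

#' Rank a gene-set collection by class-discrimination power
#'
#' Scores every set of the collection with the chosen statistic, attaches a
#' phenotype-permutation p-value (one shared set of label permutations across
#' sets), and ranks the sets by the deterministic sort key
#' (p ascending, |statistic| descending, set name ascending). Sets whose
#' effective set in the dataset is empty are dropped with a warning before
#' ranking.
#'
#' @param dataset an \code{expression_dataset} (the training fold in a
#'   learning workflow; ranking must never see test samples).
#' @param collection a \code{gene_set_collection}.
#' @param method \code{"GSEA"}, \code{"SAMGS"} or \code{"GLOBAL"}.
#' @param n_permutations permutation count B (default 999).
#' @param seed integer seed for the permutation draw.
#' @param weight_exponent GSEA hit-weight exponent (default 1).
#' @return An object of class \code{"gene_set_ranking"}: list with
#'   \code{method}, \code{entries} (data.frame set / statistic / p_value /
#'   rank, sorted by rank), \code{n} (number of ranked sets),
#'   \code{n_permutations} and \code{seed}.
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_sets = 8, n_signal = 1, seed = 7))
#' rk <- rank_gene_sets(sim$dataset, sim$collection, "GLOBAL",
#'                      n_permutations = 99, seed = 1)
#' head(rk$entries)
#' @export
rank_gene_sets <- function(dataset, collection, method = c("GLOBAL", "SAMGS", "GSEA"),
                           n_permutations = 999L, seed = 1L, weight_exponent = 1) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(collection, "gene_set_collection"))
  eff <- lapply(collection$sets, effective_set, dataset = dataset)
  keep <- vapply(eff, length, integer(1L)) > 0L
  if (method == "GSEA")  # a set covering all genes leaves no misses to walk
    keep <- keep & vapply(eff, length, integer(1L)) < length(dataset$genes)
  if (!all(keep))
    warning(sum(!keep), " set(s) dropped (empty or degenerate effective set)")
  if (!any(keep)) stop("no gene set has a usable effective set in this dataset")
  sets <- collection$sets[keep]
  idx <- lapply(eff[keep], match, table = dataset$genes)
  labs <- unname(dataset$labels)
  labmat <- cbind(labs, perm_label_matrix(labs, n_permutations, seed))
  st <- as_stat_matrix(
    statistic_columns(dataset$values, labmat, method, idx, weight_exponent),
    length(idx), ncol(labmat))
  obs <- st[, 1L]
  perm <- st[, -1L, drop = FALSE]
  b <- if (method == "GSEA") rowSums(abs(perm) >= abs(obs))
       else rowSums(perm >= obs)
  p <- (b + 1) / (n_permutations + 1)
  nm <- vapply(sets, `[[`, character(1L), "name")
  o <- order(p, -abs(obs), nm)
  entries <- data.frame(set = nm[o], statistic = unname(obs[o]),
                        p_value = unname(p[o]), rank = seq_along(o),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(method = method, entries = entries, n = nrow(entries),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "gene_set_ranking")
}

#' @export
print.gene_set_ranking <- function(x, ...) {
  cat("Gene-set ranking (", x$method, "), ", x$n, " sets, B = ",
      x$n_permutations, "\n", sep = "")
  print(utils::head(x$entries, 10L), row.names = FALSE)
  if (x$n > 10L) cat("... ", x$n - 10L, " more\n", sep = "")
  invisible(x)
}

#' Export a ranking as TSV or JSON
#'
#' @param ranking a \code{gene_set_ranking}.
#' @param path output path.
#' @param format \code{"tsv"} (columns set, statistic, p_value, rank) or
#'   \code{"json"}.
#' @export
export_ranking <- function(ranking, path, format = c("tsv", "json")) {
  stopifnot(inherits(ranking, "gene_set_ranking"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(ranking$entries, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(
      list(method = ranking$method, n_permutations = ranking$n_permutations,
           seed = ranking$seed, entries = ranking$entries),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(ranking)
}
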