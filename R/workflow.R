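#' Stratified cross-validation folds
#'
#' Partitions the samples into k disjoint test folds, stratified by class:
#' within each class the (shuffled) samples are dealt out so that every
#' fold's class count differs from an even split by at most one sample; the
#' second class's deal is rotated so fold sizes stay balanced overall.
#' Deterministic under \code{seed}. A class with fewer than k samples is
#' allowed (some folds then lack that class) but draws a warning.
#'
#' @param dataset an \code{expression_dataset}.
#' @param k number of folds (2 <= k <= number of samples).
#' @param seed integer seed.
#' @return List of k character vectors of test-fold sample identifiers.
#' @export
stratified_folds <- function(dataset, k = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  n <- length(dataset$samples)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of samples")
  tab <- table(dataset$labels)
  if (min(tab) < k)
    warning("a class has fewer than k samples; some folds will lack it")
  rng <- local_rng(seed)
  on.exit(rng())
  folds <- vector("list", k)
  offset <- 0L
  for (cls in c(0L, 1L)) {
    ids <- dataset$samples[dataset$labels == cls]
    ids <- ids[sample.int(length(ids))]
    fold_of <- ((seq_along(ids) - 1L + offset) %% k) + 1L
    for (f in seq_len(k))
      folds[[f]] <- c(folds[[f]], ids[fold_of == f])
    offset <- offset + length(ids)
  }
  folds
}

#' Experiment configuration for one workflow execution
#'
#' One point of the factorial design: the four analyzed factors (gene-set
#' collection variant, ranking algorithm, rank selection, aggregation) plus
#' the learner, a dataset identifier and the seed from which folds and
#' permutations are derived.
#'
#' @param gene_sets \code{"GENUINE"} (use the collection as given) or
#'   \code{"RANDOM"} (replace it by a size-matched randomized control
#'   collection before ranking).
#' @param ranking \code{"GLOBAL"}, \code{"SAMGS"}, \code{"GSEA"},
#'   \code{"IG"} or \code{"SVMRFE"}.
#' @param sets rank selection, see \code{\link{parse_rank_spec}}.
#' @param aggregation \code{"SVD"}, \code{"AVG"}, \code{"SETSIG"} or
#'   \code{"NONE"} (\code{NONE} is incompatible with generic ranking).
#' @param learner \code{"svm"}, \code{"1nn"}, \code{"3nn"}, \code{"nb"},
#'   \code{"dt"}.
#' @param dataset_id label of the dataset the configuration runs on.
#' @param seed master seed of the execution.
#' @return An object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(gene_sets = c("GENUINE", "RANDOM"),
                              ranking = c("GLOBAL", "SAMGS", "GSEA", "IG", "SVMRFE"),
                              sets = "1:10",
                              aggregation = c("SVD", "AVG", "SETSIG", "NONE"),
                              learner = c("svm", "1nn", "3nn", "nb", "dt"),
                              dataset_id = "d1", seed = 1L) {
  gene_sets <- match.arg(gene_sets)
  ranking <- match.arg(ranking)
  aggregation <- match.arg(aggregation)
  learner <- match.arg(learner)
  if (ranking %in% c("IG", "SVMRFE") && aggregation == "NONE")
    stop("generic ranking requires aggregation != 'NONE'")
  parse_rank_spec(sets, n = .Machine$integer.max)  # syntax check only
  structure(list(gene_sets = gene_sets, ranking = ranking,
                 sets = as.character(sets), aggregation = aggregation,
                 learner = learner, dataset_id = dataset_id,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Config: ", x$gene_sets, " | ", x$ranking, " | sets ", x$sets, " | ",
      x$aggregation, " | ", x$learner, " | ", x$dataset_id,
      " | seed ", x$seed, "\n", sep = "")
  invisible(x)
}

new_accuracy_record <- function(config, fold_accuracies, details = NULL) {
  structure(list(config = config,
                 fold_accuracies = as.numeric(fold_accuracies),
                 mean_accuracy = mean(fold_accuracies),
                 details = details),
            class = "accuracy_record")
}

#' @export
print.accuracy_record <- function(x, ...) {
  print(x$config)
  cat(sprintf("Mean accuracy %.3f over %d folds (range %.3f-%.3f)\n",
              x$mean_accuracy, length(x$fold_accuracies),
              min(x$fold_accuracies), max(x$fold_accuracies)))
  invisible(x)
}

#' Run one set-level learning workflow under cross-validation
#'
#' Executes the full learning workflow for one configuration: stratified
#' k-fold cross-validation in which, per fold, the gene sets are ranked on
#' the training fold only, sets are selected by rank, the aggregation model
#' is fitted on the training fold, both folds are reformulated to the set
#' level with that model, the learner is trained, and accuracy is measured
#' on the held-out test fold. Folds depend only on (seed, dataset_id), so
#' records produced with the same seed are fold-matched across
#' configurations, as required for the paired comparisons.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param dataset an \code{expression_dataset}.
#' @param collection the genuine \code{gene_set_collection}; when the config
#'   says \code{"RANDOM"} a seed-matched randomized control collection is
#'   substituted internally.
#' @param n_permutations permutation count for ranking p-values (default 199;
#'   the workflow consumes ranks, which stabilize faster than p-values).
#' @param k number of folds (default 10).
#' @param return_details keep per-fold selected sets, fitted models and
#'   test predictions in the record (used e.g. by leakage audits).
#' @param folds optional precomputed fold list (as returned by
#'   \code{\link{stratified_folds}}); overrides the seed-derived folds, e.g.
#'   to audit that corrupting test-fold labels cannot change the fitted
#'   models.
#' @return An \code{"accuracy_record"} with per-fold and mean accuracy.
#' @export
run_workflow <- function(config, dataset, collection, n_permutations = 199L,
                         k = 10L, return_details = FALSE, folds = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$gene_sets == "RANDOM")
    collection <- randomize_collection(
      collection, derive_seed(config$seed, config$dataset_id, "rnd"))
  if (is.null(folds))
    folds <- stratified_folds(dataset, k = k,
                              seed = derive_seed(config$seed, config$dataset_id, "folds"))
  acc <- numeric(length(folds))
  details <- if (return_details) vector("list", length(folds)) else NULL
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train <- subset_samples(dataset, setdiff(dataset$samples, test_ids))
    fit <- setlevel(train, collection, ranking = config$ranking,
                    sets = config$sets, aggregation = config$aggregation,
                    learner = config$learner, n_permutations = n_permutations,
                    seed = derive_seed(config$seed, config$dataset_id, "perm", f))
    pred <- predict(fit, dataset$values[, test_ids, drop = FALSE],
                    type = "numeric")
    acc[f] <- mean(pred == dataset$labels[test_ids])
    if (return_details)
      details[[f]] <- list(test_samples = test_ids, selected = fit$selected,
                           fit = fit, predictions = pred)
  }
  new_accuracy_record(config, acc, details)
}

#' Run the gene-level baseline classifier
#'
#' The conventional comparator: every measured gene is a feature and the
#' set-level pre-processing factors are skipped entirely. Optionally a
#' generic gene-selection step (information gain or SVM-RFE, computed on the
#' training fold only) reduces the features to the k top-ranked genes — with
#' k = 22 or 228 this matches the typical unique-gene content of single-set
#' and ten-set set-level representations. The cross-validation protocol and
#' fold assignment are identical to \code{\link{run_workflow}}.
#'
#' @param dataset an \code{expression_dataset}.
#' @param learner one of the five learners.
#' @param seed master seed (folds derived as in the workflow).
#' @param selector optional list \code{list(scorer = "IG"|"SVMRFE", k = n)}.
#' @param dataset_id dataset label recorded in the config.
#' @param k number of folds.
#' @return An \code{"accuracy_record"}; its config carries
#'   \code{ranking = "baseline"}.
#' @export
run_baseline <- function(dataset, learner = c("svm", "1nn", "3nn", "nb", "dt"),
                         seed = 1L, selector = NULL, dataset_id = "d1", k = 10L) {
  learner <- match.arg(learner)
  folds <- stratified_folds(dataset, k = k,
                            seed = derive_seed(seed, dataset_id, "folds"))
  acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train <- subset_samples(dataset, setdiff(dataset$samples, test_ids))
    genes <- if (is.null(selector)) train$genes
             else select_top_genes(train, selector$scorer, selector$k)
    acc[f] <- learn_and_score(
      t(train$values[genes, , drop = FALSE]), train$labels,
      t(dataset$values[genes, test_ids, drop = FALSE]),
      dataset$labels[test_ids], learner)
  }
  config <- list(gene_sets = "baseline", ranking = "baseline",
                 sets = if (is.null(selector)) "all genes"
                        else paste0(selector$scorer, ":", selector$k),
                 aggregation = "NONE", learner = learner,
                 dataset_id = dataset_id, seed = as.integer(seed))
  class(config) <- "experiment_config"
  new_accuracy_record(config, acc)
}

#' Run a factorial grid of workflow configurations
#'
#' Executes \code{\link{run_workflow}} for every combination of the supplied
#' factor alternatives on every dataset, sharing per-fold rankings across
#' the configurations that reuse them (selection, aggregation and learner
#' vary downstream of one ranking for the dedicated set statistics; the
#' generic scorers re-rank per aggregation mode, since aggregation precedes
#' generic ranking). Per-configuration randomness is derived
#' deterministically from the master seed, so a rerun with the same seed
#' reproduces every accuracy exactly.
#'
#' @param datasets named list of \code{expression_dataset}s.
#' @param collection the genuine \code{gene_set_collection}.
#' @param gene_sets,ranking,sets,aggregation,learner character vectors of
#'   factor alternatives (defaults: a minimal sensible grid).
#' @param master_seed master seed of the whole grid.
#' @param n_permutations ranking permutation count.
#' @param k number of folds.
#' @return List of \code{"accuracy_record"}s, one per configuration x dataset.
#' @export
run_factorial <- function(datasets, collection,
                          gene_sets = "GENUINE",
                          ranking = "GLOBAL",
                          sets = c("1", "1:10"),
                          aggregation = c("SVD", "AVG"),
                          learner = "svm",
                          master_seed = 1L, n_permutations = 199L, k = 10L) {
  stopifnot(length(datasets) > 0L, !is.null(names(datasets)))
  records <- list()
  for (ds_id in names(datasets)) {
    dataset <- datasets[[ds_id]]
    folds <- stratified_folds(dataset, k = k,
                              seed = derive_seed(master_seed, ds_id, "folds"))
    trains <- lapply(folds, function(ids)
      subset_samples(dataset, setdiff(dataset$samples, ids)))
    for (gs in gene_sets) {
      coll <- if (gs == "RANDOM")
        randomize_collection(collection, derive_seed(master_seed, ds_id, "rnd"))
      else collection
      for (rkm in ranking) {
        generic <- rkm %in% c("IG", "SVMRFE")
        agg_groups <- if (generic) setdiff(aggregation, "NONE") else "*"
        for (agg_key in agg_groups) {
          rankings <- lapply(seq_along(folds), function(f) {
            if (generic)
              rank_sets_generic(trains[[f]], coll, scorer = rkm,
                                aggregation_mode = agg_key)
            else
              rank_gene_sets(trains[[f]], coll, method = rkm,
                             n_permutations = n_permutations,
                             seed = derive_seed(master_seed, ds_id, "perm", f))
          })
          aggs <- if (generic) agg_key else aggregation
          for (sp in sets) for (agg in aggs) for (lr in learner) {
            acc <- vapply(seq_along(folds), function(f) {
              fit <- fit_from_ranking(trains[[f]], coll, rankings[[f]],
                                      sp, agg, lr)
              test_ids <- folds[[f]]
              pred <- predict(fit, dataset$values[, test_ids, drop = FALSE],
                              type = "numeric")
              mean(pred == dataset$labels[test_ids])
            }, numeric(1L))
            cfg <- experiment_config(gene_sets = gs, ranking = rkm, sets = sp,
                                     aggregation = agg, learner = lr,
                                     dataset_id = ds_id, seed = master_seed)
            records[[length(records) + 1L]] <- new_accuracy_record(cfg, acc)
          }
        }
      }
    }
  }
  records
}

#' Tabulate accuracy records
#'
#' Flattens a list of \code{"accuracy_record"}s into a data frame with one
#' row per record: the factor columns of the configuration plus the
#' fold-averaged accuracy.
#'
#' @param records list of \code{accuracy_record}s (or a single record).
#' @return data.frame with columns gene_sets, ranking, sets, aggregation,
#'   learner, dataset_id, mean_accuracy.
#' @export
records_table <- function(records) {
  if (inherits(records, "accuracy_record")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    data.frame(gene_sets = r$config$gene_sets, ranking = r$config$ranking,
               sets = r$config$sets, aggregation = r$config$aggregation,
               learner = r$config$learner, dataset_id = r$config$dataset_id,
               mean_accuracy = r$mean_accuracy,
               stringsAsFactors = FALSE)
  }))
}

#' Alternatives of the rank-selection factor
#'
#' The 22 alternatives of the "sets forming features" factor: single ranks
#' 1..10 from the top, single ranks n-9..n from the bottom, and the two
#' batches 1:10 and n-9:n.
#'
#' @return Character vector of length 22.
#' @export
factor3_alternatives <- function() {
  c(as.character(1:10), paste0("n-", 9:1), "n", "1:10", "n-9:n")
}

#' Enumerate the full factorial evaluation design
#'
#' Builds the complete factor grid of the benchmark design — 2 collection
#' variants x 3 dedicated ranking methods x 22 rank selections x 4
#' aggregation modes as analyzed factors, crossed with 5 learners,
#' \code{n_datasets} datasets and \code{n_folds} testing folds — together
#' with the baseline grid (learners x datasets x folds only).
#'
#' @param n_datasets number of benchmark datasets (default 30).
#' @param n_folds number of cross-validation folds (default 10).
#' @return List with \code{workflow_grid} and \code{baseline_grid}
#'   data frames.
#' @export
design_grid <- function(n_datasets = 30L, n_folds = 10L) {
  workflow <- expand.grid(
    gene_sets = c("GENUINE", "RANDOM"),
    ranking = c("GSEA", "SAMGS", "GLOBAL"),
    sets = factor3_alternatives(),
    aggregation = c("SVD", "AVG", "SETSIG", "NONE"),
    learner = c("svm", "1nn", "3nn", "nb", "dt"),
    dataset = paste0("d", seq_len(n_datasets)),
    fold = seq_len(n_folds),
    stringsAsFactors = FALSE)
  baseline <- expand.grid(
    learner = c("svm", "1nn", "3nn", "nb", "dt"),
    dataset = paste0("d", seq_len(n_datasets)),
    fold = seq_len(n_folds),
    stringsAsFactors = FALSE)
  list(workflow_grid = workflow, baseline_grid = baseline)
}

#' Execution and measurement counts of the factorial design
#'
#' Counts derived by enumerating \code{\link{design_grid}}: the number of
#' workflow executions (one per grid row), the number of fold-averaged
#' set-level measurements (folds collapsed), and the same two counts for the
#' baseline variant.
#'
#' @param n_datasets,n_folds as in \code{\link{design_grid}}.
#' @return Named list with \code{workflow_executions},
#'   \code{set_level_measurements}, \code{baseline_executions},
#'   \code{baseline_measurements}.
#' @export
design_counts <- function(n_datasets = 30L, n_folds = 10L) {
  g <- design_grid(n_datasets, n_folds)
  # fold-averaging collapses the fold factor: one measurement per grid slice
  list(workflow_executions = nrow(g$workflow_grid),
       set_level_measurements = nrow(g$workflow_grid[g$workflow_grid$fold == 1L, ]),
       baseline_executions = nrow(g$baseline_grid),
       baseline_measurements = nrow(g$baseline_grid[g$baseline_grid$fold == 1L, ]))
}
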