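test_that("stratified folds partition the samples with balanced classes", {
  ds <- random_dataset(5, 20, 20, seed = 2)
  folds <- stratified_folds(ds, k = 10, seed = 3)
  expect_length(folds, 10L)
  all_ids <- unlist(folds)
  expect_setequal(all_ids, ds$samples)          # partition: union = all
  expect_equal(anyDuplicated(all_ids), 0L)      # pairwise disjoint
  for (f in folds) expect_equal(as.vector(table(ds$labels[f])), c(2L, 2L))
  # determinism contract
  expect_identical(stratified_folds(ds, 10, seed = 3), folds)
  expect_false(identical(stratified_folds(ds, 10, seed = 4), folds))
  expect_error(stratified_folds(ds, 1), "at least 2")
  expect_error(stratified_folds(ds, 41), "exceeds")
  small <- random_dataset(4, 3, 9, seed = 5)
  expect_warning(stratified_folds(small, 5, seed = 1), "fewer than k")
})

test_that("learner back-ends satisfy their basic contracts", {
  set.seed(3)
  y <- rep(c(0, 1), each = 10)
  x <- cbind(y * 6 - 3 + rnorm(20, sd = 0.2), rnorm(20))
  # linearly separable, wide margin: all five learners reach accuracy 1
  for (lr in c("svm", "1nn", "3nn", "nb", "dt"))
    expect_equal(learn_and_score(x, y, x, y, lr), 1.0)
  # 1-NN predicts the class of an identical training sample
  expect_equal(learn_and_score(x, y, x[3, , drop = FALSE], 0, "1nn"), 1.0)
  # 3-NN majority rule: neighbors voting 2:1 give the majority class
  xtr <- matrix(c(0, 0.1, 0.2, 5), ncol = 1)
  ytr <- c(0, 0, 1, 1)
  expect_equal(learn_and_score(xtr, ytr, matrix(0.05), 0, "3nn"), 1.0)
  # dimension mismatch is an error
  expect_error(learn_and_score(x, y, x[, 1, drop = FALSE], y, "svm"),
               "dimension mismatch")
  expect_error(learn_and_score(x, rep(0, 20), x, y, "svm"), "both classes")
})

test_that("rank specifications parse to the documented rank lists", {
  expect_equal(parse_rank_spec("1", 50), 1L)
  expect_equal(parse_rank_spec(7, 50), 7L)
  expect_equal(parse_rank_spec("n", 50), 50L)
  expect_equal(parse_rank_spec("n-9", 50), 41L)
  expect_equal(parse_rank_spec("1:10", 50), 1:10)
  expect_equal(parse_rank_spec("n-9:n", 50), 41:50)
  expect_error(parse_rank_spec("1:10", 5), "outside")
  expect_error(parse_rank_spec("x", 5), "cannot parse")
})

test_that("the workflow separates classes on planted signal and not on null data", {
  sim <- generate_synthetic(synthetic_spec(n_sets = 30, n_signal = 3, seed = 70))
  cfg <- experiment_config(ranking = "GLOBAL", sets = "1:10", aggregation = "SVD",
                           learner = "svm", dataset_id = "sig", seed = 11)
  rec <- run_workflow(cfg, sim$dataset, sim$collection, n_permutations = 99)
  expect_gt(rec$mean_accuracy, 0.9)
  expect_equal(rec$mean_accuracy, mean(rec$fold_accuracies), tolerance = 1e-12)
  expect_true(all(rec$fold_accuracies >= 0 & rec$fold_accuracies <= 1))

  null <- generate_null(synthetic_spec(n_sets = 30, seed = 71))
  rec0 <- run_workflow(cfg, null$dataset, null$collection, n_permutations = 99)
  expect_gte(rec0$mean_accuracy, 0.35)
  expect_lte(rec0$mean_accuracy, 0.65)
})

test_that("single-rank selection presents the learner exactly one feature", {
  sim <- generate_synthetic(synthetic_spec(n_sets = 12, n_signal = 2, seed = 31))
  fit <- setlevel(sim$dataset, sim$collection, ranking = "SAMGS", sets = "1",
                  aggregation = "AVG", learner = "dt", n_permutations = 49,
                  seed = 2)
  expect_equal(fit$learner$n_features, 1L)
  expect_length(fit$selected, 1L)
  # bottom-rank singles resolve relative to n
  fitn <- setlevel(sim$dataset, sim$collection, ranking = "SAMGS", sets = "n",
                   aggregation = "AVG", learner = "dt", n_permutations = 49,
                   seed = 2)
  expect_equal(fitn$selected, fitn$ranking$entries$set[fitn$ranking$n])
  # generic ranking refuses NONE aggregation
  expect_error(setlevel(sim$dataset, sim$collection, ranking = "IG",
                        aggregation = "NONE"), "must not be 'NONE'")
})

test_that("baseline uses all genes, or per-fold selected genes", {
  sim <- generate_synthetic(synthetic_spec(n_sets = 10, n_signal = 2, delta = 2,
                                           seed = 33))
  bl <- run_baseline(sim$dataset, "svm", seed = 9, dataset_id = "d1")
  expect_gt(bl$mean_accuracy, 0.5)
  expect_equal(bl$config$ranking, "baseline")
  bl_ig <- run_baseline(sim$dataset, "svm", seed = 9,
                        selector = list(scorer = "IG", k = 22), dataset_id = "d1")
  expect_true(bl_ig$mean_accuracy >= 0 && bl_ig$mean_accuracy <= 1)
  expect_equal(bl_ig$config$sets, "IG:22")
})

test_that("the factorial runner enumerates the grid deterministically", {
  sim1 <- generate_synthetic(synthetic_spec(n_sets = 12, n_signal = 2, n0 = 10,
                                            n1 = 10, set_sizes = rep(12L, 12),
                                            seed = 51))
  sim2 <- generate_synthetic(synthetic_spec(n_sets = 12, n_signal = 2, n0 = 10,
                                            n1 = 10, set_sizes = rep(12L, 12),
                                            seed = 52))
  datasets <- list(d1 = sim1$dataset, d2 = sim2$dataset)
  recs <- run_factorial(datasets, sim1$collection,
                        ranking = c("SAMGS"), sets = c("1", "1:10"),
                        aggregation = c("AVG", "SVD"), learner = c("svm", "nb"),
                        master_seed = 5, n_permutations = 29, k = 5)
  expect_length(recs, 2 * 2 * 2 * 2)   # datasets x sets x agg x learner
  tab <- records_table(recs)
  expect_equal(nrow(unique(tab[c("dataset_id", "sets", "aggregation", "learner")])),
               16L)
  recs2 <- run_factorial(datasets, sim1$collection,
                         ranking = c("SAMGS"), sets = c("1", "1:10"),
                         aggregation = c("AVG", "SVD"), learner = c("svm", "nb"),
                         master_seed = 5, n_permutations = 29, k = 5)
  expect_identical(lapply(recs, `[[`, "fold_accuracies"),
                   lapply(recs2, `[[`, "fold_accuracies"))
  # factorial accuracies equal a standalone workflow run of the same config
  cfg <- experiment_config(ranking = "SAMGS", sets = "1:10", aggregation = "SVD",
                           learner = "svm", dataset_id = "d1", seed = 5)
  solo <- run_workflow(cfg, sim1$dataset, sim1$collection, n_permutations = 29,
                       k = 5)
  match_row <- which(tab$dataset_id == "d1" & tab$sets == "1:10" &
                     tab$aggregation == "SVD" & tab$learner == "svm")
  expect_equal(tab$mean_accuracy[match_row], solo$mean_accuracy)
})

test_that("design enumeration reproduces the factorial cardinalities", {
  g <- design_grid(n_datasets = 2, n_folds = 3)
  expect_equal(nrow(g$workflow_grid), 2 * 3 * 22 * 4 * 5 * 2 * 3)
  expect_equal(length(factor3_alternatives()), 22L)
  cnt <- design_counts(n_datasets = 2, n_folds = 3)
  expect_equal(cnt$workflow_executions, 2 * 3 * 22 * 4 * 5 * 2 * 3)
  expect_equal(cnt$set_level_measurements, cnt$workflow_executions / 3)
  expect_equal(cnt$baseline_executions, 5 * 2 * 3)
  expect_equal(cnt$baseline_measurements, 5 * 2)
})

test_that("random-collection configurations run against a matched control", {
  sim <- generate_synthetic(synthetic_spec(n_sets = 15, n_signal = 3, seed = 61))
  cfg <- experiment_config(gene_sets = "RANDOM", ranking = "SAMGS", sets = "1",
                           aggregation = "AVG", learner = "nb",
                           dataset_id = "d1", seed = 3)
  rec <- run_workflow(cfg, sim$dataset, sim$collection, n_permutations = 29,
                      return_details = TRUE)
  expect_true(all(grepl("_RND$", rec$details[[1]]$selected)))
})
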