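mk_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    cfg <- list(gene_sets = df$gene_sets[i] %||% "GENUINE",
                ranking = df$ranking[i], sets = df$sets[i],
                aggregation = df$aggregation[i], learner = df$learner[i],
                dataset_id = df$dataset_id[i], seed = 1L)
    class(cfg) <- "experiment_config"
    structure(list(config = cfg, fold_accuracies = rep(df$acc[i], 10),
                   mean_accuracy = df$acc[i]),
              class = "accuracy_record")
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("paired Wilcoxon matches exact sign-assignment enumeration for n <= 8", {
  set.seed(5)
  for (n in c(4, 6, 8)) {
    base <- runif(n, 0.5, 0.9)
    d <- rnorm(n, 0.02, 0.05)  # continuous: no ties, no zeros
    df <- data.frame(ranking = "GLOBAL", sets = "1:10",
                     aggregation = rep(c("AVG", "SVD"), each = n),
                     learner = "svm", dataset_id = rep(paste0("d", 1:n), 2),
                     acc = c(base, base + d))
    rep_g <- paired_wilcoxon(mk_records(df), "aggregation", "AVG", "SVD", "greater")
    expect_equal(rep_g$n_pairs, n)
    expect_equal(rep_g$p_value, oracle_signed_rank_p(d, "greater"), tolerance = 1e-12)
    rep_2 <- paired_wilcoxon(mk_records(df), "aggregation", "AVG", "SVD")
    expect_equal(rep_2$p_value, oracle_signed_rank_p(d, "two.sided"), tolerance = 1e-12)
  }
})

test_that("uniform advantage yields a tiny one-sided p and the right direction", {
  base <- seq(0.5, 0.88, length.out = 20)
  adv <- seq(0.03, 0.08, length.out = 20)  # distinct, all positive
  df <- data.frame(ranking = "GLOBAL", sets = "1:10",
                   aggregation = rep(c("AVG", "SVD"), each = 20),
                   learner = "svm", dataset_id = rep(paste0("d", 1:20), 2),
                   acc = c(base, base + adv))
  rep <- paired_wilcoxon(mk_records(df), "aggregation", "AVG", "SVD", "greater")
  expect_lt(rep$p_value, 0.001)
  expect_equal(rep$direction, "SVD")
  # identical records on both sides -> all differences zero
  df0 <- df; df0$acc <- rep(base, 2)
  expect_error(paired_wilcoxon(mk_records(df0), "aggregation", "AVG", "SVD"),
               "all differences zero")
  # a missing combination on one side drops that pair
  dfm <- df[-nrow(df), ]
  repm <- paired_wilcoxon(mk_records(dfm), "aggregation", "AVG", "SVD", "greater")
  expect_equal(repm$n_pairs, 19)
})

test_that("Bonferroni-Dunn adjustment multiplies and caps", {
  expect_equal(bonferroni_dunn_adjust(0.0017, 3), 0.0051)
  expect_equal(bonferroni_dunn_adjust(0.5, 3), 1.0)
  expect_equal(bonferroni_dunn_adjust(c(0.2, 0.04), 2), c(0.4, 0.08))
  expect_equal(bonferroni_dunn_adjust(0.3, 1), 0.3)
  expect_error(bonferroni_dunn_adjust(1.2, 3), "\\[0, 1\\]")
  expect_error(bonferroni_dunn_adjust(c(0.1, 0.2), 1), "m must be")
})

test_that("median ranking table pools accuracies and sorts by median", {
  df <- data.frame(ranking = c("GLOBAL", "GLOBAL", "SAMGS", "SAMGS"),
                   sets = "1:10", aggregation = "SVD", learner = "svm",
                   dataset_id = c("d1", "d2", "d1", "d2"),
                   acc = c(0.6, 0.8, 0.9, 0.95))
  tab <- median_ranking_table(mk_records(df))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$median[tab$combo == "1:10 | GLOBAL | SVD"], 0.7)
  # iqr by linear interpolation (type 7): quantile(c(.6,.8)) -> .65/.75
  expect_equal(tab$iqr[tab$combo == "1:10 | GLOBAL | SVD"], 0.1, tolerance = 1e-12)
  expect_equal(tab$combo[1], "1:10 | SAMGS | SVD")  # dominating combo first
  # all-equal accuracies give sd = iqr = 0
  df2 <- df; df2$acc <- 0.7
  tab2 <- median_ranking_table(mk_records(df2))
  expect_true(all(tab2$sd == 0) && all(tab2$iqr == 0))
})

test_that("sub-rank table follows the average-rank convention and conserves ranks", {
  grid <- expand.grid(ranking = c("GLOBAL", "SAMGS", "GSEA"),
                      dataset_id = c("d1", "d2"), learner = c("svm", "nb"),
                      stringsAsFactors = FALSE)
  grid$sets <- "1"; grid$aggregation <- "AVG"
  set.seed(2); grid$acc <- runif(nrow(grid))
  # make GLOBAL dominate everywhere
  grid$acc[grid$ranking == "GLOBAL"] <- grid$acc[grid$ranking == "GLOBAL"] + 1
  tab <- subrank_table(mk_records(grid))
  expect_equal(tab$combo[1], "1 | GLOBAL | AVG")
  expect_equal(tab$avg_subrank[1], 1.0)
  # rank conservation: average of averages = (n_combos + 1) / 2
  expect_equal(mean(tab$avg_subrank), (3 + 1) / 2)
  # exact tie in one cell -> average rank 1.5 for both
  grid2 <- grid[grid$ranking != "GSEA", ]
  grid2$acc <- rep(0.5, nrow(grid2))
  grid2$acc[grid2$ranking == "GLOBAL" & grid2$dataset_id == "d1"] <- 0.9
  tab2 <- subrank_table(mk_records(grid2))
  expect_equal(sort(tab2$avg_subrank), c(1.25, 1.75))
  # missing cell errors with the combo named
  expect_error(subrank_table(mk_records(grid[-1, ])), "GLOBAL")
})

test_that("accuracy trend is the least-squares line", {
  expect_equal(accuracy_trend(1:5, rep(0.8, 5))$slope, 0)
  tr <- accuracy_trend(c(1, 2), c(0.9, 0.7))
  expect_equal(tr$slope, -0.2); expect_equal(tr$intercept, 1.1)
  expect_error(accuracy_trend(c(2, 2), c(0.5, 0.6)), "distinct")
})

test_that("gene-set group statistics compute sizes and PCA dimensionality", {
  # rank-1 set: 3 perfectly correlated genes -> 1 component at 50% and 90%
  set.seed(9)
  base <- rnorm(20)
  v1 <- rbind(base, 2 * base, -base)
  # flat spectrum: 10 exactly uncorrelated, equal-variance genes via an
  # orthonormal design -> ceil(0.9 * 10) = 9 components at 90%
  q <- qr.Q(qr(scale(matrix(rnorm(20 * 10), 20, 10), center = TRUE, scale = FALSE)))
  v2 <- t(q) * sqrt(19)
  v <- rbind(v1, v2, matrix(rnorm(2 * 20), 2, 20))
  rownames(v) <- paste0("g", seq_len(nrow(v)))
  colnames(v) <- paste0("s", 1:20)
  ds <- make_dataset(v, rep(c("a", "b"), each = 10))
  groups <- list(
    corr = gene_set_collection(list(gene_set("corr3", c("g1", "g2", "g3"),
                                             category = "CGP"))),
    flat = gene_set_collection(list(gene_set("flat10", paste0("g", 4:13)))),
    partial = gene_set_collection(list(gene_set("part", c("g14", "g15", "gZZ")))))
  out <- gene_set_group_stats(groups, ds)
  per <- out$per_set
  expect_equal(per$pca50[per$set == "corr3"], 1)
  expect_equal(per$pca90[per$set == "corr3"], 1)
  expect_equal(per$pca90[per$set == "flat10"], 9)
  expect_equal(per$pca50[per$set == "flat10"], 5)
  # nominal >= effective always
  expect_true(all(per$nominal_size >= per$effective_size))
  expect_equal(per$effective_size[per$set == "part"], 2)
  # adjusted p respects the stated family size
  expect_equal(out$bonferroni_m, 3 * 4)
  expect_true(all(out$tests$p_adjusted >= out$tests$p_value, na.rm = TRUE))
})

test_that("reports are pure functions of the records (serialization round-trip)", {
  df <- data.frame(ranking = c("GLOBAL", "SAMGS"), sets = "1",
                   aggregation = "AVG", learner = "svm",
                   dataset_id = "d1", acc = c(0.8, 0.7))
  recs <- mk_records(df)
  tab1 <- median_ranking_table(recs)
  rt <- records_table(recs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rt, path, sep = "\t", row.names = FALSE, quote = FALSE)
  rt2 <- read.delim(path, stringsAsFactors = FALSE)
  tab2 <- median_ranking_table(rt2)
  expect_equal(tab2, tab1)
})
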