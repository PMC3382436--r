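test_that("signal-to-noise gene scores match hand arithmetic and cap degenerate cases", {
  ds <- make_dataset(rbind(c(5, 5, 5, 5),     # constant gene
                           c(2, 2, 0, 0),     # zero variance, unequal means
                           c(1, 3, 0, 2)),    # sd(1,3) = sd(0,2) = sqrt(2)
                     c("a", "a", "b", "b"))
  s <- gene_level_snr(ds)
  expect_equal(unname(s[1]), 0)
  expect_equal(unname(s[2]), 1e6)
  expect_equal(unname(s[3]), 1 / (2 * sqrt(2)), tolerance = 1e-12)
  expect_error(gene_level_snr(make_dataset(matrix(1:4, 1), c("a", "b", "b", "b"))),
               "at least 2 samples")
})

test_that("enrichment score handles single-member boundary sets", {
  ds <- make_dataset(rbind(c(3, 3, 0, 0), c(0, 0, 3, 3)), c("a", "a", "b", "b"))
  # gene 1 ranks top (positive snr), gene 2 bottom
  expect_equal(gsea_enrichment_score(ds, gene_set("top", "g1")), 1.0)
  expect_equal(gsea_enrichment_score(ds, gene_set("bot", "g2")), -1.0)
  expect_error(gsea_enrichment_score(ds, gene_set("none", "g9")), "empty effective")
  expect_error(gsea_enrichment_score(ds, gene_set("all", c("g1", "g2"))),
               "miss decrement")
})

test_that("enrichment score equals the brute-force running-sum walk", {
  # deterministic 4-gene fixture with scores (2, 1, -1, -2): set = ranks 1 and 4
  v <- rbind(c(2, 2, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 2, 2)) * sqrt(2)
  ds <- make_dataset(v + matrix(rep(c(0.1, -0.1), each = 8), 4, 4, byrow = TRUE),
                     c("a", "a", "b", "b"))
  s <- gene_level_snr(ds)
  gs <- gene_set("ends", c("g1", "g4"))
  hit <- rownames(ds$values) %in% gs$genes
  expect_equal(gsea_enrichment_score(ds, gs), oracle_es_walk(unname(s), hit))

  # randomized fixtures, several seeds and weight exponents
  for (seed in 1:5) {
    ds <- random_dataset(12, 4, 4, seed = seed)
    set.seed(seed + 100)
    gs <- gene_set("r", sample(ds$genes, 4))
    hit <- ds$genes %in% gs$genes
    s <- unname(gene_level_snr(ds))
    for (w in c(0, 1, 1.5)) {
      expect_equal(gsea_enrichment_score(ds, gs, weight_exponent = w),
                   oracle_es_walk(s, hit, w), tolerance = 1e-12)
    }
  }
})

test_that("enrichment score lies in [-1, 1] and is sample/gene-order invariant", {
  for (seed in 1:5) {
    ds <- random_dataset(20, 5, 5, seed = seed)
    gs <- gene_set("r", ds$genes[c(2, 9, 15)])
    es <- gsea_enrichment_score(ds, gs)
    expect_gte(es, -1); expect_lte(es, 1)
    perm_g <- sample(ds$genes); perm_s <- sample(ds$samples)
    ds2 <- make_dataset(ds$values[perm_g, perm_s],
                        ds$classes[ds$labels[perm_s] + 1L])
    expect_equal(gsea_enrichment_score(ds2, gs), es, tolerance = 1e-12)
  }
})

test_that("SAM-GS statistic is the centroid distance", {
  ds <- make_dataset(rbind(c(0, 0, 2, 2), c(0, 2, 0, 2)), c("a", "a", "b", "b"))
  gs <- gene_set("s", c("g1", "g2"))
  expect_equal(samgs_statistic(ds, gs), 2.0)  # centroids (0,1) vs (2,1)
  ds_eq <- make_dataset(rbind(c(1, 2, 1, 2), c(3, 4, 3, 4)), c("a", "a", "b", "b"))
  expect_equal(samgs_statistic(ds_eq, gs), 0)
  ds2 <- make_dataset(ds$values * 2, c("a", "a", "b", "b"))
  expect_equal(samgs_statistic(ds2, gs), 2 * samgs_statistic(ds, gs))
  expect_gte(samgs_statistic(random_dataset(6, 3, 3), gene_set("s", "g1")), 0)
})

test_that("global test statistic detects alignment and rejects degenerate sets", {
  # single gene orthogonal to the centered labels -> Q = 0
  ds <- make_dataset(rbind(c(1, -1, 1, -1)), c("a", "a", "b", "b"))
  expect_equal(global_test_statistic(ds, gene_set("s", "g1")), 0, tolerance = 1e-12)
  # aligned gene -> Q grows with alignment
  ds2 <- make_dataset(rbind(c(-1, -1, 1, 1), c(1, -1, 1, -1)), c("a", "a", "b", "b"))
  q_aligned <- global_test_statistic(ds2, gene_set("a", "g1"))
  q_orth <- global_test_statistic(ds2, gene_set("o", "g2"))
  expect_gt(q_aligned, q_orth)
  # all-constant set errors
  ds3 <- make_dataset(rbind(c(1, 1, 1, 1)), c("a", "a", "b", "b"))
  expect_error(global_test_statistic(ds3, gene_set("c", "g1")), "constant")
  expect_gte(global_test_statistic(random_dataset(8, 4, 4), gene_set("s", c("g1", "g2"))), 0)
})

test_that("null global test statistic sits mid-quantile under exhaustive permutation", {
  # class-symmetric noise set: observed Q must not be extreme among all 6
  # balanced labelings of a 2+2 toy
  set.seed(8)
  v <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  ds <- make_dataset(v, c("a", "a", "b", "b"))
  gs <- gene_set("s", c("g1", "g2"))
  res <- permutation_pvalue("GLOBAL", ds, gs, exhaustive = TRUE)
  expect_gte(res$p, 1 / 3)  # frozen from the 6-labeling enumeration: p = 2/3
  expect_lt(res$p, 1)
  expect_equal(res$p, 2 / 3, tolerance = 1e-12)
})

test_that("permutation p-values follow the add-one rule and match exact enumeration", {
  ds <- random_dataset(10, 4, 4, seed = 3)
  gs <- gene_set("s", ds$genes[1:3])
  # statistic constant under all labelings -> p = 1
  ds_const <- make_dataset(matrix(rep(c(1, 2, 3, 4), times = 4), 4, 4,
                                  dimnames = list(paste0("g", 1:4), paste0("s", 1:4))),
                           c("a", "a", "b", "b"))
  res <- permutation_pvalue("SAMGS", ds_const, gene_set("s", c("g1", "g2")),
                            n_permutations = 99, seed = 1)
  expect_equal(res$p, 1.0)

  # observed exceeding all B = 99 permuted values -> p = 0.01
  sim <- generate_synthetic(synthetic_spec(n_sets = 5, n_signal = 1, delta = 4,
                                           n0 = 10, n1 = 10, seed = 2))
  sig <- sim$collection$sets[[sim$signal_sets[1]]]
  res2 <- permutation_pvalue("SAMGS", sim$dataset, sig, n_permutations = 99, seed = 1)
  expect_equal(res2$p, 0.01)

  # exhaustive enumeration on a 2+2 toy equals the literal oracle
  ds22 <- random_dataset(6, 2, 2, seed = 9)
  gs22 <- gene_set("s", ds22$genes[1:3])
  for (meth in c("SAMGS", "GLOBAL")) {
    got <- permutation_pvalue(meth, ds22, gs22, exhaustive = TRUE)
    stat_fun <- function(l) {
      d <- make_dataset(ds22$values, c("a", "b")[l + 1L])
      if (meth == "SAMGS") samgs_statistic(d, gs22) else global_test_statistic(d, gs22)
    }
    expect_equal(got$p, oracle_exhaustive_p(unname(ds22$labels), stat_fun))
  }
  got_g <- permutation_pvalue("GSEA", ds22, gs22, exhaustive = TRUE)
  stat_fun_g <- function(l) gsea_enrichment_score(
    make_dataset(ds22$values, c("a", "b")[l + 1L]), gs22)
  expect_equal(got_g$p,
               oracle_exhaustive_p(unname(ds22$labels), stat_fun_g, two_sided = TRUE))
})

test_that("rank_gene_sets recovers a planted set first for all three methods", {
  sim <- generate_synthetic(synthetic_spec(
    n_sets = 2, n_signal = 1, set_sizes = c(10, 10), delta = 2,
    n0 = 20, n1 = 20, background = 20, seed = 42))
  for (meth in c("GSEA", "SAMGS", "GLOBAL")) {
    rk <- rank_gene_sets(sim$dataset, sim$collection, meth,
                         n_permutations = 199, seed = 7)
    expect_equal(rk$entries$set[1], sim$signal_sets)
  }
})

test_that("rank_gene_sets is deterministic, order-invariant, and well-formed", {
  sim <- generate_synthetic(synthetic_spec(n_sets = 8, n_signal = 2, n0 = 10,
                                           n1 = 10, seed = 4))
  rk1 <- rank_gene_sets(sim$dataset, sim$collection, "SAMGS",
                        n_permutations = 49, seed = 5)
  rk2 <- rank_gene_sets(sim$dataset, sim$collection, "SAMGS",
                        n_permutations = 49, seed = 5)
  expect_identical(rk1$entries, rk2$entries)
  expect_setequal(rk1$entries$rank, seq_len(rk1$n))
  expect_true(all(rk1$entries$p_value >= 0 & rk1$entries$p_value <= 1))
  # shuffled collection order leaves ranks unchanged
  shuf <- gene_set_collection(sim$collection$sets[sample(length(sim$collection))])
  rk3 <- rank_gene_sets(sim$dataset, shuf, "SAMGS", n_permutations = 49, seed = 5)
  expect_equal(rk3$entries, rk1$entries)
  # single-set collection ranks it 1 regardless of p
  one <- rank_gene_sets(sim$dataset, sim$collection[1], "SAMGS",
                        n_permutations = 19, seed = 1)
  expect_equal(one$entries$rank, 1L)
  # sets absent from the dataset are dropped with a warning
  with_ghost <- gene_set_collection(c(sim$collection$sets,
                                      list(gene_set("GHOST", c("zz1", "zz2")))))
  expect_warning(rk4 <- rank_gene_sets(sim$dataset, with_ghost, "SAMGS",
                                       n_permutations = 19, seed = 1),
                 "dropped")
  expect_equal(rk4$n, length(sim$collection))
})

test_that("ranking exports TSV and JSON faithfully", {
  sim <- generate_synthetic(synthetic_spec(n_sets = 5, n_signal = 1, n0 = 8,
                                           n1 = 8, seed = 6))
  rk <- rank_gene_sets(sim$dataset, sim$collection, "GLOBAL",
                       n_permutations = 19, seed = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_ranking(rk, tsv, "tsv")
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$set, rk$entries$set)
  expect_equal(back$statistic, rk$entries$statistic, tolerance = 1e-12)
  js <- withr::local_tempfile(fileext = ".json")
  export_ranking(rk, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$entries$rank, rk$entries$rank)
})
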