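# Independent oracles used to cross-check the package's implementations.
# These deliberately use the most literal (brute-force) formulation of each
# quantity and share no code with the package internals.

# Literal step-by-step GSEA running-sum walk over the full gene list.
# scores: per-gene association scores; hit: logical membership vector.
# Returns the running-sum value of maximum |deviation| (first reached).
oracle_es_walk <- function(scores, hit, w = 1) {
  o <- order(-scores, seq_along(scores))
  s <- scores[o]; h <- hit[o]
  p <- length(s); nh <- sum(h)
  nr <- sum(abs(s[h])^w)
  run <- numeric(p)
  cur <- 0
  for (t in seq_len(p)) {
    cur <- cur + if (h[t]) {
      if (nr == 0) 1 / nh else abs(s[t])^w / nr
    } else -1 / (p - nh)
    run[t] <- cur
  }
  run[which.max(abs(run))]
}

# Exact permutation p-value by full enumeration of balanced label
# assignments; statistic_fun(labels01) -> numeric. two_sided compares |stat|.
oracle_exhaustive_p <- function(labels, statistic_fun, two_sided = FALSE) {
  n <- length(labels); n0 <- sum(labels == 0L)
  obs <- statistic_fun(labels)
  idx <- utils::combn(n, n0)
  stats <- apply(idx, 2L, function(i) {
    l <- rep.int(1L, n); l[i] <- 0L
    statistic_fun(l)
  })
  if (two_sided) mean(abs(stats) >= abs(obs)) else mean(stats >= obs)
}

# Exhaustive best-binary-split information gain (bits).
oracle_ig <- function(x, y) {
  ent <- function(v) {
    p <- table(factor(v, levels = 0:1)) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  xs <- sort(unique(x))
  if (length(xs) < 2L) return(0)
  thr <- (head(xs, -1) + tail(xs, -1)) / 2
  best <- Inf
  for (t in thr) {
    l <- y[x <= t]; r <- y[x > t]
    best <- min(best, length(l) / length(y) * ent(l) +
                       length(r) / length(y) * ent(r))
  }
  ent(y) - best
}

# Exact signed-rank p-value by enumerating all 2^n sign assignments of the
# (zero-free, tie-free) differences d.
oracle_signed_rank_p <- function(d, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  if (alternative == "greater") return(mean(v_all >= v_obs))
  min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
}

# Tiny deterministic labelled dataset builder.
make_dataset <- function(values, labels) {
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_dataset(values, stats::setNames(labels, colnames(values)))
}

# Random dataset with given class sizes under a fixed seed.
random_dataset <- function(p, n0, n1, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(p * (n0 + n1)), p, n0 + n1)
  make_dataset(v, rep(c("a", "b"), c(n0, n1)))
}
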