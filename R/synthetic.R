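#' Specification of a synthetic expression benchmark
#'
#' Parameters of the simulator that every stage of the framework is
#' validated against: a binary-class expression matrix in which member genes
#' of each gene set share a latent factor (pairwise equicorrelation rho) and
#' the member genes of a few \emph{signal} sets additionally carry a
#' class-dependent mean shift delta. The defaults describe the benchmark
#' conditions used throughout the package's validation suites: 30 + 30
#' samples, 100 sets of 10-20 genes, 3 signal sets, delta = 1.5 expression
#' units, rho = 0.3, unit noise sd.
#'
#' @param p total number of genes; by default the set blocks plus
#'   \code{background} unassigned noise genes.
#' @param n0,n1 samples per class (class 0 / class 1; the shift is added to
#'   class 1).
#' @param n_sets number of gene sets in the collection.
#' @param set_sizes either a length-2 range within [5, 200] from which sizes
#'   are drawn uniformly, or an explicit size vector of length
#'   \code{n_sets} (e.g. copied from a template collection).
#' @param n_signal number of signal sets (<= n_sets).
#' @param delta class-1 mean shift per signal gene, in expression units.
#' @param rho within-set equicorrelation, 0 <= rho < 1.
#' @param sigma noise standard deviation (> 0).
#' @param background extra genes belonging to no set (default 100).
#' @param overlap if TRUE, sets draw their genes uniformly from the whole
#'   gene universe (sets may overlap; overlapping genes carry the structure
#'   of the last set generated); default FALSE: disjoint gene blocks.
#' @param variance_factor optional multiplier of the class-1 noise sd in
#'   signal sets (a variance-shift signal variant; not used by the default
#'   validation suites).
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return An object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(p = NULL, n0 = 30L, n1 = 30L, n_sets = 100L,
                           set_sizes = c(10L, 20L), n_signal = 3L,
                           delta = 1.5, rho = 0.3, sigma = 1,
                           background = 100L, overlap = FALSE,
                           variance_factor = NULL, seed = 1L) {
  if (n_signal > n_sets) stop("n_signal must not exceed n_sets")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (sigma <= 0) stop("sigma must be positive")
  if (n0 < 2L || n1 < 2L) stop("each class needs at least 2 samples")
  if (length(set_sizes) == 2L && is.null(dim(set_sizes))) {
    if (set_sizes[1L] < 5L || set_sizes[2L] > 200L || set_sizes[1L] > set_sizes[2L])
      stop("set size range must lie within [5, 200]")
  } else if (length(set_sizes) == n_sets) {
    if (any(set_sizes < 5L) || any(set_sizes > 200L))
      stop("explicit set sizes must lie within [5, 200]")
  } else stop("set_sizes must be a range c(min, max) or a vector of length n_sets")
  structure(list(p = p, n0 = as.integer(n0), n1 = as.integer(n1),
                 n_sets = as.integer(n_sets), set_sizes = set_sizes,
                 n_signal = as.integer(n_signal), delta = delta, rho = rho,
                 sigma = sigma, background = as.integer(background),
                 overlap = overlap, variance_factor = variance_factor,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic benchmark spec: ", x$n0, "+", x$n1, " samples, ",
      x$n_sets, " sets (", x$n_signal, " signal), delta=", x$delta,
      ", rho=", x$rho, ", sigma=", x$sigma, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic benchmark dataset
#'
#' Draws an expression dataset, a matched gene-set collection and the names
#' of the planted signal sets from a \code{\link{synthetic_spec}}. Member
#' genes of each set are built from a shared latent factor,
#' x = sqrt(rho) z_set + sqrt(1 - rho) eps, scaled by sigma, giving exact
#' pairwise population correlation rho within the set and variance sigma^2;
#' genes outside every set are i.i.d. Normal(0, sigma^2); member genes of the
#' signal sets receive the additional mean delta in class-1 samples. Class 0
#' is labelled "A", class 1 "B" (lexicographic order preserves the 0/1
#' coding on re-reading).
#'
#' @param spec a \code{synthetic_spec}.
#' @return List with \code{dataset} (an \code{expression_dataset}),
#'   \code{collection} (a \code{gene_set_collection}), \code{signal_sets}
#'   (character vector of planted set names) and \code{spec}.
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_sets = 10, n_signal = 2, seed = 1))
#' sim$dataset
#' sim$signal_sets
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng())
  n <- spec$n0 + spec$n1
  # a length-2 set_sizes vector is always read as a range (documented);
  # draw via index to dodge sample()'s scalar-x behavior on degenerate ranges
  sizes <- if (length(spec$set_sizes) == 2L) {
    rng_sz <- seq.int(spec$set_sizes[1L], spec$set_sizes[2L])
    rng_sz[sample.int(length(rng_sz), spec$n_sets, replace = TRUE)]
  } else as.integer(spec$set_sizes)
  total <- sum(sizes)
  p <- spec$p %||% (if (spec$overlap) max(sizes) + spec$background
                    else total + spec$background)
  if (!spec$overlap && p < total)
    stop("p too small for ", spec$n_sets, " disjoint sets of total size ", total)
  if (spec$overlap && p < max(sizes))
    stop("p smaller than the largest requested set")
  gene_ids <- sprintf("g%05d", seq_len(p))
  sample_ids <- sprintf("s%03d", seq_len(n))
  labels <- stats::setNames(rep(c("A", "B"), c(spec$n0, spec$n1)), sample_ids)
  class1 <- labels == "B"
  set_names <- sprintf("GS%03d", seq_len(spec$n_sets))
  signal <- sort(sample.int(spec$n_sets, spec$n_signal))
  members <- vector("list", spec$n_sets)
  if (spec$overlap) {
    for (k in seq_len(spec$n_sets))
      members[[k]] <- sort(sample.int(p, sizes[k]))
  } else {
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (k in seq_len(spec$n_sets))
      members[[k]] <- seq.int(starts[k], stops[k])
  }
  values <- matrix(stats::rnorm(p * n, 0, spec$sigma), p, n,
                   dimnames = list(gene_ids, sample_ids))
  for (k in seq_len(spec$n_sets)) {
    idx <- members[[k]]
    m <- length(idx)
    z <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(m * n), m, n)
    block <- spec$sigma * (sqrt(spec$rho) * rep(z, each = m) +
                           sqrt(1 - spec$rho) * eps)
    if (k %in% signal) {
      block[, class1] <- block[, class1] + spec$delta
      if (!is.null(spec$variance_factor))
        block[, class1] <- spec$delta +
          (block[, class1] - spec$delta) * spec$variance_factor
    }
    values[idx, ] <- block
  }
  sets <- lapply(seq_len(spec$n_sets), function(k)
    gene_set(set_names[k], gene_ids[members[[k]]],
             description = if (k %in% signal) "signal" else "noise"))
  list(dataset = expression_dataset(values, labels),
       collection = gene_set_collection(sets),
       signal_sets = set_names[signal],
       spec = spec)
}

#' Generate a matched null benchmark (no planted signal)
#'
#' Identical to \code{\link{generate_synthetic}} with the mean shift forced
#' to zero: labels are independent of the data by construction and the
#' ground-truth signal list is empty. Used for type-I-error calibration of
#' the ranking statistics.
#'
#' @param spec a \code{synthetic_spec} (its \code{delta} is ignored).
#' @return As \code{generate_synthetic}, with empty \code{signal_sets}.
#' @export
generate_null <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spec$delta <- 0
  spec$variance_factor <- NULL
  out <- generate_synthetic(spec)
  out$signal_sets <- character(0L)
  out
}
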