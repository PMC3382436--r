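#' Average aggregation of one sample over a gene set
#'
#' The simplest set-level feature: the arithmetic mean of the sample's
#' expressions over the set's effective genes. Depends on the one sample
#' only, not on other samples or on class labels.
#'
#' @param sample_expressions numeric vector of the sample's expressions over
#'   a non-empty effective set.
#' @return The mean expression.
#' @export
aggregate_avg <- function(sample_expressions) {
  if (length(sample_expressions) == 0L) stop("empty effective set")
  mean(sample_expressions)
}

#' Fit a set-level aggregation model on training data
#'
#' Learns, on the training samples only, the per-set state needed to map any
#' sample (training or unseen) to one feature value per selected gene set:
#' \describe{
#'   \item{AVG}{the effective gene list (stateless averaging).}
#'   \item{SVD}{per-gene training means and the unit-norm direction of
#'     maximum training variance in the set's expression subspace; samples
#'     are centered with the training means and projected onto it. The
#'     direction's sign is fixed so that its largest-magnitude loading is
#'     positive, making results reproducible across linear-algebra back-ends.}
#'   \item{SETSIG}{the training samples' effective-set expressions and class
#'     labels; a sample's feature is the pooled-variance two-sample
#'     t statistic contrasting its Pearson correlations with class-0 vs
#'     class-1 training samples (positive = correlates rather with class 0).}
#'   \item{NONE}{no aggregation: the ordered union of the selected sets'
#'     unique effective genes, each passed through as its own feature.}
#' }
#'
#' @param train an \code{\link{expression_dataset}} of training samples.
#' @param selected_sets list of \code{gene_set} objects (typically the
#'   top-ranked sets, in rank order) or a \code{gene_set_collection}.
#' @param mode one of \code{"AVG"}, \code{"SVD"}, \code{"SETSIG"}, \code{"NONE"}.
#' @param self_exclude for SETSIG: when the evaluated sample is itself one of
#'   the stored references (matched by sample identifier), exclude it from
#'   its own class's correlation population (default TRUE; its
#'   self-correlation of 1 would bias the statistic).
#' @param cap magnitude returned by SETSIG when the pooled variance is zero
#'   but the population means differ.
#' @return An object of class \code{"aggregation_model"}.
#' @export
fit_aggregation <- function(train, selected_sets,
                            mode = c("AVG", "SVD", "SETSIG", "NONE"),
                            self_exclude = TRUE, cap = 1e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "expression_dataset"))
  if (inherits(selected_sets, "gene_set_collection"))
    selected_sets <- selected_sets$sets
  if (length(selected_sets) == 0L) stop("no selected sets")
  nm <- vapply(selected_sets, `[[`, character(1L), "name")
  eff <- lapply(selected_sets, effective_set, dataset = train)
  if (any(vapply(eff, length, integer(1L)) == 0L))
    stop("empty effective set for: ",
         paste(nm[vapply(eff, length, integer(1L)) == 0L], collapse = ", "))
  state <- switch(mode,
    AVG = lapply(eff, function(g) list(genes = g)),
    SVD = lapply(eff, function(g) fit_svd_state(train, g)),
    SETSIG = lapply(eff, function(g) fit_setsig_state(train, g)),
    NONE = {
      union_genes <- train$genes[train$genes %in% unique(unlist(eff))]
      list(list(genes = union_genes))
    })
  if (mode != "NONE") names(state) <- nm
  structure(list(mode = mode, set_names = nm, state = state,
                 self_exclude = self_exclude, cap = cap),
            class = "aggregation_model")
}

#' @export
print.aggregation_model <- function(x, ...) {
  cat("Aggregation model (", x$mode, "), ",
      if (x$mode == "NONE") paste0(length(x$state[[1L]]$genes), " gene features")
      else paste0(length(x$set_names), " set feature(s)"), "\n", sep = "")
  invisible(x)
}

fit_svd_state <- function(train, eff_genes) {
  if (length(train$samples) < 2L) stop("SVD aggregation needs >= 2 training samples")
  m <- t(train$values[eff_genes, , drop = FALSE])   # samples x genes
  center <- colMeans(m)
  mc <- sweep(m, 2L, center)
  v <- svd(mc, nu = 0L, nv = 1L)$v[, 1L]
  j <- which.max(abs(v))
  if (v[j] < 0) v <- -v
  list(genes = eff_genes, center = center, direction = v)
}

fit_setsig_state <- function(train, eff_genes) {
  if (length(eff_genes) < 3L)
    stop("SETSIG needs an effective set of >= 3 genes")
  tab <- table(train$labels)
  if (any(tab < 2L))
    stop("SETSIG needs >= 2 training samples per class")
  list(genes = eff_genes,
       ref = train$values[eff_genes, , drop = FALSE],
       ref_labels = train$labels,
       ref_ids = train$samples)
}

#' Fit an SVD aggregation model for one gene set
#'
#' Convenience wrapper around \code{\link{fit_aggregation}} with
#' \code{mode = "SVD"} and a single set; see there for the construction.
#'
#' @param train training \code{expression_dataset} (>= 2 samples).
#' @param gene_set a \code{gene_set} with non-empty effective set.
#' @return A single-set \code{aggregation_model} of mode SVD.
#' @export
fit_svd <- function(train, gene_set) {
  fit_aggregation(train, list(gene_set), mode = "SVD")
}

#' Project a sample with a fitted SVD aggregation model
#'
#' Centers the sample's effective-set expressions with the stored training
#' means and returns the dot product with the stored maximum-variance
#' direction. A sample equal to the training mean vector maps to 0.
#'
#' @param model a single-set \code{aggregation_model} of mode SVD (see
#'   \code{\link{fit_svd}}).
#' @param sample_expressions named numeric vector of expressions covering the
#'   model's genes.
#' @return The projection value.
#' @export
apply_svd <- function(model, sample_expressions) {
  stopifnot(inherits(model, "aggregation_model"), model$mode == "SVD")
  st <- model$state[[1L]]
  x <- sample_vector(sample_expressions, st$genes)
  sum((x - st$center) * st$direction)
}

#' SetSig signature of a sample
#'
#' Pearson correlations are computed between the sample's effective-set
#' vector and each stored training sample's vector over the same genes; the
#' correlations split by training class into two populations, and the
#' pooled-variance Student t statistic for the difference of their means is
#' returned. Positive signatures indicate the sample correlates rather with
#' the class-0 references, negative with class-1.
#'
#' @param sample_expressions named numeric vector covering the model's genes;
#'   must have nonzero variance over the set.
#' @param model a single- or multi-set \code{aggregation_model} of mode
#'   SETSIG.
#' @param set which stored set to use (name or index, default first).
#' @param sample_id optional identifier of the evaluated sample; when it
#'   matches a stored reference and self-exclusion is on, that reference is
#'   left out of its class's population.
#' @return The t-statistic signature.
#' @export
setsig <- function(sample_expressions, model, set = 1L, sample_id = NULL) {
  stopifnot(inherits(model, "aggregation_model"), model$mode == "SETSIG")
  st <- model$state[[set]]
  x <- sample_vector(sample_expressions, st$genes)
  setsig_value(x, st, model$self_exclude, model$cap, sample_id)
}

setsig_value <- function(x, st, self_exclude, cap, sample_id = NULL) {
  if (stats::sd(x) == 0)
    stop("zero-variance sample vector; correlation undefined")
  keep <- rep.int(TRUE, length(st$ref_ids))
  if (self_exclude && !is.null(sample_id))
    keep <- st$ref_ids != sample_id
  r <- suppressWarnings(stats::cor(x, st$ref[, keep, drop = FALSE]))[1L, ]
  if (anyNA(r)) stop("zero-variance reference sample; correlation undefined")
  labs <- st$ref_labels[keep]
  a <- r[labs == 0L]; b <- r[labs == 1L]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("SETSIG needs >= 2 reference samples per class after self-exclusion")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  num <- mean(a) - mean(b)
  if (sp2 == 0) return(if (num == 0) 0 else sign(num) * cap)
  num / (sqrt(sp2) * sqrt(1 / na + 1 / nb))
}

sample_vector <- function(sample_expressions, genes) {
  if (is.null(names(sample_expressions)))
    stop("sample expressions must be named by gene")
  miss <- setdiff(genes, names(sample_expressions))
  if (length(miss))
    stop("sample missing required gene(s): ", paste(miss, collapse = ", "))
  as.numeric(sample_expressions[genes])
}

#' Build a set-level feature matrix with a fitted aggregation model
#'
#' Applies a training-fitted aggregation model identically to any samples
#' (training or testing), producing one column per selected set in rank order
#' for the aggregating modes, or one column per unique effective gene (in
#' dataset gene order) under NONE. Applying the model to the same samples
#' twice yields identical matrices.
#'
#' @param model an \code{\link{fit_aggregation}} result.
#' @param data an \code{expression_dataset}, or a genes-by-samples numeric
#'   matrix with gene rownames and sample colnames.
#' @return Numeric matrix, samples in rows, features in columns (set names,
#'   or gene identifiers under NONE).
#' @export
build_feature_matrix <- function(model, data) {
  stopifnot(inherits(model, "aggregation_model"))
  vals <- if (inherits(data, "expression_dataset")) data$values else data
  if (!is.matrix(vals) || is.null(rownames(vals)) || is.null(colnames(vals)))
    stop("'data' must be an expression_dataset or a named genes x samples matrix")
  samples <- colnames(vals)
  if (model$mode == "NONE") {
    genes <- model$state[[1L]]$genes
    miss <- setdiff(genes, rownames(vals))
    if (length(miss))
      stop("sample(s) missing required gene(s): ", paste(miss, collapse = ", "))
    return(t(vals[genes, , drop = FALSE]))
  }
  out <- matrix(NA_real_, nrow = length(samples), ncol = length(model$set_names),
                dimnames = list(samples, model$set_names))
  for (k in seq_along(model$state)) {
    st <- model$state[[k]]
    miss <- setdiff(st$genes, rownames(vals))
    if (length(miss))
      stop("sample(s) missing required gene(s): ", paste(miss, collapse = ", "))
    sub <- vals[st$genes, , drop = FALSE]
    out[, k] <- switch(model$mode,
      AVG = colMeans(sub),
      SVD = as.numeric(crossprod(sub - st$center, st$direction)),
      SETSIG = vapply(samples, function(s)
        setsig_value(sub[, s], st, model$self_exclude, model$cap, sample_id = s),
        numeric(1L)))
  }
  out
}
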