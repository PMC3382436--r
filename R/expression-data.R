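#' Construct an expression dataset
#'
#' Bundles a genes-by-samples matrix of normalized expression values with a
#' binary phenotype labelling of the samples. This is the central data
#' container of the package: rows are genes, columns are samples, and every
#' sample carries a class label in \{0, 1\}. The two original class strings are
#' mapped to 0/1 in lexicographic order, so the lexicographically smaller
#' class string always becomes class 0 (the "first" class; the sign convention
#' of SetSig signatures and of the signal-to-noise gene scores refers to it).
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers). All entries must be
#'   finite; the values are assumed to be already normalized.
#' @param labels either a named vector (names = sample identifiers) of class
#'   strings/integers, or an unnamed vector aligned with \code{colnames(values)}.
#'   Exactly two distinct classes must be present, each with at least one
#'   sample.
#' @return An object of class \code{"expression_dataset"}: a list with
#'   elements \code{genes}, \code{samples}, \code{values}, \code{labels}
#'   (named integer vector of 0/1) and \code{classes} (the two original class
#'   strings, \code{classes[1]} mapped to 0).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"))
#' ds
#' @export
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(genes))
    stop("duplicate gene identifier: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample identifier: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyNA(values) || !all(is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (is.null(names(labels))) {
    if (length(labels) != length(samples))
      stop("unnamed 'labels' must match the number of samples")
    names(labels) <- samples
  }
  missing <- setdiff(samples, names(labels))
  if (length(missing))
    stop("no class label for sample(s): ", paste(missing, collapse = ", "))
  labels <- labels[samples]
  cls <- sort(unique(as.character(labels)))
  if (length(cls) != 2L)
    stop("exactly two classes required, found ", length(cls))
  lab01 <- ifelse(as.character(labels) == cls[1L], 0L, 1L)
  names(lab01) <- samples
  if (min(table(lab01)) < 1L) stop("both classes must be non-empty")
  structure(list(genes = genes, samples = samples, values = values,
                 labels = lab01, classes = cls),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  n <- table(x$labels)
  cat("Expression dataset: ", length(x$genes), " genes x ",
      length(x$samples), " samples\n", sep = "")
  cat("Classes: '", x$classes[1L], "' (0, n=", n[["0"]], ")  '",
      x$classes[2L], "' (1, n=", n[["1"]], ")\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression dataset from TSV files
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and one row per gene whose first column is the gene identifier
#' (genes-in-rows, samples-in-columns; the common microarray export
#' convention). The labels file is a two-column tab-separated file without
#' header: sample identifier, class string; exactly two distinct class strings
#' must occur among the dataset's samples.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param labels_path path to the two-column labels TSV.
#' @return An \code{\link{expression_dataset}}.
#' @export
read_expression_dataset <- function(matrix_path, labels_path) {
  tab <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("matrix file must have a gene id column and at least one sample")
  gene_ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cells in expression matrix")
  rownames(vals) <- gene_ids
  lab <- utils::read.delim(labels_path, header = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (ncol(lab) < 2L) stop("labels file must have two columns (sample id, class)")
  if (anyDuplicated(lab[[1L]]))
    stop("duplicate sample identifier in labels file")
  labels <- stats::setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  extra <- setdiff(names(labels), colnames(vals))
  if (length(extra))
    warning("labels file mentions sample(s) not in the matrix: ",
            paste(extra, collapse = ", "))
  labels <- labels[names(labels) %in% colnames(vals)]
  expression_dataset(vals, labels)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of \code{\link{read_expression_dataset}}; the original class
#' strings are written to the labels file.
#'
#' @param dataset an \code{expression_dataset}.
#' @param matrix_path,labels_path output paths.
#' @export
write_expression_dataset <- function(dataset, matrix_path, labels_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tab <- data.frame(gene = dataset$genes, dataset$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  lab <- data.frame(sample = dataset$samples,
                    class = dataset$classes[dataset$labels + 1L])
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  invisible(dataset)
}

#' Subset an expression dataset by samples
#'
#' Used by the cross-validation harness to form training and testing views;
#' gene order is preserved, labels follow the retained samples.
#'
#' @param dataset an \code{expression_dataset}.
#' @param samples character vector of sample identifiers (or integer indices).
#' @return An \code{expression_dataset} restricted to the given samples. Both
#'   classes must remain represented.
#' @export
subset_samples <- function(dataset, samples) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.numeric(samples)) samples <- dataset$samples[samples]
  if (!all(samples %in% dataset$samples))
    stop("unknown sample identifier(s)")
  vals <- dataset$values[, samples, drop = FALSE]
  labels <- dataset$classes[dataset$labels[samples] + 1L]
  names(labels) <- samples
  expression_dataset(vals, labels)
}
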