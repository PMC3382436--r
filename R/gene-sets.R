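#' Construct a gene set
#'
#' @param name set name (non-empty string).
#' @param genes character vector of member gene identifiers; duplicates are
#'   not allowed.
#' @param description free-text description (kept as metadata, e.g. the GMT
#'   second field).
#' @param category optional provenance tag (e.g. "CGP" or "CP" for MSigDB
#'   chemical-and-genetic-perturbation vs canonical-pathway sets).
#' @return An object of class \code{"gene_set"}.
#' @export
gene_set <- function(name, genes, description = "", category = NA_character_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a non-empty string")
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes))
    stop("duplicate genes in set '", name, "'")
  structure(list(name = name, genes = genes, description = description,
                 category = category),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "' (", length(x$genes), " genes)\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Construct a gene-set collection
#'
#' An ordered list of \code{\link{gene_set}} objects with unique names.
#'
#' @param sets list of \code{gene_set} objects.
#' @return An object of class \code{"gene_set_collection"}.
#' @export
gene_set_collection <- function(sets = list()) {
  if (!all(vapply(sets, inherits, logical(1L), "gene_set")))
    stop("all elements must be gene_set objects")
  nm <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nm))
    stop("duplicate set name: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  structure(list(sets = sets), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- set_sizes(x)
  cat("Gene-set collection: ", length(x$sets), " sets", sep = "")
  if (length(sz)) cat(" (sizes ", min(sz), "-", max(sz), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
`[.gene_set_collection` <- function(x, i) gene_set_collection(x$sets[i])

#' Names of the sets in a collection
#' @param x a \code{gene_set_collection}.
#' @return Character vector of set names in collection order.
#' @export
set_names <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  unname(vapply(x$sets, `[[`, character(1L), "name"))
}

#' Nominal sizes of the sets in a collection
#' @param x a \code{gene_set_collection}.
#' @return Integer vector of set cardinalities, named by set.
#' @export
set_sizes <- function(x) {
  stopifnot(inherits(x, "gene_set_collection"))
  vapply(x$sets, function(s) length(s$genes), integer(1L))
}

#' Read a gene-set collection from a GMT file
#'
#' The Broad/MSigDB GMT dialect: one set per line,
#' \code{name TAB description TAB gene TAB gene ...}. Duplicate gene mentions
#' within one line are deduplicated with a warning; a line with fewer than
#' three fields or a repeated set name is an error. An empty file yields an
#' empty collection.
#'
#' @param path path to the GMT file.
#' @return A \code{\link{gene_set_collection}}; descriptions are retained as
#'   metadata and ignored for computation.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", k, " has fewer than 3 fields")
    genes <- f[-c(1L, 2L)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene mention(s) in set '", f[1L], "' deduplicated")
      genes <- unique(genes)
    }
    sets[[k]] <- gene_set(f[1L], genes, description = f[2L])
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a \code{gene_set_collection}.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s) {
    desc <- if (is.null(s$description) || !nzchar(s$description)) "na" else s$description
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = FALSE)
  invisible(collection)
}

#' Filter a collection by nominal set size
#'
#' Retains exactly the sets with \code{min_size <= |set| <= max_size},
#' preserving order. The defaults discard sets with fewer than 5 or more than
#' 200 genes, the usual curation filter for set-level analysis.
#'
#' @param collection a \code{gene_set_collection}.
#' @param min_size,max_size inclusive size bounds; \code{1 <= min_size <= max_size}.
#' @return The filtered collection.
#' @export
filter_by_size <- function(collection, min_size = 5L, max_size = 200L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (min_size < 1L || min_size > max_size)
    stop("require 1 <= min_size <= max_size")
  sz <- set_sizes(collection)
  gene_set_collection(collection$sets[sz >= min_size & sz <= max_size])
}

#' Effective set of a gene set in a dataset
#'
#' The genes of a set actually measured in a dataset, returned in dataset
#' gene order (deterministic). Its length is the set's \emph{effective size}.
#'
#' @param gene_set a \code{gene_set}.
#' @param dataset an \code{expression_dataset}.
#' @return Character vector (possibly empty) of gene identifiers.
#' @export
effective_set <- function(gene_set, dataset) {
  stopifnot(inherits(gene_set, "gene_set"), inherits(dataset, "expression_dataset"))
  dataset$genes[dataset$genes %in% gene_set$genes]
}

#' Pooled gene universe of a collection
#'
#' The union of all member genes over the collection's sets — the sampling
#' pool used when constructing size-matched randomized control collections.
#'
#' @param collection a non-empty \code{gene_set_collection}.
#' @return Character vector of unique gene identifiers (first-occurrence order).
#' @export
gene_pool <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop("empty collection has no gene pool")
  unique(unlist(lapply(collection$sets, `[[`, "genes"), use.names = FALSE))
}

#' Randomize a gene-set collection
#'
#' Builds a biologically meaningless control collection matched to the input
#' in set count and in the multiset of set cardinalities: for every genuine
#' set of size m, m genes are sampled without replacement, uniformly, from
#' the pooled gene universe of the genuine collection. Draws are independent
#' across sets (a gene may recur in several random sets, as it may in the
#' genuine collection). Deterministic under \code{seed}.
#'
#' @param collection a \code{gene_set_collection}.
#' @param seed integer seed.
#' @return A collection of the same size whose set names carry the
#'   \code{"_RND"} suffix.
#' @export
randomize_collection <- function(collection, seed) {
  stopifnot(inherits(collection, "gene_set_collection"))
  pool <- gene_pool(collection)
  sz <- set_sizes(collection)
  if (max(sz) > length(pool))
    stop("a set is larger than the pooled gene universe")
  rng <- local_rng(seed)
  on.exit(rng())
  sets <- lapply(collection$sets, function(s) {
    gene_set(paste0(s$name, "_RND"),
             sample(pool, length(s$genes), replace = FALSE),
             description = "randomized control", category = s$category)
  })
  gene_set_collection(sets)
}
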