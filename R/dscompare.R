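#' @include utils.R
NULL

#' @noRd
.canonicalId <- function(ids) toupper(trimws(ids))

#' Common genes across datasets
#'
#' Exact set intersection of gene ids after canonicalization (trimmed
#' whitespace, upper case); no symbol aliasing or ortholog mapping is
#' attempted. Duplicated ids within a dataset are a contract error; a
#' disjoint result warns.
#'
#' @param bundles list (>= 2) of character id vectors, or data.frames with
#'   a `gene` column.
#' @return character vector of common canonical ids.
#' @examples
#' commonGenes(list(c("a", "b", "c"), c("b", "c", "d"), c("c", "e")))
#' @export
commonGenes <- function(bundles) {
  .assert(is.list(bundles) && length(bundles) >= 2, "need at least 2 datasets")
  ids <- lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    v <- if (is.data.frame(b)) b$gene else b
    v <- .canonicalId(v)
    .assert(
      !anyDuplicated(v),
      "dataset ", i, " has duplicated gene ids after canonicalization"
    )
    v
  })
  common <- Reduce(intersect, ids)
  if (!length(common)) warning("no genes common to all datasets")
  common
}

#' Relative Euclidean distance matrix among samples
#'
#' Pairwise Euclidean distances over genes, divided by the maximum
#' pairwise distance in the dataset, so entries lie in \[0, 1\] with a
#' zero diagonal and a maximum of exactly 1. Identical datasets up to a
#' common rescaling of all distances yield the same matrix.
#'
#' @param m numeric matrix, genes x samples (>= 2 samples, finite).
#' @return symmetric samples x samples matrix.
#' @examples
#' m <- cbind(a = c(0, 0), b = c(3, 4), c = c(0, 8))
#' relativeEuclideanMatrix(m) # off-diagonals 0.625, 0.625, 1
#' @export
relativeEuclideanMatrix <- function(m) {
  .assert(is.matrix(m) && ncol(m) >= 2, "need a matrix with >= 2 samples")
  .assert(all(is.finite(m)), "values must be finite")
  d <- as.matrix(dist(t(m)))
  mx <- max(d)
  .assert(mx > 0, "all samples identical: maximum distance is zero",
    class = "lncomat_degenerate_error"
  )
  d / mx
}

#' Cross-dataset fold-change correlation
#'
#' Pearson correlation of per-gene log2 fold changes between two datasets
#' over a common gene set. Symmetric in its arguments; the number of genes
#' used is attached as attribute `n`.
#'
#' @param a,b data.frames with columns `gene` and `log2fc`.
#' @param genes character vector of common genes (canonical ids; see
#'   [commonGenes()]); defaults to the intersection of `a` and `b`.
#' @return the correlation, with attribute `n`.
#' @export
crossDatasetFCCor <- function(a, b, genes = NULL) {
  for (d in list(a, b)) {
    .assert(
      is.data.frame(d) && all(c("gene", "log2fc") %in% colnames(d)),
      "datasets must have columns 'gene' and 'log2fc'"
    )
  }
  ga <- .canonicalId(a$gene)
  gb <- .canonicalId(b$gene)
  if (is.null(genes)) genes <- commonGenes(list(ga, gb))
  genes <- .canonicalId(genes)
  .assert(
    all(genes %in% ga) && all(genes %in% gb),
    "'genes' must be present in both datasets"
  )
  .assert(length(genes) >= 3, "need at least 3 common genes")
  r <- cor(
    a$log2fc[match(genes, ga)],
    b$log2fc[match(genes, gb)]
  )
  attr(r, "n") <- length(genes)
  r
}
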