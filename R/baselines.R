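# Read-counting RPKM baseline: whole-gene exon-union counts scaled by gene
# length and library size, log2.

#' Exon-union gene lengths
#'
#' Length of each gene's exon union in bases (overlapping exons are merged
#' before summing).
#'
#' @param gene_models exon table from [read_gene_models()].
#' @return named numeric vector of lengths.
#' @export
exon_union_length <- function(gene_models) {
  grl <- gene_models_grl(gene_models)
  setNames(sum(GenomicRanges::width(grl)), names(grl))
}

#' RPKM expression table
#'
#' Reads per kilobase of exon-union length per million counted fragments:
#' `RPKM = 1e9 * C / (N * L)` with `C` the gene's count, `N` the sample's
#' library size and `L` the gene's exon-union length. Values are returned
#' as `log2(RPKM + epsilon)`. With the default `epsilon = 0`, genes with a
#' zero count in any sample are dropped (their log2 RPKM is undefined and
#' low-expression features are filtered out downstream anyway); set
#' `epsilon > 0` to keep them.
#'
#' @param counts gene-level [count_matrix()] object, or a counts matrix
#'   (genes x samples) with `library_sizes` supplied.
#' @param lengths named vector from [exon_union_length()].
#' @param library_sizes per-sample totals; taken from `counts` when it is a
#'   `count_matrix`.
#' @param epsilon offset added before log2 (default 0).
#' @return an [expression_table()] with namespace `"gene"` (log2 scale).
#' @export
rpkm <- function(counts, lengths, library_sizes = NULL, epsilon = 0) {
  if (inherits(counts, "count_matrix")) {
    library_sizes <- counts$library_sizes
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) stop("library_sizes required")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("no length for counted gene: ", missing[1])
  L <- lengths[rownames(counts)]
  vals <- 1e9 * sweep(counts, 2L, library_sizes, "/") / L
  if (epsilon == 0) {
    keep <- rowSums(counts == 0) == 0L
    vals <- vals[keep, , drop = FALSE]
  } else {
    vals <- vals + epsilon
  }
  expression_table(log2(vals), namespace = "gene")
}
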