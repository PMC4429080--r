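# Gene models as a GRangesList of per-gene reduced (exon-union) ranges.
gene_models_grl <- function(gene_models) {
  strand <- ifelse(gene_models$strand == ".", "*", gene_models$strand)
  gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start + 1L, gene_models$end),
    strand = strand)
  grl <- S4Vectors::split(gr, factor(gene_models$gene_id,
                                     levels = unique(gene_models$gene_id)))
  GenomicRanges::reduce(grl)
}

#' Count fragment overlaps with probe regions
#'
#' Produces one sample's column of the probe-region count matrix. Every
#' retained fragment increments the count of every distinct probe region it
#' overlaps — a fragment overlapping several regions is counted for all of
#' them, so column sums may exceed the number of fragments. Fragments
#' failing the uniqueness filter are dropped when `unique_only` is `TRUE`
#' (the default: only unique genomic alignments are used).
#'
#' @param fragments a `GRangesList` from [read_alignments()] (or built in
#'   code), optionally with a `unique` metadata column.
#' @param index a [build_probe_index()] object.
#' @param ignore_strand ignore strand when testing overlap (default `TRUE`).
#' @param unique_only keep only uniquely aligned fragments (default `TRUE`).
#' @param gene_models optional exon table ([read_gene_models()]); when
#'   supplied, the diagnostics additionally report how many fragments fall
#'   in gene regions and, of those, how many hit a probe region.
#' @return a list with `counts` (named integer vector over probe ids),
#'   `library_size` (number of retained fragments) and `diagnostics`
#'   (`n_fragments`, `n_retained`, `n_genic`, `n_genic_on_probe`,
#'   `n_on_probe`).
#' @export
count_probe_overlaps <- function(fragments, index, ignore_strand = TRUE,
                                 unique_only = TRUE, gene_models = NULL) {
  stopifnot(inherits(index, "probe_index"))
  n_total <- length(fragments)
  fragments <- filter_unique(fragments, unique_only)
  counts <- GenomicRanges::countOverlaps(index$regions, fragments,
                                         ignore.strand = ignore_strand)
  names(counts) <- S4Vectors::mcols(index$regions)$probe_id
  on_probe <- GenomicRanges::countOverlaps(fragments, index$regions,
                                           ignore.strand = ignore_strand) > 0
  diagnostics <- list(n_fragments = n_total,
                      n_retained = length(fragments),
                      n_genic = NA_integer_,
                      n_genic_on_probe = NA_integer_,
                      n_on_probe = sum(on_probe))
  if (!is.null(gene_models)) {
    genic <- GenomicRanges::countOverlaps(
      fragments, gene_models_grl(gene_models),
      ignore.strand = ignore_strand) > 0
    diagnostics$n_genic <- sum(genic)
    diagnostics$n_genic_on_probe <- sum(genic & on_probe)
  }
  list(counts = counts, library_size = length(fragments),
       diagnostics = diagnostics)
}

#' Count fragment overlaps with gene exon unions
#'
#' Gene-level read counting for the RPKM baseline: a fragment increments a
#' gene when any of its aligned blocks overlaps the gene's exon union
#' (intron-only hits do not count), once per fragment per gene. A fragment
#' overlapping exons of two genes increments both.
#'
#' @inheritParams count_probe_overlaps
#' @param gene_models exon table from [read_gene_models()].
#' @return a list with `counts` (named integer vector over gene ids) and
#'   `library_size` (number of retained fragments).
#' @export
count_gene_overlaps <- function(fragments, gene_models, ignore_strand = TRUE,
                                unique_only = TRUE) {
  fragments <- filter_unique(fragments, unique_only)
  grl <- gene_models_grl(gene_models)
  counts <- GenomicRanges::countOverlaps(grl, fragments,
                                         ignore.strand = ignore_strand)
  names(counts) <- names(grl)
  list(counts = counts, library_size = length(fragments))
}

filter_unique <- function(fragments, unique_only) {
  if (!unique_only) return(fragments)
  uniq <- S4Vectors::mcols(fragments)$unique
  if (is.null(uniq)) return(fragments)
  fragments[!is.na(uniq) & uniq]
}

#' Probe coverage ratios
#'
#' From counting diagnostics, reports what fraction of fragments fall in
#' gene regions and, of those, what fraction hit a microarray probe region
#' — a measure of how much of the data the probe-region restriction keeps.
#' Undefined ratios (zero denominator, or no gene models supplied) are
#' returned as `NA`, never as 0.
#'
#' @param diagnostics the `diagnostics` element of [count_probe_overlaps()].
#' @return list with `gene_ratio` and `probe_ratio`.
#' @export
probe_coverage_report <- function(diagnostics) {
  d <- diagnostics
  gene_ratio <- if (is.na(d$n_genic) || d$n_retained == 0) NA_real_
                else d$n_genic / d$n_retained
  probe_ratio <- if (is.na(d$n_genic) || is.na(d$n_genic_on_probe) ||
                     d$n_genic == 0) NA_real_
                 else d$n_genic_on_probe / d$n_genic
  list(gene_ratio = gene_ratio, probe_ratio = probe_ratio)
}

#' Assemble a count matrix over several samples
#'
#' Convenience wrapper running [count_probe_overlaps()] (or
#' [count_gene_overlaps()]) over one alignment file per sample.
#'
#' @param paths named character vector of SAM/BAM paths; names become
#'   sample ids.
#' @param index a [build_probe_index()] object, or `NULL` when counting
#'   genes.
#' @param gene_models exon table; required when `index` is `NULL`.
#' @param paired_mode,ignore_strand,unique_only,unique_mapq passed through.
#' @return a list of class `count_matrix` with `counts` (integer matrix,
#'   regions or genes x samples), `library_sizes` (named vector) and
#'   `diagnostics` (per-sample list).
#' @export
count_matrix <- function(paths, index = NULL, gene_models = NULL,
                         paired_mode = FALSE, ignore_strand = TRUE,
                         unique_only = TRUE, unique_mapq = 10L) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.(sam|bam)$", "", basename(paths))
  if (is.null(index) && is.null(gene_models))
    stop("supply a probe index or gene models")
  cols <- lapply(paths, function(p) {
    frags <- read_alignments(p, paired_mode = paired_mode,
                             unique_mapq = unique_mapq)
    if (is.null(index))
      count_gene_overlaps(frags, gene_models, ignore_strand, unique_only)
    else
      count_probe_overlaps(frags, index, ignore_strand, unique_only,
                           gene_models = gene_models)
  })
  counts <- do.call(cbind, lapply(cols, `[[`, "counts"))
  colnames(counts) <- names(paths)
  structure(list(counts = counts,
                 library_sizes = vapply(cols, `[[`, numeric(1),
                                        "library_size"),
                 diagnostics = lapply(cols, `[[`, "diagnostics")),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d regions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
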