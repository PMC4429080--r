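#' Build a probe-region index
#'
#' Converts a probe-region table into a queryable index: a `GRanges` of
#' probe regions (one per probe, perfect-match regions only) plus the map
#' from each summarisation group (gene or probe set) to its ordered probes.
#' Every probe belongs to exactly one group.
#'
#' @param regions data frame from [read_probe_regions()].
#' @param namespace what the group ids denote: `"gene"` (custom-CDF style
#'   gene annotations) or `"probeset"` (manufacturer probe sets). The two
#'   modes differ only in the contents of `group_id`; all downstream
#'   computation is identical.
#' @return an object of class `probe_index` with elements `regions`
#'   (`GRanges` carrying `probe_id` and `group_id`), `groups` (named list of
#'   probe-id vectors) and `namespace`.
#' @export
build_probe_index <- function(regions, namespace = c("gene", "probeset")) {
  namespace <- match.arg(namespace)
  validate_probe_regions(regions)
  grp <- tapply(regions$group_id, regions$probe_id,
                function(x) length(unique(x)))
  if (any(grp > 1))
    stop("probe assigned to more than one group: ",
         names(grp)[which(grp > 1)[1]])
  strand <- ifelse(regions$strand == ".", "*", regions$strand)
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(regions$start + 1L, regions$end),
    strand = strand,
    probe_id = regions$probe_id, group_id = regions$group_id)
  groups <- split(regions$probe_id, regions$group_id)
  groups <- groups[unique(regions$group_id)]
  structure(list(regions = gr, groups = groups, namespace = namespace),
            class = "probe_index")
}

#' @export
print.probe_index <- function(x, ...) {
  cat(sprintf("probe_index: %d probe regions in %d %s groups\n",
              length(x$regions), length(x$groups), x$namespace))
  invisible(x)
}

#' Probe regions overlapped by a fragment
#'
#' Returns the distinct probes whose region shares at least one base with
#' any of the fragment's aligned blocks. A probe is reported at most once
#' per fragment even when several blocks (e.g. both mates of a pair) hit
#' it. Strand is compared only when `ignore_strand` is `FALSE`; the default
#' ignores strand, matching unstranded RNA-seq protocols.
#'
#' @param index a [build_probe_index()] object.
#' @param intervals a `GRanges` of the fragment's aligned blocks.
#' @param ignore_strand ignore strand when testing overlap (default `TRUE`).
#' @return character vector of probe ids (no duplicates, index order).
#' @export
overlapping_regions <- function(index, intervals, ignore_strand = TRUE) {
  stopifnot(inherits(index, "probe_index"))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(index$regions, intervals,
                                ignore.strand = ignore_strand))
  unique(S4Vectors::mcols(index$regions)$probe_id[
    S4Vectors::queryHits(hits)])
}
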