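# Fixture builders and independent brute-force oracles used across tests.

write_sam <- function(records, sq = c(chr1 = 100000L),
                      path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos1, cigar, mapq = 50L,
                       rnext = "*", pnext = 0L, tlen = 0L,
                       tags = character(0)) {
  paste(c(qname, flag, rname, pos1, mapq, cigar, rnext, pnext, tlen,
          "*", "*", tags), collapse = "\t")
}

# A fragment as a plain list: data.frame of 0-based half-open blocks plus a
# strand, independent of any GRanges machinery.
plain_fragment <- function(chrom, starts, ends, strand = "+") {
  list(blocks = data.frame(chrom = chrom, start = starts, end = ends),
       strand = strand)
}

fragments_to_grl <- function(frags, unique = TRUE) {
  # one flat GRanges split by fragment id (much faster than one
  # GRanges per fragment)
  nb <- vapply(frags, function(f) nrow(f$blocks), integer(1))
  if (!length(frags)) {
    grl <- GenomicRanges::GRangesList()
  } else {
    flat <- GenomicRanges::GRanges(
      unlist(lapply(frags, function(f) f$blocks$chrom)),
      IRanges::IRanges(
        unlist(lapply(frags, function(f) f$blocks$start)) + 1L,
        unlist(lapply(frags, function(f) f$blocks$end))),
      strand = rep(vapply(frags, function(f) f$strand, character(1)), nb))
    grl <- S4Vectors::split(flat, factor(rep(seq_along(frags), nb),
                                         levels = seq_along(frags)))
  }
  S4Vectors::mcols(grl)$unique <- rep(unique, length.out = length(grl))
  grl
}

strand_compatible <- function(a, b) a == "*" | b == "*" | a == "." |
  b == "." | a == b

# O(n*m) oracle: for each region, count fragments with >= 1 overlapping
# base in any block.
bf_probe_counts <- function(frags, regions, ignore_strand = TRUE) {
  counts <- integer(nrow(regions))
  rchrom <- regions$chrom; rstart <- regions$start; rend <- regions$end
  for (f in frags) {
    hit <- logical(nrow(regions))
    bchrom <- f$blocks$chrom; bstart <- f$blocks$start; bend <- f$blocks$end
    for (bi in seq_along(bstart)) {
      ok <- rchrom == bchrom[bi] & rstart < bend[bi] & bstart[bi] < rend
      if (!ignore_strand)
        ok <- ok & strand_compatible(f$strand, regions$strand)
      hit <- hit | ok
    }
    counts <- counts + hit
  }
  setNames(counts, regions$probe_id)
}

# Oracle for gene counting: regions grouped by gene, fragment counted once
# per gene when any block overlaps any exon of the gene's union.
bf_gene_counts <- function(frags, gene_models, ignore_strand = TRUE) {
  genes <- unique(gene_models$gene_id)
  counts <- setNames(integer(length(genes)), genes)
  for (f in frags) {
    for (g in genes) {
      ex <- gene_models[gene_models$gene_id == g, ]
      hit <- FALSE
      for (bi in seq_len(nrow(f$blocks))) {
        b <- f$blocks[bi, ]
        ok <- ex$chrom == b$chrom & ex$start < b$end & b$start < ex$end
        if (!ignore_strand)
          ok <- ok & strand_compatible(f$strand, ex$strand)
        if (any(ok)) { hit <- TRUE; break }
      }
      if (hit) counts[g] <- counts[g] + 1L
    }
  }
  counts
}

random_regions <- function(n, chroms = c("chr1", "chr2"),
                           span = 5000L, width_max = 60L) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(width_max, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             probe_id = sprintf("p%04d", seq_len(n)),
             group_id = sprintf("grp%03d", 1L + (seq_len(n) - 1L) %/% 5L))
}

random_fragments <- function(n, chroms = c("chr1", "chr2"),
                             span = 5000L) {
  lapply(seq_len(n), function(i) {
    chrom <- sample(chroms, 1L)
    nb <- sample(1:2, 1L)
    s <- sort(sample.int(span, nb))
    w <- sample(20:60, nb, replace = TRUE)
    if (nb == 2L && s[2] < s[1] + w[1]) s[2] <- s[1] + w[1] + 10L
    plain_fragment(chrom, s, s + w, strand = sample(c("+", "-"), 1L))
  })
}

make_probe_index <- function(regions, namespace = "gene") {
  build_probe_index(regions, namespace = namespace)
}

random_expression_table <- function(n_feat = 8L, n_samp = 3L,
                                    namespace = "gene") {
  m <- matrix(round(rnorm(n_feat * n_samp, 8, 2), 6), n_feat,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  expression_table(m, namespace)
}
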