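# Synthetic paired RNA-seq / microarray data with known ground truth: a toy
# genome with multi-exon genes, probe regions inside exons, spliced reads
# drawn by Poisson sampling from latent expression levels, and coupled
# microarray probe intensities sharing probe affinities and a per-gene
# probe-region bias with the sequencing side. Everything is deterministic
# under the configured seed.

#' Simulation configuration
#'
#' Study conditions for the synthetic generator. Defaults describe a small
#' but realistic desk-scale experiment: 200 multi-exon genes, 10
#' twenty-five-mer probes per gene (within the usual 8--20 probes per
#' probe set), 100,000 spliced 50-bp reads per sample, base log2
#' expression N(6, 2) with per-sample deviations of sd 1, lognormal probe
#' affinities (sdlog 0.4) fixed across samples, microarray measurement
#' noise sdlog 0.1, and a per-gene probe-region bias of sd 0.5 log2 units
#' shared by both platforms (probe regions interrogate a biased portion of
#' the transcript; the bias is common to the array and to reads falling in
#' probe regions, and cancels in fold changes).
#'
#' @param n_genes number of genes.
#' @param n_samples number of coupled samples.
#' @param exons_per_gene,exon_length,intron_length,intergenic_length gene
#'   geometry in bases.
#' @param probes_per_gene probes per gene (8--20).
#' @param probe_length probe length in bases (default 25).
#' @param read_length read length in bases.
#' @param depth expected total reads per sample.
#' @param log_expr_mean,log_expr_sd base log2 expression distribution.
#' @param sample_effect_sd sd of per-gene, per-sample log2 deviations.
#' @param affinity_sdlog lognormal sdlog of probe affinities.
#' @param array_noise_sdlog lognormal sdlog of microarray intensity noise.
#' @param probe_bias_sd sd (log2) of the per-gene probe-region bias shared
#'   by the two platforms; 0 disables it.
#' @param paired generate paired-end reads.
#' @param grouping probe group ids: `"gene"` or `"probeset"` (one probe
#'   set per gene).
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L, n_samples = 2L,
                              exons_per_gene = 3L, exon_length = 300L,
                              intron_length = 200L,
                              intergenic_length = 500L,
                              probes_per_gene = 10L, probe_length = 25L,
                              read_length = 50L, depth = 1e5,
                              log_expr_mean = 6, log_expr_sd = 2,
                              sample_effect_sd = 1,
                              affinity_sdlog = 0.4,
                              array_noise_sdlog = 0.1,
                              probe_bias_sd = 0.5,
                              paired = FALSE,
                              grouping = c("gene", "probeset"),
                              seed = 1L) {
  grouping <- match.arg(grouping)
  stopifnot(n_genes >= 1, n_samples >= 1, exons_per_gene >= 1,
            probes_per_gene >= 8, probes_per_gene <= 20,
            probe_length >= 1, read_length >= probe_length,
            log_expr_sd >= 0, sample_effect_sd >= 0,
            affinity_sdlog >= 0, array_noise_sdlog >= 0,
            probe_bias_sd >= 0, depth >= 0)
  if (exon_length < probe_length)
    stop("exon too short to hold a probe")
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

#' Simulate the reference: genome, gene models, probe regions
#'
#' Lays `n_genes` genes along one synthetic chromosome, each with
#' `exons_per_gene` exons, draws a random genome sequence, and places
#' `probes_per_gene` probes fully inside exons of each gene. Probe
#' sequences are therefore exact substrings of the genome.
#'
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed`.
#' @return list with `genome` (a [Biostrings::DNAStringSet]),
#'   `gene_models`, `probe_regions` (data frames in the flat-file layouts)
#'   and `config`.
#' @export
simulate_reference <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_genes
  ex <- config$exons_per_gene
  gene_span <- ex * config$exon_length + (ex - 1) * config$intron_length
  step <- gene_span + config$intergenic_length
  glen <- n * step + config$intergenic_length
  chrom <- "chrS1"
  genome <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), glen, replace = TRUE), collapse = ""))
  names(genome) <- chrom
  gene_ids <- sprintf("g%03d", seq_len(n))
  gm <- do.call(rbind, lapply(seq_len(n), function(i) {
    gstart <- config$intergenic_length + (i - 1L) * step
    starts <- gstart + (seq_len(ex) - 1L) *
      (config$exon_length + config$intron_length)
    data.frame(gene_id = gene_ids[i], chrom = chrom,
               start = starts, end = starts + config$exon_length,
               strand = "+")
  }))
  pr <- do.call(rbind, lapply(seq_len(n), function(i) {
    exons <- gm[gm$gene_id == gene_ids[i], ]
    which_exon <- sample(nrow(exons), config$probes_per_gene,
                         replace = TRUE)
    offset <- sample(config$exon_length - config$probe_length + 1L,
                     config$probes_per_gene, replace = TRUE) - 1L
    start <- exons$start[which_exon] + offset
    group <- if (config$grouping == "gene") gene_ids[i]
             else paste0(gene_ids[i], "_ps")
    data.frame(chrom = chrom, start = start,
               end = start + config$probe_length, strand = "+",
               probe_id = sprintf("%s_p%02d", gene_ids[i],
                                  seq_len(config$probes_per_gene)),
               group_id = group)
  }))
  validate_probe_regions(pr)
  list(genome = genome, gene_models = gm, probe_regions = pr,
       config = config)
}

#' Simulate the latent ground truth
#'
#' Per-gene, per-sample linear expression levels `theta`, per-probe
#' affinities (lognormal, fixed across samples) and the per-gene
#' probe-region bias (log2) shared by the two platforms.
#'
#' @param reference output of [simulate_reference()].
#' @param seed overrides `config$seed` (offset internally so the draws are
#'   independent of the reference layout).
#' @return list of class `ground_truth` with `theta` (genes x samples,
#'   linear), `log2_theta`, `affinity` (named by probe), `probe_bias`
#'   (named by gene, log2) and `sample_ids`.
#' @export
simulate_truth <- function(reference, seed = reference$config$seed) {
  config <- reference$config
  set.seed(seed + 1000L)
  gene_ids <- unique(reference$gene_models$gene_id)
  n <- length(gene_ids)
  sample_ids <- sprintf("s%02d", seq_len(config$n_samples))
  base <- rnorm(n, config$log_expr_mean, config$log_expr_sd)
  delta <- matrix(rnorm(n * config$n_samples, 0, config$sample_effect_sd),
                  n, config$n_samples)
  log2_theta <- base + delta
  dimnames(log2_theta) <- list(gene_ids, sample_ids)
  affinity <- setNames(
    exp(rnorm(nrow(reference$probe_regions), 0, config$affinity_sdlog)),
    reference$probe_regions$probe_id)
  probe_bias <- setNames(rnorm(n, 0, config$probe_bias_sd), gene_ids)
  structure(list(theta = 2^log2_theta, log2_theta = log2_theta,
                 affinity = affinity, probe_bias = probe_bias,
                 sample_ids = sample_ids),
            class = "ground_truth")
}

# Transcript-coordinate exon offsets for one gene (exons sorted by start).
transcript_map <- function(exons) {
  exons <- exons[order(exons$start), ]
  widths <- exons$end - exons$start
  list(exon_start = exons$start, width = widths,
       tx_offset = cumsum(c(0L, widths[-length(widths)])),
       total = sum(widths))
}

# Genomic blocks and CIGAR for transcript interval [u, u + len).
tx_to_genomic <- function(map, u, len) {
  lo <- u; hi <- u + len
  blocks <- NULL
  for (i in seq_along(map$width)) {
    a <- max(lo, map$tx_offset[i])
    b <- min(hi, map$tx_offset[i] + map$width[i])
    if (a < b)
      blocks <- rbind(blocks, c(map$exon_start[i] + (a - map$tx_offset[i]),
                                map$exon_start[i] + (b - map$tx_offset[i])))
  }
  cigar <- character(0)
  for (i in seq_len(nrow(blocks))) {
    cigar <- c(cigar, sprintf("%dM", blocks[i, 2] - blocks[i, 1]))
    if (i < nrow(blocks))
      cigar <- c(cigar, sprintf("%dN", blocks[i + 1, 1] - blocks[i, 2]))
  }
  list(blocks = blocks, cigar = paste(cigar, collapse = ""),
       pos = blocks[1, 1])
}

# Per-start-position sampling weights along a gene's transcript: positions
# whose read would overlap a probe region get the gene's probe-region bias.
start_weights <- function(map, probe_tx, read_length, bias_log2) {
  n_pos <- map$total - read_length + 1L
  if (n_pos < 1L) return(numeric(0))
  w <- rep(1, n_pos)
  if (bias_log2 != 0 && nrow(probe_tx)) {
    hit <- rep(FALSE, n_pos)
    for (i in seq_len(nrow(probe_tx))) {
      lo <- max(1L, probe_tx[i, 1] - read_length + 2L)
      hi <- min(n_pos, probe_tx[i, 2])
      if (lo <= hi) hit[lo:hi] <- TRUE
    }
    w[hit] <- 2^bias_log2
  }
  w
}

# Probe intervals of a gene in transcript coordinates (0-based half-open).
probe_tx_intervals <- function(map, probes) {
  if (!nrow(probes)) return(matrix(numeric(0), 0, 2))
  out <- matrix(NA_real_, nrow(probes), 2)
  for (i in seq_len(nrow(probes))) {
    ex <- which(probes$start[i] >= map$exon_start &
                  probes$end[i] <= map$exon_start + map$width)
    out[i, ] <- map$tx_offset[ex[1]] + probes$start[i] -
      map$exon_start[ex[1]] + c(0, probes$end[i] - probes$start[i])
  }
  out
}

#' Simulate spliced RNA-seq reads as a SAM file
#'
#' Draws per-gene read counts Poisson-distributed around the gene's share
#' of the sequencing depth (proportional to expression times effective
#' transcript weight), places read start positions along each gene's exon
#' union — positions overlapping probe regions are re-weighted by the
#' gene's shared probe-region bias — and writes a valid SAM file with
#' junction-spanning CIGARs (`N` gaps), real spliced sequences, and
#' `NH:i:1` tags. In paired mode two proper mates bracketing a fragment
#' are written per unit.
#'
#' @param reference output of [simulate_reference()].
#' @param truth output of [simulate_truth()].
#' @param sample sample id (column of `truth$theta`).
#' @param path output SAM path.
#' @param seed RNG seed for this sample's reads.
#' @return `path`, invisibly.
#' @export
simulate_reads <- function(reference, truth, sample, path,
                           seed = reference$config$seed) {
  config <- reference$config
  set.seed(seed + 2000L + match(sample, truth$sample_ids))
  rl <- config$read_length
  unit <- if (config$paired) 2L * rl + 50L else rl
  gene_ids <- unique(reference$gene_models$gene_id)
  maps <- lapply(gene_ids, function(g)
    transcript_map(reference$gene_models[
      reference$gene_models$gene_id == g, ]))
  names(maps) <- gene_ids
  weights <- lapply(gene_ids, function(g) {
    map <- maps[[g]]
    ptx <- probe_tx_intervals(map, reference$probe_regions[
      startsWith(reference$probe_regions$probe_id, paste0(g, "_")), ])
    start_weights(map, ptx, min(unit, map$total), truth$probe_bias[[g]])
  })
  names(weights) <- gene_ids
  wsum <- vapply(weights, sum, numeric(1))
  theta <- truth$theta[gene_ids, sample]
  rate <- theta * wsum
  expected <- if (sum(rate) > 0) config$depth * rate / sum(rate) else
    rep(0, length(rate))
  n_reads <- rpois(length(gene_ids), expected)
  chrom <- names(reference$genome)[1]
  genome_str <- as.character(reference$genome[[1]])
  out <- vector("list", length(gene_ids) + 1L)
  out[[1]] <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", chrom, nchar(genome_str)))
  ridx <- 0L
  for (gi in seq_along(gene_ids)) {
    k <- n_reads[gi]
    if (k == 0L) next
    map <- maps[[gene_ids[gi]]]
    w <- weights[[gene_ids[gi]]]
    flen <- min(unit, map$total)
    us <- sample.int(length(w), k, replace = TRUE, prob = w) - 1L
    pair_mode <- config$paired && flen >= 2L * rl
    lines <- character(if (pair_mode) 2L * k else k)
    li <- 0L
    for (u in us) {
      ridx <- ridx + 1L
      qname <- sprintf("r%07d", ridx)
      if (!pair_mode) {
        g <- tx_to_genomic(map, u, min(rl, flen))
        lines[li <- li + 1L] <- sam_line(qname, 0L, chrom, g, genome_str)
      } else {
        g1 <- tx_to_genomic(map, u, rl)
        g2 <- tx_to_genomic(map, u + flen - rl, rl)
        tlen <- g2$blocks[nrow(g2$blocks), 2] - g1$pos
        lines[li <- li + 1L] <-
          sam_line(qname, 99L, chrom, g1, genome_str,
                   pnext = g2$pos + 1L, tlen = tlen)
        lines[li <- li + 1L] <-
          sam_line(qname, 147L, chrom, g2, genome_str,
                   pnext = g1$pos + 1L, tlen = -tlen)
      }
    }
    out[[gi + 1L]] <- lines
  }
  writeLines(unlist(out), path)
  invisible(path)
}

sam_line <- function(qname, flag, chrom, g, genome_str, pnext = 0L,
                     tlen = 0L) {
  seq <- paste(substring(genome_str, g$blocks[, 1] + 1L, g$blocks[, 2]),
               collapse = "")
  rnext <- if (pnext > 0L) "=" else "*"
  # force plain integer rendering (avoid scientific notation in POS/TLEN)
  paste(qname, flag, chrom, sprintf("%d", as.integer(g$pos + 1L)), 50L,
        g$cigar, rnext, sprintf("%d", as.integer(pnext)),
        sprintf("%d", as.integer(tlen)), seq, "*", "NH:i:1", sep = "\t")
}

#' Simulate coupled microarray probe intensities
#'
#' Probe intensity = gene expression x shared probe-region bias x probe
#' affinity x lognormal measurement noise. Affinities and bias are fixed
#' across samples, so they cancel in fold changes between samples.
#'
#' @param reference output of [simulate_reference()].
#' @param truth output of [simulate_truth()].
#' @param seed RNG seed for the noise draws.
#' @return positive matrix, probes x samples (linear intensities), ready
#'   for [summarise_expression()].
#' @export
simulate_microarray <- function(reference, truth,
                                seed = reference$config$seed) {
  config <- reference$config
  set.seed(seed + 3000L)
  pr <- reference$probe_regions
  gene_of_probe <- sub("_p[0-9]+$", "", pr$probe_id)
  theta <- truth$theta[gene_of_probe, , drop = FALSE]
  bias <- 2^truth$probe_bias[gene_of_probe]
  noise <- matrix(exp(rnorm(nrow(pr) * ncol(theta), 0,
                            config$array_noise_sdlog)),
                  nrow(pr), ncol(theta))
  intensity <- theta * bias * truth$affinity[pr$probe_id] * noise
  dimnames(intensity) <- list(pr$probe_id, colnames(theta))
  intensity
}

#' Simulate a coupled query/database panel at the expression level
#'
#' Expression-level generator for retrieval experiments: `n_pairs` coupled
#' query/database sample pairs sharing a per-sample signal, plus
#' `n_distractors` unrelated database samples. In `"signal"` mode a query
#' and its pair share the sample's expression profile up to measurement
#' noise; in `"noise"` mode queries and database are mutually independent
#' noise, so retrieval can only succeed at chance level.
#'
#' @param n_pairs,n_distractors panel composition.
#' @param n_genes number of features.
#' @param signal_sd sd of the per-sample expression deviations (log2).
#' @param noise_sd sd of per-platform measurement noise (log2).
#' @param mode `"signal"` or `"noise"`.
#' @param seed RNG seed.
#' @return list with `queries`, `database` (both [expression_table()]s)
#'   and `truth` (query id -> database id).
#' @export
simulate_coupled_panel <- function(n_pairs, n_distractors,
                                   n_genes = 1000L, signal_sd = 1,
                                   noise_sd = 0.3,
                                   mode = c("signal", "noise"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  qids <- sprintf("q%02d", seq_len(n_pairs))
  dids <- c(sprintf("d%02d", seq_len(n_pairs)),
            sprintf("x%02d", seq_len(n_distractors)))
  if (mode == "noise") {
    q <- matrix(rnorm(n_genes * n_pairs), n_genes,
                dimnames = list(genes, qids))
    db <- matrix(rnorm(n_genes * length(dids)), n_genes,
                 dimnames = list(genes, dids))
  } else {
    base <- rnorm(n_genes, 6, 2)
    signal <- matrix(rnorm(n_genes * n_pairs, 0, signal_sd), n_genes)
    q <- base + signal + matrix(rnorm(n_genes * n_pairs, 0, noise_sd),
                                n_genes)
    dbp <- base + signal + matrix(rnorm(n_genes * n_pairs, 0, noise_sd),
                                  n_genes)
    dbx <- base + matrix(rnorm(n_genes * n_distractors, 0, signal_sd),
                         n_genes) +
      matrix(rnorm(n_genes * n_distractors, 0, noise_sd), n_genes)
    db <- cbind(dbp, dbx)
    dimnames(q) <- list(genes, qids)
    dimnames(db) <- list(genes, dids)
  }
  list(queries = expression_table(q, "gene"),
       database = expression_table(db, "gene"),
       truth = setNames(sprintf("d%02d", seq_len(n_pairs)), qids))
}

#' End-to-end recovery experiment
#'
#' Runs the whole pipeline on synthetic data — simulate reference, truth,
#' reads and coupled microarray; count probe overlaps; fit the
#' empirical-Bayes gamma prior and estimate probe expression; summarise
#' into gene (or probe-set) expression; compute the RPKM baseline — and
#' reports how well each method recovers the latent expression and agrees
#' with the coupled microarray.
#'
#' @param config a [simulation_config()].
#' @param mode summarisation mode passed to [summarise_expression()].
#' @param seed overrides `config$seed`.
#' @return list with expression tables (`prebs`, `microarray`, `rpkm`),
#'   the ground truth, per-sample correlations (`cor_prebs_truth`,
#'   `cor_prebs_array`, `cor_rpkm_truth`, `cor_rpkm_array`), and the
#'   probe `coverage` ratios of sample 1.
#' @export
end_to_end_recovery <- function(config = simulation_config(),
                                mode = c("rpa", "rma"),
                                seed = config$seed) {
  mode <- match.arg(mode)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  reference <- stage("simulate_reference", simulate_reference(config, seed))
  truth <- stage("simulate_truth", simulate_truth(reference, seed))
  sams <- setNames(vapply(truth$sample_ids, function(s) {
    p <- tempfile(fileext = ".sam")
    simulate_reads(reference, truth, s, p, seed)
    p
  }, character(1)), truth$sample_ids)
  on.exit(unlink(sams))
  index <- stage("build_index",
                 build_probe_index(reference$probe_regions,
                                   namespace = if (config$grouping ==
                                                   "gene") "gene"
                                   else "probeset"))
  pc <- stage("count", count_matrix(sams, index,
                                    gene_models = reference$gene_models,
                                    paired_mode = config$paired))
  est <- stage("estimate", estimate_expression(pc))
  prebs <- stage("summarise", summarise_expression(est, index, mode = mode))
  intensities <- stage("simulate_microarray",
                       simulate_microarray(reference, truth, seed))
  array <- stage("summarise_microarray",
                 summarise_expression(intensities, index, mode = mode))
  gc_counts <- stage("count_genes",
                     count_matrix(sams, index = NULL,
                                  gene_models = reference$gene_models,
                                  paired_mode = config$paired))
  rpkm_tab <- if (all(gc_counts$library_sizes > 0))
    stage("rpkm", rpkm(gc_counts,
                       exon_union_length(reference$gene_models)))
  else NULL
  per_sample_cor <- function(tab, target, fraction = 1) {
    if (is.null(tab)) return(NULL)
    shared <- intersect(rownames(tab), rownames(target))
    vapply(truth$sample_ids, function(s) {
      ids <- if (fraction < 1)
        top_fraction_features(target[shared, , drop = FALSE], s, fraction)
      else shared
      stats::cor(tab[ids, s], target[ids, s])
    }, numeric(1))
  }
  truth_tab <- truth$log2_theta
  if (config$grouping == "probeset")
    rownames(truth_tab) <- paste0(rownames(truth_tab), "_ps")
  # method-vs-array agreement is computed over the top 60% of genes by
  # array expression: low-expressed features are filtered out before any
  # cross-platform comparison, as is standard
  list(prebs = prebs, microarray = array, rpkm = rpkm_tab,
       truth = truth, counts = pc,
       cor_prebs_truth = per_sample_cor(prebs, truth_tab),
       cor_prebs_array = per_sample_cor(prebs, array, fraction = 0.6),
       cor_rpkm_truth = per_sample_cor(rpkm_tab, truth$log2_theta),
       cor_rpkm_array = if (config$grouping == "gene")
         per_sample_cor(rpkm_tab, array, fraction = 0.6) else NULL,
       coverage = probe_coverage_report(pc$diagnostics[[1]]))
}
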