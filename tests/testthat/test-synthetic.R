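small_config <- function(...) {
  args <- list(n_genes = 12L, n_samples = 2L, depth = 4000,
               exon_length = 120L, intron_length = 80L,
               intergenic_length = 150L, probes_per_gene = 8L, seed = 5L)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

test_that("reference generator places probes inside exons, deterministically", {
  cfg <- small_config()
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$probe_regions), 12L * 8L)
  gm <- ref$gene_models
  for (i in seq_len(nrow(ref$probe_regions))) {
    p <- ref$probe_regions[i, ]
    g <- sub("_p[0-9]+$", "", p$probe_id)
    ex <- gm[gm$gene_id == g, ]
    expect_true(any(p$start >= ex$start & p$end <= ex$end))
  }
  ref2 <- simulate_reference(cfg)
  expect_identical(ref$probe_regions, ref2$probe_regions)
  expect_identical(as.character(ref$genome), as.character(ref2$genome))
  expect_error(simulate_reference(small_config(exon_length = 20L)),
               "too short")
})

test_that("read SEQ fields are exact spliced substrings of the genome", {
  cfg <- small_config(depth = 300)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(ref)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(ref, truth, "s01", sam)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  genome <- as.character(ref$genome[[1]])
  for (ln in body[seq_len(min(25, length(body)))]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    pos <- as.integer(f[4])
    ops <- regmatches(f[6], gregexpr("[0-9]+[MN]", f[6]))[[1]]
    cur <- pos
    expected <- ""
    for (op in ops) {
      n <- as.integer(sub("[MN]$", "", op))
      if (endsWith(op, "M"))
        expected <- paste0(expected, substring(genome, cur, cur + n - 1L))
      cur <- cur + n
    }
    expect_equal(f[10], expected)
  }
})

test_that("simulated reads round-trip through alignment reading cleanly", {
  cfg <- small_config(depth = 500)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(ref)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(ref, truth, "s01", sam)
  expect_no_warning(frags <- read_alignments(sam))
  expect_equal(S4Vectors::metadata(frags)$diagnostics$n_skipped, 0)
  expect_true(all(S4Vectors::mcols(frags)$unique))

  sam2 <- tempfile(fileext = ".sam")
  simulate_reads(ref, truth, "s01", sam2)
  expect_identical(readLines(sam), readLines(sam2))  # bitwise reproducible
})

test_that("paired simulation yields proper mate pairs that merge on read", {
  cfg <- small_config(depth = 300, paired = TRUE)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(ref)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(ref, truth, "s01", sam)
  single <- read_alignments(sam, paired_mode = FALSE)
  paired <- read_alignments(sam, paired_mode = TRUE)
  expect_equal(length(single), 2L * length(paired))
  expect_equal(S4Vectors::metadata(paired)$diagnostics$n_orphans, 0L)
})

test_that("a single expressed gene receives all reads", {
  cfg <- simulation_config(n_genes = 8L, depth = 400, seed = 3L)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(ref)
  truth$theta[, ] <- 0
  truth$theta["g003", ] <- 100
  sam <- tempfile(fileext = ".sam")
  simulate_reads(ref, truth, "s01", sam)
  counts <- count_gene_overlaps(read_alignments(sam), ref$gene_models)
  expect_gt(counts$counts[["g003"]], 0)
  expect_equal(sum(counts$counts[setdiff(names(counts$counts), "g003")]), 0)
})

test_that("per-gene read counts track the Poisson expectation", {
  cfg <- simulation_config(n_genes = 6L, depth = 2000, probe_bias_sd = 0,
                           sample_effect_sd = 0, seed = 13L)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(ref)
  L <- exon_union_length(ref$gene_models)
  theta <- truth$theta[, "s01"]
  # equal effective weights (no bias): expectation ~ depth * theta*L / sum
  expected <- cfg$depth * theta * (L - cfg$read_length + 1) /
    sum(theta * (L - cfg$read_length + 1))
  reps <- 30L
  totals <- matrix(0, length(theta), reps,
                   dimnames = list(names(theta), NULL))
  for (r in seq_len(reps)) {
    sam <- tempfile(fileext = ".sam")
    simulate_reads(ref, truth, "s01", sam, seed = 1000L + r)
    cg <- count_gene_overlaps(read_alignments(sam), ref$gene_models)
    totals[names(cg$counts), r] <- cg$counts
    unlink(sam)
  }
  m <- rowMeans(totals)
  se <- sqrt(expected / reps)  # Poisson variance
  big <- expected > 20
  expect_true(all(abs(m[big] - expected[big]) < 4 * se[big]))
})

test_that("microarray intensities follow the generative model exactly at zero noise", {
  cfg <- small_config(array_noise_sdlog = 0, affinity_sdlog = 0,
                      probe_bias_sd = 0)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(ref)
  ints <- simulate_microarray(ref, truth)
  gene_of_probe <- sub("_p[0-9]+$", "", rownames(ints))
  expect_equal(unname(ints), unname(truth$theta[gene_of_probe, ]))
  ints2 <- simulate_microarray(ref, truth)
  expect_identical(ints, ints2)
})

test_that("probe affinities cancel in summarised microarray fold changes", {
  cfg <- small_config(array_noise_sdlog = 0, affinity_sdlog = 0.6,
                      probe_bias_sd = 0.5)
  ref <- simulate_reference(cfg)
  truth <- simulate_truth(ref)
  ints <- simulate_microarray(ref, truth)
  # affinities and shared bias are sample-constant, so per-group median
  # polish cancels them exactly in fold changes
  logm <- log2(ints)
  for (g in unique(ref$gene_models$gene_id)[1:5]) {
    probes <- ref$probe_regions$probe_id[
      startsWith(ref$probe_regions$probe_id, paste0(g, "_"))]
    mp <- median_polish(logm[probes, ], tol = 1e-10, max_iter = 100L)
    expect_equal(unname(mp$summaries["s01"] - mp$summaries["s02"]),
                 truth$log2_theta[g, "s01"] - truth$log2_theta[g, "s02"],
                 tolerance = 1e-8)
  }
  # the full pipeline adds quantile normalisation, which perturbs fold
  # changes only slightly
  idx <- build_probe_index(ref$probe_regions)
  tab <- summarise_expression(ints, idx, mode = "rma")
  lfc <- log2_fold_changes(tab, "s01", "s02")
  true_lfc <- truth$log2_theta[names(lfc), "s01"] -
    truth$log2_theta[names(lfc), "s02"]
  expect_gt(cor(lfc, true_lfc), 0.95)
})

test_that("zero sequencing depth still flows through the pipeline", {
  cfg <- small_config(depth = 0)
  res <- suppressWarnings(end_to_end_recovery(cfg, mode = "rma"))
  expect_true(all(is.finite(unclass(res$prebs))))
  expect_equal(diff(range(res$prebs[, 1])), 0)  # all-equal summaries
})

test_that("synthetic counts are marginally gamma-Poisson recoverable", {
  set.seed(17)
  k <- rpois(3000, rgamma(3000, shape = 1.2, rate = 0.05))
  pr <- fit_gamma_prior(k)
  expect_lt(abs(pr$shape - 1.2) / 1.2, 0.2)
  expect_lt(abs(pr$rate - 0.05) / 0.05, 0.2)
})
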