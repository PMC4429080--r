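# Comparison machinery between sequencing-based and microarray expression
# tables: top-fraction filtering, absolute and differential correlation,
# correlation-difference tests, DE-set overlap, extreme quantile
# normalisation for cross-platform fold changes, and signature-based
# retrieval.

#' Top-fraction feature set
#'
#' The `ceiling(fraction * n)` features with the highest expression in one
#' sample of a table. Ties at the cut are broken deterministically by
#' feature id (lexicographically smallest ids included), so the set size is
#' exact.
#'
#' @param table an [expression_table()] (or matrix with rownames).
#' @param sample sample id or column index.
#' @param fraction fraction of features to keep, in (0, 1].
#' @return character vector of feature ids.
#' @export
top_fraction_features <- function(table, sample, fraction) {
  if (!nrow(table)) stop("empty expression table")
  stopifnot(fraction > 0, fraction <= 1)
  v <- table[, sample]
  k <- ceiling(fraction * length(v))
  ids <- rownames(table)
  ord <- order(-v, ids)
  ids[ord[seq_len(k)]]
}

#' Absolute expression agreement with the reference platform
#'
#' For every method table, paired sample and top-expressed fraction,
#' computes the Pearson correlation between the method's values and the
#' reference (microarray) values over the feature set shared by both
#' tables, restricted to the top fraction of most highly expressed
#' features. Per-dataset averages are means over samples with standard
#' errors of the mean.
#'
#' @param methods named list of [expression_table()]s (sequencing-based
#'   methods), sharing the reference's feature namespace.
#' @param reference microarray [expression_table()].
#' @param pairing named character vector mapping method sample ids to
#'   reference sample ids; must be injective. Defaults to identically
#'   named samples.
#' @param fractions numeric vector of top-expressed fractions (default
#'   `seq(0.1, 0.6, 0.1)`, the usual low-expression filtering range).
#' @param rank_by rank features by the `"method"`'s own values in that
#'   sample (default) or by the `"reference"` values.
#' @return list with `per_sample` (data frame: method, sample, fraction,
#'   r, n) and `summary` (method, fraction, mean_r, sem, n_samples).
#'   Correlations with fewer than 3 features are `NA`.
#' @export
absolute_agreement <- function(methods, reference,
                               pairing = NULL,
                               fractions = seq(0.1, 0.6, by = 0.1),
                               rank_by = c("method", "reference")) {
  rank_by <- match.arg(rank_by)
  stopifnot(length(names(methods)) == length(methods))
  rows <- list()
  for (m in names(methods)) {
    tab <- methods[[m]]
    pr <- pairing
    if (is.null(pr)) pr <- setNames(colnames(tab), colnames(tab))
    if (anyDuplicated(pr)) stop("pairing must be injective")
    shared <- intersect(rownames(tab), rownames(reference))
    for (s in names(pr)) {
      ref_s <- pr[[s]]
      for (f in fractions) {
        ranking <- if (rank_by == "method")
          top_fraction_features(tab[shared, , drop = FALSE], s, f)
        else
          top_fraction_features(reference[shared, , drop = FALSE], ref_s, f)
        r <- if (length(ranking) < 3) NA_real_ else
          stats::cor(tab[ranking, s], reference[ranking, ref_s])
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, sample = s, fraction = f, r = r,
          n = length(ranking))
      }
    }
  }
  per_sample <- do.call(rbind, rows)
  agg <- split(per_sample, list(per_sample$method, per_sample$fraction),
               drop = TRUE)
  summary <- do.call(rbind, lapply(agg, function(d) data.frame(
    method = d$method[1], fraction = d$fraction[1],
    mean_r = mean(d$r), sem = stats::sd(d$r) / sqrt(nrow(d)),
    n_samples = nrow(d))))
  rownames(summary) <- NULL
  list(per_sample = per_sample, summary = summary)
}

#' Test a difference between two correlations
#'
#' Fisher z-transform test for the difference between two Pearson
#' correlations computed on `n` features. The independent form compares
#' correlations from unrelated samples:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))`. The dependent form
#' (default use case: two methods correlated against the same microarray
#' vector) applies Steiger's adjustment using the correlation `r12`
#' between the two method vectors.
#'
#' @param r1,r2 the two correlations (each with the shared reference, in
#'   the dependent case).
#' @param n number of features the correlations were computed on (> 6).
#' @param dependent do the correlations share a variable? (default TRUE).
#' @param r12 correlation between the two non-shared variables; required
#'   when `dependent`.
#' @return list with `statistic` (z) and `p` (two-sided).
#' @export
correlation_difference_test <- function(r1, r2, n, dependent = TRUE,
                                        r12 = NULL) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n > 6)
  z1 <- atanh(r1); z2 <- atanh(r2)
  if (dependent) {
    if (is.null(r12)) stop("r12 required for dependent correlations")
    rbar2 <- ((r1 + r2) / 2)^2
    cov12 <- (r12 * (1 - 2 * rbar2) -
                0.5 * rbar2 * (1 - 2 * rbar2 - r12^2)) / (1 - rbar2)^2
    z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov12))
  } else {
    z <- (z1 - z2) / sqrt(2 / (n - 3))
  }
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon signed-rank test on paired correlation differences
#'
#' Tests whether per-sample correlation differences between two methods
#' are symmetric about zero. Uses the exact signed-rank distribution for
#' fewer than 25 non-zero differences and the normal approximation (with
#' continuity correction) otherwise; zero differences are dropped
#' (standard zero-handling). If every difference is zero, returns p = 1
#' with a warning.
#'
#' @param differences numeric vector of paired differences (>= 6).
#' @return list with `statistic` (V) and `p` (two-sided).
#' @export
paired_sample_test <- function(differences) {
  stopifnot(length(differences) >= 6)
  nz <- differences[differences != 0]
  if (!length(nz)) {
    warning("all differences are zero")
    return(list(statistic = 0, p = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = length(nz) < 25,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Log2 fold changes between two samples
#'
#' Values are already on the log2 scale, so the fold change is the
#' per-feature difference `table[, sample_a] - table[, sample_b]`.
#'
#' @param table an [expression_table()].
#' @param sample_a,sample_b sample ids.
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_changes <- function(table, sample_a, sample_b) {
  setNames(table[, sample_a] - table[, sample_b], rownames(table))
}

#' Enumerate all sample pairs
#'
#' All `choose(m, 2)` unordered pairs of sample ids, for all-pairs
#' fold-change analyses.
#'
#' @param sample_ids character vector.
#' @return two-column character matrix, one pair per row.
#' @export
enumerate_sample_pairs <- function(sample_ids) {
  t(combn(sample_ids, 2L))
}

#' Differential-expression sets and overlap counts
#'
#' Calls a feature differentially expressed when its absolute log2 fold
#' change exceeds `threshold` (default 1.5), per method, and counts the
#' regions of the Venn diagram over the methods' DE sets (all 2^k - 1
#' non-empty membership patterns).
#'
#' @param lfc_by_method named list of log2 fold-change vectors sharing a
#'   feature space (names are feature ids).
#' @param threshold absolute log2 fold-change cutoff (default 1.5).
#' @return list with `sets` (named list of feature-id vectors) and `venn`
#'   (named integer vector; names like `"A&B"` list the methods a region
#'   belongs to, exclusively).
#' @export
de_overlap <- function(lfc_by_method, threshold = 1.5) {
  stopifnot(length(names(lfc_by_method)) == length(lfc_by_method))
  sets <- lapply(lfc_by_method, function(l) names(l)[abs(l) > threshold])
  all_feats <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  membership <- vapply(sets, function(s) all_feats %in% s,
                       logical(length(all_feats)))
  if (length(all_feats) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- apply(membership, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  venn <- integer(0)
  for (i in seq_len(2^k - 1)) {
    inc <- as.logical(bitwAnd(i, 2^(seq_len(k) - 1L)))
    nm <- paste(names(sets)[inc], collapse = "&")
    venn[nm] <- sum(patterns == nm)
  }
  list(sets = sets, venn = venn)
}

#' Extreme quantile normalisation
#'
#' Replaces each RNA-seq value by the microarray value of the same rank in
#' the coupled experiment: the output multiset equals the microarray
#' multiset exactly and the RNA-seq rank order is preserved, equalising the
#' two platforms' dynamic ranges. Ties in the RNA-seq values are ordered
#' deterministically by feature id.
#'
#' @param rnaseq named numeric vector (one RNA-seq sample).
#' @param microarray_ref named numeric vector over the same features (the
#'   coupled microarray sample).
#' @return named numeric vector over the same features.
#' @export
extreme_quantile_normalise <- function(rnaseq, microarray_ref) {
  if (!setequal(names(rnaseq), names(microarray_ref)) ||
      length(rnaseq) != length(microarray_ref))
    stop("feature sets must be identical")
  microarray_ref <- microarray_ref[names(rnaseq)]
  o <- order(rnaseq, names(rnaseq))
  out <- numeric(length(rnaseq))
  out[o] <- sort(microarray_ref)
  names(out) <- names(rnaseq)
  out
}

#' Cross-platform log2 fold change
#'
#' Fold change between an RNA-seq sample and a microarray sample measured
#' on different platforms: the RNA-seq values are first mapped onto the
#' microarray scale by [extreme_quantile_normalise()] against the RNA-seq
#' sample's own coupled microarray experiment, then subtracted from the
#' other platform's values.
#'
#' @param rnaseq named vector (RNA-seq sample, log2).
#' @param microarray named vector (the microarray sample being compared
#'   against, log2).
#' @param coupled_ref named vector (microarray experiment coupled to the
#'   RNA-seq sample, used only for the rank mapping).
#' @return named numeric vector: transformed RNA-seq minus microarray.
#' @export
cross_platform_lfc <- function(rnaseq, microarray, coupled_ref) {
  transformed <- extreme_quantile_normalise(rnaseq, coupled_ref)
  transformed - microarray[names(transformed)]
}

#' Retrieval of coupled experiments by expression signature
#'
#' For each query (RNA-seq) sample and signature size `N`, correlates the
#' query's top-`N` expressed features against every database (microarray)
#' sample and checks whether the query's true pair attains the strict
#' maximum correlation. Accuracy is the fraction of queries whose true
#' pair wins; ties at the maximum count as failures.
#'
#' @param queries [expression_table()] of query samples.
#' @param database [expression_table()] of database samples (a superset of
#'   the true pairs).
#' @param truth named character vector: query sample id -> database sample
#'   id.
#' @param signature_sizes integer vector of top-`N` sizes; sizes exceeding
#'   the shared feature count are capped with a warning.
#' @return named numeric vector of accuracies, one per signature size.
#' @export
retrieval_accuracy <- function(queries, database, truth, signature_sizes) {
  shared <- intersect(rownames(queries), rownames(database))
  if (length(shared) < 3) stop("fewer than 3 shared features")
  q <- queries[shared, , drop = FALSE]
  db <- database[shared, , drop = FALSE]
  sizes <- signature_sizes
  if (any(sizes > length(shared))) {
    warning("signature size exceeds feature count; capping")
    sizes <- pmin(sizes, length(shared))
  }
  acc <- setNames(numeric(length(sizes)), as.character(signature_sizes))
  for (i in seq_along(sizes)) {
    n_top <- sizes[i]
    hits <- vapply(names(truth), function(s) {
      ord <- order(-q[, s], rownames(q))
      ids <- rownames(q)[ord[seq_len(n_top)]]
      rs <- stats::cor(q[ids, s], db[ids, , drop = FALSE])[1L, ]
      best <- max(rs)
      sum(rs == best) == 1L && names(which.max(rs)) == truth[[s]]
    }, logical(1))
    acc[i] <- mean(hits)
  }
  acc
}
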