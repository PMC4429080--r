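test_that("top-fraction sets have exact size with deterministic tie-breaks", {
  set.seed(19)
  tab <- random_expression_table(10, 1)
  top3 <- top_fraction_features(tab, "s01", 0.3)
  expect_equal(length(top3), 3L)
  expect_setequal(top3, rownames(tab)[order(-tab[, 1])][1:3])
  expect_setequal(top_fraction_features(tab, "s01", 1.0), rownames(tab))

  # ties at the cut: lexicographically smallest ids win, size exact
  vals <- matrix(c(5, 5, 5, 1), 4, 1,
                 dimnames = list(c("d", "b", "a", "z"), "s1"))
  tied <- expression_table(vals, "gene")
  expect_equal(sort(top_fraction_features(tied, "s1", 0.5)), c("a", "b"))

  # brute-force oracle over random vectors with many ties
  for (i in 1:20) {
    v <- sample(1:4, 12, replace = TRUE)
    m <- expression_table(matrix(v, 12, 1,
                                 dimnames = list(sprintf("f%02d", 1:12),
                                                 "s1")), "gene")
    f <- runif(1, 0.1, 1)
    got <- top_fraction_features(m, "s1", f)
    ord <- order(-v, sprintf("f%02d", 1:12))
    expect_identical(got, sprintf("f%02d", 1:12)[ord][seq_len(ceiling(f * 12))])
  }
  expect_error(top_fraction_features(
    expression_table(matrix(numeric(0), 0, 1,
                            dimnames = list(character(0), "s1")), "gene"),
    "s1", 0.5), "empty")
})

test_that("absolute agreement recovers perfect, inverted and known correlations", {
  set.seed(40)
  ref <- random_expression_table(50, 2)
  res <- absolute_agreement(list(self = ref), ref, fractions = c(0.2, 0.6))
  expect_true(all(abs(res$per_sample$r - 1) < 1e-12))
  neg <- expression_table(-unclass(ref), "gene")
  res_neg <- absolute_agreement(list(neg = neg), ref, fractions = 0.6,
                                rank_by = "reference")
  expect_true(all(abs(res_neg$per_sample$r + 1) < 1e-12))

  rho <- 0.8
  z <- rnorm(2000)
  x <- rho * z + sqrt(1 - rho^2) * rnorm(2000)
  m <- expression_table(matrix(z, dimnames = list(sprintf("g%04d", 1:2000),
                                                  "s1")), "gene")
  r <- expression_table(matrix(x, dimnames = list(sprintf("g%04d", 1:2000),
                                                  "s1")), "gene")
  res2 <- absolute_agreement(list(m = m), r, fractions = 1.0)
  expect_lt(abs(res2$per_sample$r - rho), 0.03)
})

test_that("per-dataset averages and standard errors match brute force", {
  set.seed(41)
  ref <- random_expression_table(30, 4)
  noisy <- expression_table(unclass(ref) + rnorm(120, 0, 0.5), "gene")
  res <- absolute_agreement(list(noisy = noisy), ref, fractions = 0.5)
  rs <- res$per_sample$r
  expect_equal(res$summary$mean_r, mean(rs))
  expect_equal(res$summary$sem, sd(rs) / sqrt(length(rs)))
})

test_that("correlation-difference tests match their closed forms", {
  same <- correlation_difference_test(0.5, 0.5, 100, dependent = FALSE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  ind <- correlation_difference_test(0.5, 0.3, 100, dependent = FALSE)
  expect_equal(ind$statistic,
               (atanh(0.5) - atanh(0.3)) / sqrt(2 / 97))
  expect_equal(ind$statistic, 1.670, tolerance = 1e-3)
  expect_error(correlation_difference_test(0.5, 0.3, 100, dependent = TRUE),
               "r12")
  dep <- correlation_difference_test(0.5, 0.3, 100, dependent = TRUE,
                                     r12 = 0.6)
  expect_true(is.finite(dep$statistic) && dep$p > 0 && dep$p < 1)
})

test_that("signed-rank test: one-sided extremes and degenerate input", {
  all_pos <- paired_sample_test(runif(20, 0.01, 0.1))
  expect_lt(all_pos$p, 0.001)
  expect_warning(res <- paired_sample_test(rep(0, 10)), "zero")
  expect_equal(res$p, 1)
})

test_that("fold changes are log2 differences; all-pairs enumeration is complete", {
  tab <- random_expression_table(5, 3)
  expect_equal(unname(log2_fold_changes(tab, "s01", "s01")), rep(0, 5))
  vals <- matrix(c(5, 3), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_equal(unname(log2_fold_changes(expression_table(vals, "gene"),
                                        "a", "b")), 2)
  pairs <- enumerate_sample_pairs(sprintf("s%03d", 1:147))
  expect_equal(nrow(pairs), 10731L)
  expect_equal(nrow(enumerate_sample_pairs(c("a", "b", "c"))), 3L)
})

test_that("DE sets and Venn regions match brute-force enumeration", {
  lfc <- c(g1 = 2.0, g2 = -1.6, g3 = 1.0, g4 = 0.0)
  res <- de_overlap(list(m = lfc))
  expect_setequal(res$sets$m, c("g1", "g2"))

  two <- de_overlap(list(a = lfc, b = lfc))
  expect_equal(unname(two$venn[["a&b"]]), 2L)
  expect_equal(unname(two$venn[["a"]]), 0L)

  set.seed(61)
  for (i in 1:10) {
    feats <- sprintf("g%03d", 1:40)
    lfcs <- lapply(setNames(1:3, c("A", "B", "C")), function(j)
      setNames(rnorm(40, 0, 2), feats))
    res3 <- de_overlap(lfcs, threshold = 1.5)
    inA <- feats %in% res3$sets$A
    inB <- feats %in% res3$sets$B
    inC <- feats %in% res3$sets$C
    expect_equal(unname(res3$venn[["A"]]), sum(inA & !inB & !inC))
    expect_equal(unname(res3$venn[["A&B"]]), sum(inA & inB & !inC))
    expect_equal(unname(res3$venn[["A&B&C"]]), sum(inA & inB & inC))
    expect_equal(sum(res3$venn), length(unique(unlist(res3$sets))))
  }
})

test_that("extreme quantile normalisation substitutes ranked reference values", {
  rnaseq <- c(a = 5, b = 1, c = 3)
  ref <- c(a = 10, b = 20, c = 30)
  out <- extreme_quantile_normalise(rnaseq, ref)
  expect_equal(out, c(a = 30, b = 10, c = 20))
  expect_setequal(unname(out), unname(ref))       # multiset identity
  expect_equal(cor(rnaseq, out, method = "spearman"), 1)
  expect_equal(extreme_quantile_normalise(ref, ref), ref)
})

test_that("cross-platform fold change is zero for self and rank-equivalent pairs", {
  set.seed(71)
  ref <- setNames(rnorm(30, 8, 2), sprintf("g%02d", 1:30))
  expect_equal(unname(cross_platform_lfc(ref, ref, ref)), rep(0, 30))
  distorted <- ref^3  # monotone distortion: same ranks
  expect_equal(unname(cross_platform_lfc(distorted, ref, ref)), rep(0, 30))

  other <- setNames(rnorm(30, 8, 2), names(ref))
  rnaseq <- setNames(rnorm(30), names(ref))
  got <- cross_platform_lfc(rnaseq, other, ref)
  oracle <- extreme_quantile_normalise(rnaseq, ref) - other
  expect_equal(got, oracle)
})

test_that("retrieval accuracy: perfect coupling wins, ties count as failures", {
  set.seed(81)
  tab <- random_expression_table(100, 5)
  truth <- setNames(colnames(tab), colnames(tab))
  acc <- retrieval_accuracy(tab, tab, truth, c(20, 100))
  expect_equal(unname(acc), c(1, 1))

  # two identical database columns tie at the maximum -> failure
  db <- cbind(unclass(tab), dup = unclass(tab)[, 1])
  db <- expression_table(db, "gene")
  acc_tie <- retrieval_accuracy(tab, db, truth, 50)
  expect_equal(unname(acc_tie), 4 / 5)
  expect_warning(retrieval_accuracy(tab, tab, truth, 1000), "capping")
})
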