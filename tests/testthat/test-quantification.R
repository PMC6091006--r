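test_that("frequency tables: percentages, column sums, count reconstruction", {
  asg <- data.frame(
    sample_id = rep("89-Mot", 16),
    loci = c(rep("chr3q12.3_K-5", 10), rep("chr7q34_K-15", 4),
             rep("a|b", 1), "unassigned"),
    stringsAsFactors = FALSE)
  ft <- frequency_table(asg)
  expect_equal(unname(ft$frequency["chr3q12.3_K-5", "89-Mot"]), 62.50)
  expect_equal(unname(colSums(ft$frequency)), 100)
  # single read, single locus -> 100%
  ft1 <- frequency_table(data.frame(sample_id = "s", loci = "x"))
  expect_equal(unname(ft1$frequency["x", "s"]), 100)
  # count reconstruction round-trip
  back <- counts_from_frequencies(round(ft$frequency, 2), ft$totals)
  expect_equal(unname(back), unname(ft$counts))
  # zero-read sample dropped with a warning
  meta <- sample_meta(c("89-Mot", "ghost"), condition = "ALS")
  expect_warning(frequency_table(asg, meta), "0 reads")
})

test_that("aggregation: per-sample mean vs pooled", {
  counts <- matrix(c(4L, 6L, 54L, 36L), nrow = 2,
                   dimnames = list(c("x", "y"), c("s1", "s2")))
  ft <- frequency_table_from_counts(counts)   # x: 40% of 10, 60% of 90
  meta <- sample_meta(c("s1", "s2"), condition = "ALS", tissue = "other")
  meta$g <- "all"
  m <- aggregate_frequencies(ft, meta, "g", "per_sample_mean")
  expect_equal(m$value[m$category == "x"], 50)
  p <- aggregate_frequencies(ft, meta, "g", "pooled")
  expect_equal(p$value[p$category == "x"], 58)
  # equal totals -> the two modes coincide
  counts2 <- matrix(c(4L, 6L, 2L, 8L), nrow = 2,
                    dimnames = list(c("x", "y"), c("s1", "s2")))
  ft2 <- frequency_table_from_counts(counts2)
  expect_equal(
    aggregate_frequencies(ft2, meta, "g", "per_sample_mean")$value,
    aggregate_frequencies(ft2, meta, "g", "pooled")$value)
})

test_that("group comparison: test selection and degenerate cases", {
  set.seed(42)
  x <- rnorm(10)
  # identical groups: t statistic 0, p = 1
  cmp <- compare_groups(c(x, x), rep(c("ALS", "control"), each = 10))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  # clear normal effect -> Welch t, small p
  y <- rnorm(20); z <- rnorm(20, mean = 2)
  cmp2 <- compare_groups(c(y, z), rep(c("a", "b"), each = 20))
  expect_identical(cmp2$test, "welch_t")
  expect_lt(cmp2$p_value, 0.01)
  # heavy-tailed data fail the normality screen -> rank-based test
  set.seed(9)
  h1 <- rcauchy(15); h2 <- rcauchy(15, location = 1)
  cmp3 <- compare_groups(c(h1, h2), rep(c("a", "b"), each = 15))
  expect_identical(cmp3$test, "wilcoxon_rank_sum")
  expect_error(compare_groups(c(1, 2, 1, 2), rep(c("a", "b"), 2)),
               "insufficient")
})

test_that("ddCt: reference fold 1, closed forms, shift invariance", {
  ct <- ct_table(
    sample_id = rep(c("H9-hESC", "s1"), each = 4),
    target = rep(c("HML2_gag", "HML2_gag", "GAPDH", "GAPDH"), 2),
    ct = c(20, 20, 15, 15,    26, 26, 18, 18),
    reference_sample_id = "H9-hESC")
  f <- ddct_fold_change(ct)
  expect_equal(f$fold_change[f$sample_id == "H9-hESC"], 1)
  # sample delta-Ct exceeds the reference's by 3 -> fold 0.125
  expect_equal(f$fold_change[f$sample_id == "s1"], 0.125)
  # +1 on every Ct leaves folds unchanged
  ct2 <- ct_table(ct$sample_id, ct$target, ct$ct + 1,
                  reference_sample_id = "H9-hESC")
  expect_equal(ddct_fold_change(ct2)$fold_change, f$fold_change)
  # missing normalizer -> sample skipped with warning
  expect_warning(
    ct3 <- ct_table(
      sample_id = c(rep("H9-hESC", 4), "s1", "s1"),
      target = c("HML2_gag", "HML2_gag", "GAPDH", "GAPDH",
                 "HML2_gag", "HML2_gag"),
      ct = c(20, 20, 15, 15, 26, 26),
      reference_sample_id = "H9-hESC"),
    "without normalizer")
  expect_warning(f3 <- ddct_fold_change(ct3), "skipping")
  expect_false("s1" %in% f3$sample_id)
})

test_that("noiseless Ct simulation recovers planted folds exactly", {
  set.seed(1)
  folds <- c(s1 = 0.125, s2 = 2, s3 = 0.01)
  ct <- simulate_ct_table(folds, replicate_sd = 0)
  f <- ddct_fold_change(ct)
  expect_equal(f$fold_change[match(names(folds), f$sample_id)],
               unname(folds))
  expect_equal(f$delta_delta_ct[f$sample_id == "s1"], 3)
  # noisy recovery within the propagated-error bound
  set.seed(2)
  folds50 <- setNames(2^runif(50, -8, 2), sprintf("n%02d", 1:50))
  ctn <- simulate_ct_table(folds50, replicate_sd = 0.2, n_replicates = 4L)
  fn <- ddct_fold_change(ctn)
  err <- abs(log2(fn$fold_change[match(names(folds50), fn$sample_id)]) -
               log2(folds50))
  expect_lt(mean(err), 3 * 0.2 / sqrt(4))
})

test_that("QC correlation: closed forms and the null", {
  x <- 1:10
  expect_equal(suppressWarnings(qc_correlation(x, 3 * x - 2)), 1.0)
  expect_equal(qc_correlation(c(0, 1, 2), c(0, 1, 0)), 0.0)
  set.seed(77)
  expect_lt(qc_correlation(rnorm(1000), rnorm(1000)), 0.02)
  expect_error(qc_correlation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(qc_correlation(1:2, 1:2), "at least 3")
})

test_that("rank-based branch agrees with a label-permutation oracle", {
  set.seed(123)
  # heavy-tailed: a gross outlier in each group defeats the normality screen
  x <- c(0.11, 0.23, 0.18, 0.31, 0.27, 0.15, 0.09, 0.36, 0.22, 9.4)
  y <- c(1.02, 1.31, 0.88, 1.22, 0.97, 1.41, 1.13, 0.79, 1.27, 14.8)
  cmp <- compare_groups(c(x, y), rep(c("a", "b"), each = 10))
  expect_identical(cmp$test, "wilcoxon_rank_sum")
  # the exact rank-sum null IS the permutation distribution of the rank sum
  stat <- function(a, b) sum(rank(c(a, b))[seq_along(a)]) -
    length(a) * (length(a) + length(b) + 1) / 2
  p_perm <- oracle_permutation_p(x, y, stat, n_perm = 4000L)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(cmp$p_value - p_perm), 3 * mc_se + 0.005)
})
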