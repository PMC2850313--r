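test_that("vectorized t-tests agree with stats::t.test site by site", {
  set.seed(5)
  n <- 24; m <- 40
  vals <- matrix(runif(n * m, 0.2, 0.8), n, m)
  g <- rep(c(1, 0), c(9, 15))
  bm <- toy_bm(vals)
  for (variant in c("pooled", "welch")) {
    res <- ttest_by_group(bm, g, variant = variant)
    for (j in seq_len(m)) {
      ref <- t.test(vals[g == 1, j], vals[g == 0, j],
                    var.equal = (variant == "pooled"))
      expect_equal(res$statistic[j], unname(ref$statistic), tolerance = 1e-12)
      expect_equal(res$p_value[j], ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("t-test direction, null and degenerate cases behave as specified", {
  vals <- cbind(c(0.2, 0.3, 0.25, 0.6, 0.7, 0.65),   # higher in group 1
                c(0.6, 0.7, 0.65, 0.2, 0.3, 0.25),   # higher in group 0
                c(0.1, 0.2, 0.3, 0.3, 0.2, 0.1),     # equal means
                c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))     # zero variance
  g <- rep(c(0, 1), each = 3)
  res <- ttest_by_group(toy_bm(vals), g)
  expect_equal(res$direction[1:2], c("higher_in_group1", "higher_in_group0"))
  expect_equal(res$statistic[3], 0, tolerance = 1e-12)
  expect_equal(res$p_value[3], 1, tolerance = 1e-12)
  expect_true(res$degenerate[4])
  expect_equal(res$p_value[4], 1)
  expect_equal(res$direction[4], "undefined")
  expect_true(is.na(res$statistic[4]))
})

test_that("missing betas are dropped pairwise per site", {
  set.seed(8)
  vals <- matrix(runif(10 * 3, 0.2, 0.8), 10, 3)
  vals[1, 2] <- NA
  g <- rep(c(1, 0), each = 5)
  res <- ttest_by_group(toy_bm(vals), g)
  expect_equal(res$n_used, c(10L, 9L, 10L))
  ref <- t.test(vals[2:5, 2], vals[6:10, 2], var.equal = TRUE)
  expect_equal(res$p_value[2], ref$p.value, tolerance = 1e-12)
})

test_that("sitewise Pearson correlations agree with stats::cor.test", {
  set.seed(9)
  n <- 50; m <- 30
  vals <- matrix(runif(n * m, 0.1, 0.9), n, m)
  y <- rnorm(n, 35, 10)
  res <- correlate_with_phenotype(toy_bm(vals), y, name = "age")
  for (j in seq_len(m)) {
    ref <- cor.test(vals[, j], y)
    expect_equal(res$statistic[j], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p_value[j], ref$p.value, tolerance = 1e-10)
  }
  expect_true(all(res$n_used == n))
})

test_that("correlation identities: r = 1 on itself, r = -1 on its negation", {
  y <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  bm <- toy_bm(cbind(y, rev(y), 1 - y))
  res <- correlate_with_phenotype(bm, y)
  expect_equal(res$statistic[1], 1)
  expect_equal(res$p_value[1], 0)
  expect_equal(res$statistic[3], -1)
  expect_equal(res$direction[1:3],
               c("positive_corr", "negative_corr", "negative_corr"))
})

test_that("correlation is symmetric and invariant to affine rescaling", {
  set.seed(10)
  x <- runif(40, 0.2, 0.8)
  y <- rnorm(40)
  r1 <- correlate_with_phenotype(toy_bm(cbind(x)), y)$statistic
  # symmetry via direct cor on swapped arguments
  expect_equal(r1, cor(y, x), tolerance = 1e-12)
  r2 <- correlate_with_phenotype(toy_bm(cbind(x)), 3 * y + 7)$statistic
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("degenerate correlations are flagged, not silently numeric", {
  vals <- cbind(rep(0.5, 6), runif(6, 0.2, 0.8))
  res <- correlate_with_phenotype(toy_bm(vals), rnorm(6))
  expect_true(res$degenerate[1])
  expect_true(is.na(res$p_value[1]))
  res2 <- correlate_with_phenotype(toy_bm(vals), rep(2, 6))
  expect_true(all(res2$degenerate))
})

test_that("Bonferroni thresholds are alpha over the family size", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 20493), 0.05 / 20493)
  expect_equal(bonferroni_threshold(0.05, 20493), 2.440e-6, tolerance = 1e-3)
  # the factor-level family: alpha / 26 lets p = 1.82e-3 pass but not 2.7e-3
  thr <- bonferroni_threshold(0.05, 26)
  expect_equal(thr, 1.923e-3, tolerance = 1e-3)
  expect_lt(1.82e-3, thr)
  expect_gt(2.7e-3, thr)
  expect_error(bonferroni_threshold(0.05, 0), class = "bad_threshold")
})

test_that("summaries count significance and direction correctly", {
  res <- data.frame(site_id = c("a", "b", "c"), gene = "", chromosome = "1",
                    phenotype = "sex", test = "t_pooled",
                    statistic = c(3, -1, 0.1), p_value = c(0.01, 0.2, 0.9),
                    direction = c("higher_in_group1", "higher_in_group0",
                                  "higher_in_group1"),
                    n_used = 10L, degenerate = FALSE)
  s_unc <- summarize_results(res, alpha = 0.05, correction = "none")
  expect_equal(s_unc$n_significant, 1L)
  s_bon <- summarize_results(res, alpha = 0.05, correction = "bonferroni")
  expect_equal(s_bon$threshold, 0.05 / 3, tolerance = 1e-12)
  expect_equal(s_bon$n_significant, 1L)
  expect_equal(s_bon$direction_tally[["higher_in_group1"]], 1L)
  expect_equal(s_bon$min_p, 0.01)
  expect_equal(s_bon$max_abs_statistic, 3)
  expect_error(summarize_results(res[0, ]), class = "empty_result")
})

test_that("summaries equal a brute-force recount on randomized inputs", {
  set.seed(12)
  for (i in 1:10) {
    nr <- sample(20:80, 1)
    res <- data.frame(site_id = sprintf("s%d", seq_len(nr)), gene = "",
                      chromosome = "1", phenotype = "x", test = "t_pooled",
                      statistic = rnorm(nr),
                      p_value = runif(nr)^2,
                      direction = "undefined", n_used = 10L,
                      degenerate = FALSE)
    res$direction <- ifelse(res$statistic > 0, "higher_in_group1",
                            "higher_in_group0")
    alpha <- runif(1, 0.01, 0.2)
    s <- summarize_results(res, alpha = alpha, correction = "bonferroni")
    thr <- alpha / nr
    expect_equal(s$n_significant, sum(res$p_value <= thr))
    expect_equal(sum(s$direction_tally), s$n_significant)
    expect_equal(s$min_p, min(res$p_value))
  }
})

test_that("pooled and Welch t agree under equal group sizes and variances", {
  x <- c(0.2, 0.4, 0.3, 0.5)
  y <- c(0.6, 0.8, 0.7, 0.9)  # same spread, shifted
  bm <- toy_bm(cbind(c(x, y)))
  g <- rep(c(0, 1), each = 4)
  tp <- ttest_by_group(bm, g, "pooled")
  tw <- ttest_by_group(bm, g, "welch")
  expect_equal(tp$statistic, tw$statistic, tolerance = 1e-12)
  expect_equal(tp$p_value, tw$p_value, tolerance = 1e-12)
})

test_that("gene overlap rates report counts and half-up rounded percent", {
  r <- gene_overlap_rate(c("A", "B"), c("A", "B"), c("A", "B", "C"))
  expect_equal(r$percent, 100)
  # 7 of 13 -> 53.85 -> 54; 1 of 8 -> 12.5 -> 13 (half-up)
  u <- sprintf("g%02d", 1:40)
  expect_equal(gene_overlap_rate(u[1:13], u[1:7], u)$percent, 54)
  expect_equal(gene_overlap_rate(u[1:8], u[1], u)$percent, 13)
  expect_error(gene_overlap_rate("zz", u[1], u), class = "empty_result")
})

test_that("gene-level significance means any significant site of the gene", {
  res <- data.frame(site_id = c("s1", "s2", "s3", "s4"),
                    gene = c("G1", "G1", "G2", ""),
                    chromosome = "X", phenotype = "sex", test = "t_pooled",
                    statistic = c(5, 0.1, -4, 6),
                    p_value = c(1e-6, 0.8, 1e-5, 1e-9),
                    direction = "higher_in_group1", n_used = 10L,
                    degenerate = FALSE)
  expect_equal(significant_genes(res, alpha = 0.05, correction = "none"),
               c("G1", "G2"))
})

test_that("the full scan produces one table per phenotype", {
  co <- small_cohort(seed = 6)
  res <- associate_phenotypes(co$data, co$phenotypes)
  expect_named(res, c("sex", "age", "audit", "cigarettes"))
  expect_equal(unique(res$sex$test), "t_pooled")
  expect_equal(unique(res$age$test), "pearson")
  expect_equal(nrow(res$sex), ncol(co$data$values))
})
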