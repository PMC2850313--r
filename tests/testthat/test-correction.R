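# Build a fake profiles table the way profile_factors() would.
mk_profiles <- function(df, k, alpha = 0.05, group_name = "sex") {
  df$significant <- df$p_value <= alpha / k
  attr(df, "k") <- k
  attr(df, "alpha") <- alpha
  attr(df, "group_name") <- group_name
  class(df) <- c("factor_profiles", "data.frame")
  df
}

test_that("a factor equal to the sex coding profiles as sex-only", {
  set.seed(31)
  n <- 60
  sex <- rep(c(1, 0), c(20, 40))
  mixing <- cbind(sex + rnorm(n, 0, 0.05), rnorm(n), rnorm(n))
  rownames(mixing) <- sprintf("subj%03d", 1:n)
  d <- structure(list(mixing = mixing, k = 3L, method = "ica",
                      sources = matrix(rnorm(3 * 10), 3, 10)),
                 class = "factor_decomposition")
  ph <- phenotype_table(rownames(mixing), ifelse(sex == 1, "F", "M"),
                        group_name = "sex",
                        continuous = data.frame(age = rnorm(n, 35, 8)))
  prof <- profile_factors(d, ph, alpha = 0.05)
  expect_equal(nrow(prof), 6L)
  sex1 <- prof[prof$factor == 1 & prof$phenotype == "sex", ]
  expect_lt(sex1$p_value, 1e-10)
  expect_true(sex1$significant)
  expect_false(any(prof$significant[prof$factor == 1 &
                                      prof$phenotype == "age"]))
  # profile values agree with direct t.test / cor.test calls
  ref <- t.test(mixing[sex == 1, 1], mixing[sex == 0, 1], var.equal = TRUE)
  expect_equal(sex1$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("pure-noise factors are essentially never significant after factor-level correction", {
  set.seed(32)
  n <- 100; k <- 26
  hits <- 0L
  for (rep in 1:20) {
    mixing <- matrix(rnorm(n * k), n, k)
    rownames(mixing) <- sprintf("subj%03d", 1:n)
    d <- structure(list(mixing = mixing, k = k, method = "ica"),
                   class = "factor_decomposition")
    ph <- phenotype_table(rownames(mixing),
                          rep(c("F", "M"), c(30, 70)),
                          group_name = "sex",
                          continuous = data.frame(age = rnorm(n, 35, 8)))
    prof <- profile_factors(d, ph, alpha = 0.05)
    hits <- hits + sum(prof$significant)
  }
  # 20 replicates x 52 corrected tests at alpha/k: expect ~ 2 hits in total
  expect_lte(hits, 6L)
})

test_that("factor selection keeps the clean sex factor and excludes cross-associated ones", {
  # two sex-significant factors among 26: A clean (p ~ 2.5e-69), B with
  # marginal audit/cigarette associations at 0.05 / 0.02
  phenos <- c("ads", "audit", "max_drinks", "cigarettes", "age", "mj_days")
  rows <- list()
  for (f in 1:3) {
    p_sex <- c(2.53e-69, 1.82e-3, 0.4)[f]
    rows[[length(rows) + 1L]] <-
      data.frame(factor = f, phenotype = "sex", test = "t_test",
                 statistic = c(27.62, 3.16, 0.5)[f], p_value = p_sex)
    p_prot <- rep(0.3, 6)
    if (f == 2) p_prot[c(2, 4)] <- c(0.05, 0.02)
    for (i in seq_along(phenos)) {
      rows[[length(rows) + 1L]] <-
        data.frame(factor = f, phenotype = phenos[i], test = "pearson",
                   statistic = 0.1, p_value = p_prot[i])
    }
  }
  prof <- mk_profiles(do.call(rbind, rows), k = 26)
  expect_message(
    rep_out <- identify_sex_factor(prof, target = "sex",
                                   protected_alpha = 0.05),
    "excluded")
  expect_equal(rep_out$factor_index, 1L)
  expect_equal(rep_out$target_p, 2.53e-69)
  expect_equal(rep_out$excluded$factor, 2L)
  expect_match(rep_out$excluded$conflicting_phenotypes,
               "audit.*cigarettes|cigarettes.*audit")
})

test_that("no qualifying factor raises the documented errors", {
  base <- data.frame(factor = 1:2,
                     phenotype = "sex", test = "t_test",
                     statistic = 1, p_value = c(0.5, 0.9))
  expect_error(identify_sex_factor(mk_profiles(base, k = 2), target = "sex"),
               class = "no_sex_factor")
  # sex-significant but dirty on a protected phenotype
  rows <- rbind(
    data.frame(factor = 1, phenotype = "sex", test = "t_test",
               statistic = 10, p_value = 1e-20),
    data.frame(factor = 1, phenotype = "audit", test = "pearson",
               statistic = 0.3, p_value = 0.01))
  expect_error(
    suppressMessages(identify_sex_factor(mk_profiles(rows, k = 1),
                                         target = "sex")),
    class = "no_clean_sex_factor")
})

test_that("several clean candidates: smallest sex P wins with a warning", {
  rows <- rbind(
    data.frame(factor = 1:2, phenotype = "sex", test = "t_test",
               statistic = c(8, 12), p_value = c(1e-10, 1e-30)),
    data.frame(factor = 1:2, phenotype = "age", test = "pearson",
               statistic = 0.02, p_value = 0.8))
  expect_warning(out <- identify_sex_factor(mk_profiles(rows, k = 2),
                                            target = "sex"),
                 "2 factors qualify")
  expect_equal(out$factor_index, 2L)
})

test_that("factor removal annihilates a planted rank-one structure", {
  set.seed(33)
  n <- 20; m <- 30
  mu <- runif(m, 0.3, 0.6)
  w <- rnorm(n, 0, 0.05)
  s <- rnorm(m)
  vals <- sweep(outer(w, s), 2, mu, `+`)
  bm <- beta_matrix(pmin(pmax(vals, 0), 1), range_check = FALSE,
                    subject_ids = sprintf("s%02d", 1:n))
  cen <- center_matrix(bm)
  d <- pca_decompose(cen)
  corrected <- remove_factor(bm, d, 1)
  resid <- sweep(corrected$values, 2, cen$site_means, `-`)
  expect_equal(max(abs(resid)), 0, tolerance = 1e-10)
})

test_that("removal is an exact rank-one subtraction for any factor and input", {
  set.seed(34)
  for (i in 1:20) {
    n <- sample(8:20, 1); m <- sample(10:40, 1)
    vals <- matrix(runif(n * m, 0.1, 0.9), n, m)
    bm <- toy_bm(vals)
    d <- pca_decompose(center_matrix(bm))
    f <- sample(d$k, 1)
    corrected <- remove_factor(bm, d, f)
    rank1 <- tcrossprod(d$mixing[, f], d$sources[f, ])
    expect_equal(corrected$values + rank1, vals,
                 tolerance = 1e-12, ignore_attr = TRUE)
    # residual projection of the centered part onto the removed factor is 0
    cen_corr <- sweep(corrected$values, 2, colMeans(vals), `-`)
    proj <- as.vector(cen_corr %*% d$sources[f, ]) /
      sqrt(sum(d$sources[f, ]^2))
    expect_equal(max(abs(proj)) / max(abs(d$mixing[, f])), 0,
                 tolerance = 1e-8)
  }
})

test_that("out-of-range corrected values are preserved, counted, and clippable", {
  set.seed(35)
  vals <- matrix(runif(60, 0.01, 0.99), 6, 10)
  vals[, 1] <- c(0.999, 0.998, 0.997, 0.01, 0.02, 0.01)
  bm <- toy_bm(vals)
  d <- pca_decompose(center_matrix(bm))
  corrected <- remove_factor(bm, d, 1)
  n_out <- attr(corrected, "n_out_of_range")
  expect_equal(n_out, sum(corrected$values < 0 | corrected$values > 1))
  clipped <- remove_factor(bm, d, 1, clip = TRUE)
  expect_true(all(clipped$values >= 0 & clipped$values <= 1))
  expect_equal(attr(clipped, "n_out_of_range"), n_out)
  expect_error(remove_factor(bm, d, 99), class = "bad_index")
})

test_that("before/after comparison set arithmetic is exact", {
  mk <- function(p) data.frame(site_id = sprintf("s%d", seq_along(p)),
                               gene = "", chromosome = "1",
                               phenotype = "sex", test = "t_pooled",
                               statistic = 1, p_value = p,
                               direction = "higher_in_group1",
                               n_used = 10L, degenerate = FALSE)
  before <- list(sex = mk(c(1e-9, 1e-8, 0.5, 0.7)))
  # identical inputs: everything common
  cmp <- compare_before_after(before, before, correction = "none")
  expect_equal(cmp$table$n_common, 2L)
  expect_equal(cmp$table$n_gained + cmp$table$n_lost, 0L)
  # disjoint significant sets
  after <- list(sex = mk(c(0.5, 0.9, 1e-9, 1e-8)))
  cmp2 <- compare_before_after(before, after, correction = "none")
  expect_equal(cmp2$table$n_common, 0L)
  expect_equal(sort(cmp2$sites$sex$gained), c("s3", "s4"))
  expect_equal(sort(cmp2$sites$sex$lost), c("s1", "s2"))
  # mismatched universes error
  other <- list(sex = mk(c(0.1, 0.2))[1:2, ])
  expect_error(compare_before_after(before, other, correction = "none"),
               class = "mismatched_universe")
})

test_that("correction leaves age associations essentially untouched", {
  co <- simulate_cohort(simulation_config(
    n_subjects = 200L, n_sites = 800L, x_chrom_sites = 60L,
    sex_factor = list(n_loaded_x = 25L, n_loaded_autosomal = 15L),
    age_factor = list(n_loaded = 25L), seed = 9))
  qc <- qc_filter_sites(co$data)
  cen <- center_matrix(qc$data)
  k <- select_components_by_variance(pca_decompose(cen), 0.99)
  d <- suppressWarnings(infomax_ica(cen, k = k, seed = 9))
  ph <- align_phenotypes(qc$data, co$phenotypes)
  prof <- profile_factors(d, ph)
  sf <- suppressWarnings(suppressMessages(
    identify_sex_factor(prof, "sex", decomp = d, groups = ph$sex)))
  corrected <- remove_factor(qc$data, d, sf$factor_index)
  r_before <- correlate_with_phenotype(qc$data, ph$age)$statistic
  r_after <- correlate_with_phenotype(corrected, ph$age)$statistic
  age_idx <- match(intersect(co$truth$age_sites$site_id,
                             qc$data$sites$site_id),
                   qc$data$sites$site_id)
  expect_lt(max(abs(r_before[age_idx] - r_after[age_idx])), 0.02)
})

test_that("removing a non-sex factor leaves sitewise sex statistics unchanged", {
  co <- small_cohort(seed = 13)
  qc <- qc_filter_sites(co$data)
  cen <- center_matrix(qc$data)
  d <- suppressWarnings(infomax_ica(cen, k = 10, seed = 13))
  ph <- align_phenotypes(qc$data, co$phenotypes)
  t_before <- ttest_by_group(qc$data, ph$sex)
  # pick the factor least correlated with sex
  cors <- abs(cor(d$mixing, ph$sex))
  noise_f <- which.min(cors)
  corrected <- remove_factor(qc$data, d, noise_f)
  t_after <- ttest_by_group(corrected, ph$sex)
  expect_gt(cor(t_before$statistic, t_after$statistic), 0.98)
  expect_identical(
    significant_sites(t_before, 0.05, "bonferroni"),
    significant_sites(t_after, 0.05, "bonferroni"))
})
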