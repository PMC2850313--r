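# Sitewise association tests: vectorized two-sample t-tests against a
# binary phenotype, Pearson correlations against continuous phenotypes,
# Bonferroni control, summaries and cross-dataset gene overlap rates.

#' Two-sample t-test at every methylation site
#'
#' Vectorized over sites. The default pooled-variance Student's t is the
#' conventional two-sample test; Welch's unequal-variance variant is
#' available by flag. Missing beta values are handled pairwise: a subject
#' missing a site is dropped from that site's test only.
#'
#' `direction` records the sign of `mean(group 1) - mean(group 0)`; with
#' the package's coding convention group 1 is the female group, so
#' `"higher_in_group1"` means higher methylation in females. Sites with
#' zero variance in both groups (or fewer than two observed subjects per
#' group) are reported as degenerate with an undefined direction and
#' P-value 1.
#'
#' @param data a [beta_matrix()].
#' @param groups binary 0/1 vector, one entry per subject, or a
#'   `phenotype_table` (its grouping column is used).
#' @param variant `"pooled"` (Student) or `"welch"`.
#' @param phenotype label stored in the result (default the group name).
#' @return a `data.frame` (one row per site) with columns `site_id`,
#'   `gene`, `chromosome`, `phenotype`, `test`, `statistic`, `p_value`,
#'   `direction`, `n_used`, `degenerate`.
#' @export
ttest_by_group <- function(data, groups, variant = c("pooled", "welch"),
                           phenotype = NULL) {
  stopifnot(inherits(data, "beta_matrix"))
  variant <- match.arg(variant)
  if (inherits(groups, "phenotype_table")) {
    phenotype <- phenotype %||% attr(groups, "group_name")
    groups <- align_phenotypes(data, groups)[[attr(groups, "group_name")]]
  }
  phenotype <- phenotype %||% "group"
  if (length(groups) != nrow(data$values)) {
    stop_mica("groups length (%d) != number of subjects (%d)",
              length(groups), nrow(data$values), class = "bad_dimensions")
  }
  if (!all(groups %in% c(0, 1, NA))) {
    stop_mica("groups must be coded 0/1", class = "bad_group_levels")
  }
  x <- data$values
  x1 <- x[!is.na(groups) & groups == 1, , drop = FALSE]
  x0 <- x[!is.na(groups) & groups == 0, , drop = FALSE]
  n1 <- colSums(!is.na(x1)); n0 <- colSums(!is.na(x0))
  m1 <- colMeans(x1, na.rm = TRUE); m0 <- colMeans(x0, na.rm = TRUE)
  v1 <- col_vars(x1); v0 <- col_vars(x0)

  if (variant == "pooled") {
    df <- n1 + n0 - 2
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  } else {
    a <- v1 / n1; b <- v0 / n0
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n0 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * pt(-abs(tstat), df)

  too_few <- n1 < 2 | n0 < 2
  zero_var <- !too_few & se == 0
  degenerate <- too_few | zero_var
  tstat[degenerate] <- NA_real_
  p[zero_var] <- 1
  p[too_few] <- NA_real_

  direction <- ifelse(degenerate | m1 == m0, "undefined",
                      ifelse(m1 > m0, "higher_in_group1", "higher_in_group0"))
  data.frame(site_id = data$sites$site_id,
             gene = data$sites$gene,
             chromosome = data$sites$chromosome,
             phenotype = phenotype,
             test = paste0("t_", variant),
             statistic = unname(tstat),
             p_value = unname(p),
             direction = direction,
             n_used = unname(n1 + n0),
             degenerate = unname(degenerate),
             stringsAsFactors = FALSE)
}

#' Pearson correlation of every site with a continuous phenotype
#'
#' Pairwise-complete: subjects missing either the site value or the
#' phenotype are dropped for that site only. Two-sided P-values come from
#' the t transform of r on `n - 2` degrees of freedom. Sites (or a
#' phenotype) with zero variance, or fewer than 3 complete pairs, are
#' flagged degenerate with an undefined direction.
#'
#' @param data a [beta_matrix()].
#' @param phenotype numeric vector, one value per subject (missing
#'   allowed).
#' @param name phenotype label stored in the result.
#' @return a `data.frame` with the same columns as [ttest_by_group()];
#'   `statistic` is Pearson's r.
#' @export
correlate_with_phenotype <- function(data, phenotype, name = "phenotype") {
  stopifnot(inherits(data, "beta_matrix"))
  if (length(phenotype) != nrow(data$values)) {
    stop_mica("phenotype length (%d) != number of subjects (%d)",
              length(phenotype), nrow(data$values), class = "bad_dimensions")
  }
  x <- data$values
  y <- as.numeric(phenotype)
  r <- suppressWarnings(as.vector(cor(x, y, use = "pairwise.complete.obs")))
  n <- colSums(!is.na(x) & !is.na(y))
  degenerate <- is.na(r) | n < 3
  r[degenerate] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[!degenerate & is.infinite(tstat)] <- 0  # |r| == 1 exactly
  p[degenerate] <- NA_real_
  direction <- ifelse(degenerate, "undefined",
                      ifelse(r > 0, "positive_corr",
                             ifelse(r < 0, "negative_corr", "undefined")))
  data.frame(site_id = data$sites$site_id,
             gene = data$sites$gene,
             chromosome = data$sites$chromosome,
             phenotype = name,
             test = "pearson",
             statistic = unname(r),
             p_value = unname(p),
             direction = direction,
             n_used = unname(n),
             degenerate = unname(degenerate),
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha family-wise error rate (e.g. 0.05).
#' @param n_tests number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    stop_mica("n_tests must be a positive count", class = "bad_threshold")
  }
  alpha / n_tests
}

#' Summarize a sitewise association scan
#'
#' Computes the minimum P-value, maximum absolute statistic, number of
#' significant sites under the requested correction, and (for group
#' tests) the direction tally of the significant sites: how many are
#' higher in group 1 (females) versus group 0 (males).
#'
#' @param results result `data.frame` from [ttest_by_group()] or
#'   [correlate_with_phenotype()] (a single phenotype).
#' @param alpha family-wise significance level.
#' @param correction `"bonferroni"` or `"none"`.
#' @param n_tests family size for the correction; defaults to the number
#'   of sites in `results`.
#' @return an `assoc_summary` list.
#' @export
summarize_results <- function(results, alpha = 0.05,
                              correction = c("bonferroni", "none"),
                              n_tests = NULL) {
  correction <- match.arg(correction)
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop_mica("empty result list", class = "empty_result")
  }
  if (length(unique(results$phenotype)) != 1L) {
    stop_mica("results mix phenotypes: %s",
              paste(unique(results$phenotype), collapse = ", "),
              class = "mixed_phenotypes")
  }
  n_tests <- n_tests %||% nrow(results)
  threshold <- if (correction == "bonferroni") {
    bonferroni_threshold(alpha, n_tests)
  } else {
    alpha
  }
  sig <- !is.na(results$p_value) & results$p_value <= threshold
  is_group_test <- any(grepl("^t_", results$test))
  tally <- if (is_group_test) {
    c(higher_in_group1 = sum(sig & results$direction == "higher_in_group1"),
      higher_in_group0 = sum(sig & results$direction == "higher_in_group0"))
  } else {
    NULL
  }
  structure(list(phenotype = results$phenotype[1L],
                 test = results$test[1L],
                 min_p = suppressWarnings(min(results$p_value, na.rm = TRUE)),
                 max_abs_statistic = suppressWarnings(
                   max(abs(results$statistic), na.rm = TRUE)),
                 n_significant = sum(sig),
                 alpha = alpha,
                 correction = correction,
                 n_tests = n_tests,
                 threshold = threshold,
                 direction_tally = tally),
            class = "assoc_summary")
}

#' @export
print.assoc_summary <- function(x, ...) {
  cat(sprintf("%s (%s): min P = %.3g, max |stat| = %.3g, %d significant (%s alpha=%g, %d tests)\n",
              x$phenotype, x$test, x$min_p, x$max_abs_statistic,
              x$n_significant, x$correction, x$alpha, x$n_tests))
  if (!is.null(x$direction_tally)) {
    cat(sprintf("  direction: %d higher in group 1, %d higher in group 0\n",
                x$direction_tally[["higher_in_group1"]],
                x$direction_tally[["higher_in_group0"]]))
  }
  invisible(x)
}

#' Site ids significant under a correction
#'
#' @inheritParams summarize_results
#' @return character vector of significant `site_id`s.
#' @export
significant_sites <- function(results, alpha = 0.05,
                              correction = c("bonferroni", "none"),
                              n_tests = NULL) {
  correction <- match.arg(correction)
  n_tests <- n_tests %||% nrow(results)
  threshold <- if (correction == "bonferroni") {
    bonferroni_threshold(alpha, n_tests)
  } else {
    alpha
  }
  results$site_id[!is.na(results$p_value) & results$p_value <= threshold]
}

#' Genes significant under a correction
#'
#' A gene counts as significant when any of its sites is.
#'
#' @inheritParams summarize_results
#' @return character vector of gene symbols.
#' @export
significant_genes <- function(results, alpha = 0.05,
                              correction = c("bonferroni", "none"),
                              n_tests = NULL) {
  ids <- significant_sites(results, alpha, match.arg(correction), n_tests)
  genes <- results$gene[results$site_id %in% ids]
  sort(unique(genes[!is.na(genes) & genes != ""]))
}

#' Overlap rate of significant genes between two data sets
#'
#' The rate asks: of the genes found significant in data set A that were
#' assayed in both platforms (`universe`), what fraction was also found
#' significant in data set B? The percentage is rounded half-up; the
#' exact counts are always reported alongside.
#'
#' @param set_a significant genes from data set A.
#' @param set_b significant genes from data set B.
#' @param universe genes assayed in both data sets.
#' @return list with `overlap_count`, `denominator`, `percent`.
#' @export
gene_overlap_rate <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  eligible <- intersect(set_a, universe)
  if (length(eligible) == 0L) {
    stop_mica("no genes from set A are in the shared universe",
              class = "empty_result")
  }
  overlap <- intersect(eligible, set_b)
  list(overlap_count = length(overlap),
       denominator = length(eligible),
       percent = round_half_up(100 * length(overlap) / length(eligible)))
}

#' Run the full sitewise association scan
#'
#' Applies [ttest_by_group()] to the grouping phenotype and
#' [correlate_with_phenotype()] to every continuous phenotype, returning
#' one result table per phenotype.
#'
#' @param data a [beta_matrix()].
#' @param phenotypes a `phenotype_table` (aligned by subject id).
#' @param variant t-test variant, see [ttest_by_group()].
#' @return named list of result `data.frame`s, grouping phenotype first.
#' @export
associate_phenotypes <- function(data, phenotypes,
                                 variant = c("pooled", "welch")) {
  stopifnot(inherits(data, "beta_matrix"),
            inherits(phenotypes, "phenotype_table"))
  variant <- match.arg(variant)
  ph <- align_phenotypes(data, phenotypes)
  gname <- attr(ph, "group_name")
  out <- list()
  out[[gname]] <- ttest_by_group(data, ph[[gname]], variant = variant,
                                 phenotype = gname)
  for (nm in continuous_phenotypes(ph)) {
    out[[nm]] <- correlate_with_phenotype(data, ph[[nm]], name = nm)
  }
  out
}

#' Write association results as TSV
#'
#' @param results result `data.frame` (any phenotype), with a
#'   `significant_flag` column added under the given correction.
#' @param path output file path.
#' @param alpha,correction,n_tests see [summarize_results()].
#' @return `path`, invisibly.
#' @export
write_association_results <- function(results, path, alpha = 0.05,
                                      correction = c("bonferroni", "none"),
                                      n_tests = NULL) {
  correction <- match.arg(correction)
  sig <- significant_sites(results, alpha, correction, n_tests)
  results$significant_flag <- results$site_id %in% sig
  data.table::fwrite(results, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
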