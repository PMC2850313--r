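# Profile latent factors against phenotypes, identify the factor that is
# associated with the target phenotype (sex) and with nothing else,
# remove its rank-one contribution from the data, and compare sitewise
# association results before and after the correction.

#' Test every factor against every phenotype
#'
#' For the binary grouping phenotype a two-sample t-test (pooled
#' variance) is run on the factor's subject weights; for each continuous
#' phenotype a Pearson correlation. Within each phenotype the
#' significance threshold is Bonferroni-corrected across the K factors.
#'
#' @param decomp a `factor_decomposition`.
#' @param phenotypes a `phenotype_table`; subject ids must match the
#'   decomposition's mixing-matrix rows.
#' @param alpha family-wise level for the factor-level correction.
#' @return a `factor_profiles` data.frame with columns `factor`,
#'   `phenotype`, `test`, `statistic`, `p_value`, `significant`
#'   (Bonferroni across factors), plus attributes `k` and `alpha`.
#' @export
profile_factors <- function(decomp, phenotypes, alpha = 0.05) {
  stopifnot(inherits(decomp, "factor_decomposition"),
            inherits(phenotypes, "phenotype_table"))
  subj <- rownames(decomp$mixing)
  if (is.null(subj)) subj <- phenotypes$subject_id
  idx <- match(subj, phenotypes$subject_id)
  if (anyNA(idx) || length(subj) != nrow(decomp$mixing)) {
    stop_mica("subjects of decomposition and phenotype table do not align",
              class = "misaligned_subjects")
  }
  ph <- phenotypes[idx, , drop = FALSE]
  gname <- attr(phenotypes, "group_name")
  cont <- setdiff(names(ph), c("subject_id", gname))
  k <- decomp$k
  thr <- bonferroni_threshold(alpha, k)

  rows <- vector("list", k * (1L + length(cont)))
  ri <- 0L
  for (j in seq_len(k)) {
    w <- decomp$mixing[, j]
    g <- ph[[gname]]
    tt <- t.test(w[g == 1], w[g == 0], var.equal = TRUE)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(factor = j, phenotype = gname, test = "t_test",
                             statistic = unname(tt$statistic),
                             p_value = tt$p.value,
                             stringsAsFactors = FALSE)
    for (nm in cont) {
      y <- ph[[nm]]
      ok <- !is.na(y)
      ct <- cor.test(w[ok], y[ok], method = "pearson")
      ri <- ri + 1L
      rows[[ri]] <- data.frame(factor = j, phenotype = nm, test = "pearson",
                               statistic = unname(ct$estimate),
                               p_value = ct$p.value,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value <= thr
  attr(out, "k") <- k
  attr(out, "alpha") <- alpha
  attr(out, "group_name") <- gname
  class(out) <- c("factor_profiles", "data.frame")
  out
}

#' Identify the sex factor among profiled factors
#'
#' A factor qualifies as the target-phenotype (sex) factor when it is
#' significantly associated with the target under the factor-level
#' Bonferroni correction and *not* associated with any protected
#' phenotype at `protected_alpha` (uncorrected). Candidates that are
#' sex-significant but cross-associated with a protected phenotype are
#' excluded and reported — correcting on such a factor would damage the
#' protected associations. If several factors qualify, the one with the
#' smallest target P-value is returned with a warning; if none
#' qualifies, an error asks the user to fall back to a different
#' correction strategy.
#'
#' @param profiles a `factor_profiles` table from [profile_factors()].
#' @param target name of the target phenotype (e.g. `"sex"`).
#' @param protected phenotype names that must stay clean; defaults to
#'   every other profiled phenotype.
#' @param protected_alpha uncorrected level for the protection check.
#' @param decomp optional `factor_decomposition`; when given, the report
#'   carries the factor's subject weights (oriented so the group-1 /
#'   female mean is positive) and site Z scores.
#' @param groups optional 0/1 vector of group codes (group 1 = female)
#'   used for the orientation and the weight-sign exception count.
#' @return a `sex_factor_report` list: `factor_index`, `target_p`,
#'   `other_phenotype_min_p`, `excluded` (data.frame of excluded
#'   candidates and the phenotypes that disqualified them),
#'   `subject_weights`, `z_scores`, `n_weight_sign_exceptions`.
#' @export
identify_sex_factor <- function(profiles, target,
                                protected = NULL,
                                protected_alpha = 0.05,
                                decomp = NULL, groups = NULL) {
  stopifnot(inherits(profiles, "factor_profiles"))
  phenos <- unique(profiles$phenotype)
  if (!target %in% phenos) {
    stop_mica("target phenotype '%s' not in profiles", target,
              class = "missing_phenotype")
  }
  protected <- protected %||% setdiff(phenos, target)
  tp <- profiles[profiles$phenotype == target, ]
  candidates <- tp$factor[tp$significant]
  if (length(candidates) == 0L) {
    stop_mica(paste("no factor is significantly associated with '%s' at the",
                    "factor-level Bonferroni threshold; a factorization-based",
                    "correction is not applicable to these data -- use a",
                    "different approach"), target, class = "no_sex_factor")
  }
  prot <- profiles[profiles$phenotype %in% protected &
                     profiles$factor %in% candidates, ]
  bad <- prot[!is.na(prot$p_value) & prot$p_value <= protected_alpha, ]
  excluded <- if (nrow(bad)) {
    data.frame(factor = sort(unique(bad$factor)),
               conflicting_phenotypes = vapply(
                 sort(unique(bad$factor)),
                 function(f) paste(sprintf("%s (p=%.3g)",
                                           bad$phenotype[bad$factor == f],
                                           bad$p_value[bad$factor == f]),
                                   collapse = ", "),
                 ""),
               stringsAsFactors = FALSE)
  } else {
    data.frame(factor = integer(), conflicting_phenotypes = character())
  }
  clean <- setdiff(candidates, excluded$factor)
  if (length(clean) == 0L) {
    stop_mica(paste("every '%s'-associated factor is also associated with a",
                    "protected phenotype (%s) at alpha = %g; removing it",
                    "would damage those associations -- use a different",
                    "approach"),
              target,
              paste(excluded$conflicting_phenotypes, collapse = "; "),
              protected_alpha, class = "no_clean_sex_factor")
  }
  clean_p <- tp$p_value[match(clean, tp$factor)]
  chosen <- clean[which.min(clean_p)]
  if (length(clean) > 1L) {
    warning(sprintf(
      "%d factors qualify as the '%s' factor (indices %s); returning the one with the smallest P-value (%d)",
      length(clean), target, paste(clean, collapse = ", "), chosen))
  }
  if (nrow(excluded)) {
    message(sprintf(
      "excluded %s-significant factor(s) %s: associated with protected phenotype(s) %s",
      target, paste(excluded$factor, collapse = ", "),
      paste(excluded$conflicting_phenotypes, collapse = "; ")))
  }
  prot_chosen <- profiles[profiles$phenotype %in% protected &
                            profiles$factor == chosen, ]
  report <- list(factor_index = as.integer(chosen),
                 target = target,
                 target_p = tp$p_value[tp$factor == chosen],
                 other_phenotype_min_p =
                   if (nrow(prot_chosen)) min(prot_chosen$p_value, na.rm = TRUE)
                   else NA_real_,
                 excluded = excluded,
                 subject_weights = NULL,
                 z_scores = NULL,
                 n_weight_sign_exceptions = NA_integer_)
  if (!is.null(decomp)) {
    w <- decomp$mixing[, chosen]
    z <- site_z_scores(decomp, chosen)
    if (!is.null(groups)) {
      # orient so the female (group 1) mean weight is positive
      if (mean(w[groups == 1]) < 0) {
        w <- -w
        z$z <- -z$z
      }
      maj1 <- sign(stats::median(w[groups == 1]))
      maj0 <- sign(stats::median(w[groups == 0]))
      report$n_weight_sign_exceptions <-
        sum(sign(w[groups == 1]) != maj1) + sum(sign(w[groups == 0]) != maj0)
    }
    report$subject_weights <- w
    report$z_scores <- z
  }
  structure(report, class = "sex_factor_report")
}

#' @export
print.sex_factor_report <- function(x, ...) {
  cat(sprintf("sex factor report: factor %d ('%s' p = %.3g)\n",
              x$factor_index, x$target, x$target_p))
  cat(sprintf("  smallest protected-phenotype p: %.3g\n",
              x$other_phenotype_min_p))
  if (nrow(x$excluded)) {
    cat("  excluded candidates:\n")
    for (i in seq_len(nrow(x$excluded))) {
      cat(sprintf("    factor %d: %s\n", x$excluded$factor[i],
                  x$excluded$conflicting_phenotypes[i]))
    }
  }
  if (!is.na(x$n_weight_sign_exceptions)) {
    cat(sprintf("  subjects whose weight sign contradicts their group: %d\n",
                x$n_weight_sign_exceptions))
  }
  invisible(x)
}

#' Remove one latent factor from the data
#'
#' Subtracts the factor's rank-one contribution,
#' `outer(mixing[, i], sources[i, ])`, from the beta values. Site means
#' are untouched (the decomposition was fitted on the centered matrix,
#' so the correction acts on the centered part only). Corrected values
#' can fall slightly outside `[0, 1]`; they are preserved as-is — the
#' downstream tests are scale-free — and counted, unless `clip = TRUE`.
#'
#' @param data the [beta_matrix()] the decomposition was fitted on.
#' @param decomp a `factor_decomposition`.
#' @param factor_index which factor to remove.
#' @param clip clamp corrected values back into `[0, 1]`?
#' @return a `beta_matrix` with attribute `n_out_of_range` (count of
#'   values pushed outside `[0, 1]` before any clipping).
#' @export
remove_factor <- function(data, decomp, factor_index, clip = FALSE) {
  stopifnot(inherits(data, "beta_matrix"),
            inherits(decomp, "factor_decomposition"))
  if (factor_index < 1L || factor_index > decomp$k) {
    stop_mica("factor_index %d out of range 1..%d", factor_index, decomp$k,
              class = "bad_index")
  }
  if (nrow(decomp$mixing) != nrow(data$values) ||
      ncol(decomp$sources) != ncol(data$values)) {
    stop_mica("decomposition (%d x %d) does not match data (%d x %d)",
              nrow(decomp$mixing), ncol(decomp$sources),
              nrow(data$values), ncol(data$values),
              class = "bad_dimensions")
  }
  corrected <- data$values -
    tcrossprod(decomp$mixing[, factor_index], decomp$sources[factor_index, ])
  n_out <- sum(!is.na(corrected) & (corrected < 0 | corrected > 1))
  if (clip) corrected <- pmin(pmax(corrected, 0), 1)
  out <- beta_matrix(corrected, subject_ids = data$subject_ids,
                     sites = data$sites, range_check = FALSE)
  attr(out, "n_out_of_range") <- n_out
  attr(out, "removed_factor") <- as.integer(factor_index)
  out
}

#' Compare sitewise associations before and after a correction
#'
#' Both inputs are named lists of per-phenotype association tables (as
#' returned by [associate_phenotypes()]) computed on the same site
#' universe with the same phenotypes. For each phenotype the report
#' gives the minimum P-value and significant-site count before and
#' after, and the set arithmetic of the significant sites (common,
#' gained, lost).
#'
#' @param before,after named lists of association result `data.frame`s.
#' @param alpha,correction,n_tests significance rule applied to both
#'   sides (see [summarize_results()]).
#' @return a `ba_comparison` list: `table` (one row per phenotype) and
#'   `sites` (per phenotype: `common`, `gained`, `lost` site ids).
#' @export
compare_before_after <- function(before, after, alpha = 0.05,
                                 correction = c("bonferroni", "none"),
                                 n_tests = NULL) {
  correction <- match.arg(correction)
  if (!setequal(names(before), names(after))) {
    stop_mica("before/after phenotype sets differ", class = "bad_input")
  }
  rows <- list()
  sites <- list()
  for (nm in names(before)) {
    b <- before[[nm]]
    a <- after[[nm]]
    if (!setequal(b$site_id, a$site_id)) {
      stop_mica("site universes differ for phenotype '%s'", nm,
                class = "mismatched_universe")
    }
    sb <- significant_sites(b, alpha, correction, n_tests)
    sa <- significant_sites(a, alpha, correction, n_tests)
    sites[[nm]] <- list(common = intersect(sb, sa),
                        gained = setdiff(sa, sb),
                        lost = setdiff(sb, sa))
    rows[[nm]] <- data.frame(
      phenotype = nm,
      min_p_before = suppressWarnings(min(b$p_value, na.rm = TRUE)),
      min_p_after = suppressWarnings(min(a$p_value, na.rm = TRUE)),
      max_abs_stat_before = suppressWarnings(max(abs(b$statistic), na.rm = TRUE)),
      max_abs_stat_after = suppressWarnings(max(abs(a$statistic), na.rm = TRUE)),
      n_significant_before = length(sb),
      n_significant_after = length(sa),
      n_common = length(sites[[nm]]$common),
      n_gained = length(sites[[nm]]$gained),
      n_lost = length(sites[[nm]]$lost),
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 sites = sites,
                 alpha = alpha, correction = correction),
            class = "ba_comparison")
}

#' @export
print.ba_comparison <- function(x, ...) {
  cat(sprintf("before/after comparison (%s alpha = %g)\n",
              x$correction, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}
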