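# End-to-end workflow: QC -> sitewise association -> PCA/ICA -> factor
# profiling -> sex-factor identification -> rank-one removal ->
# re-association -> before/after comparison. Every artifact is plain
# text; the run manifest records the configuration fingerprint and seed.

#' Run the full confound-correction workflow
#'
#' Stages: (1) site QC; (2) sitewise association of every phenotype with
#' methylation (Bonferroni across retained sites); (3) PCA of the
#' centered complete-site matrix and selection of the smallest K
#' retaining `variance_target` of the variance; (4) infomax ICA with
#' that K; (5) factor-phenotype profiling and identification of the
#' target-phenotype (sex) factor; (6) removal of that factor; (7)
#' re-association on the same site universe; (8) before/after
#' comparison. Each stage logs its counts and timing via `message()`.
#'
#' @param data a [beta_matrix()].
#' @param phenotypes a `phenotype_table` covering the matrix's subjects.
#' @param qc_mode,mean_threshold,variance_threshold,detection_p,detection_threshold
#'   QC settings, see [qc_filter_sites()].
#' @param variant sitewise t-test variant.
#' @param alpha family-wise significance level (sitewise and
#'   factor-level).
#' @param variance_target PCA variance-retention target in (0, 1].
#' @param k optional override of the component count.
#' @param seed integer seed for the ICA initialization (required).
#' @param target_phenotype phenotype defining the confound factor;
#'   defaults to the table's grouping phenotype.
#' @param protected phenotypes that must stay clean (default: all
#'   others).
#' @param protected_alpha uncorrected level for the protection check.
#' @param learning_rate,max_iter,tol infomax settings, see
#'   [infomax_ica()].
#' @param out_dir optional directory; when given, all artifacts are
#'   written there as TSV/key-value text files plus a JSON manifest.
#' @param verbose log stage progress?
#' @return a `pipeline_result` list: `qc_report`, `before` (association
#'   tables), `summaries_before`, `pca`, `k`, `ica`, `profiles`,
#'   `sex_factor`, `corrected`, `after`, `summaries_after`,
#'   `comparison`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(data, phenotypes,
                         qc_mode = c("relative", "absolute"),
                         mean_threshold = 0.05,
                         variance_threshold = 0.01,
                         detection_p = NULL,
                         detection_threshold = 0.5,
                         variant = c("pooled", "welch"),
                         alpha = 0.05,
                         variance_target = 0.99,
                         k = NULL,
                         seed,
                         target_phenotype = NULL,
                         protected = NULL,
                         protected_alpha = 0.05,
                         learning_rate = 0.05,
                         max_iter = 2000L,
                         tol = 1e-6,
                         out_dir = NULL,
                         verbose = TRUE) {
  qc_mode <- match.arg(qc_mode)
  variant <- match.arg(variant)
  if (missing(seed) || is.null(seed)) {
    stop_mica("a seed is required for a reproducible factorization",
              class = "bad_config")
  }
  stopifnot(inherits(data, "beta_matrix"),
            inherits(phenotypes, "phenotype_table"))
  gname <- attr(phenotypes, "group_name")
  target_phenotype <- target_phenotype %||% gname
  all_phenos <- c(gname, continuous_phenotypes(phenotypes))
  if (!target_phenotype %in% all_phenos) {
    stop_mica("unknown target phenotype '%s' (available: %s)",
              target_phenotype, paste(all_phenos, collapse = ", "),
              class = "missing_phenotype")
  }
  if (target_phenotype != gname) {
    stop_mica("the target phenotype must currently be the binary grouping phenotype ('%s')",
              gname, class = "bad_config")
  }
  protected <- protected %||% setdiff(all_phenos, target_phenotype)
  unknown <- setdiff(protected, all_phenos)
  if (length(unknown)) {
    stop_mica("unknown protected phenotype(s): %s",
              paste(unknown, collapse = ", "), class = "missing_phenotype")
  }
  phenotypes <- align_phenotypes(data, phenotypes)

  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                 sprintf(fmt, ...)))
  }
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop_mica("stage '%s' failed: %s", name, conditionMessage(e),
                class = "stage_error")
    })
    log_stage("%s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  qc <- timed("qc", qc_filter_sites(data, mode = qc_mode,
                                    mean_threshold = mean_threshold,
                                    variance_threshold = variance_threshold,
                                    detection_p = detection_p,
                                    detection_threshold = detection_threshold))
  log_stage("qc retained %d of %d sites", qc$report$n_retained,
            qc$report$n_input_sites)
  filtered <- qc$data

  before <- timed("associate_before",
                  associate_phenotypes(filtered, phenotypes, variant = variant))
  summaries_before <- lapply(before, summarize_results, alpha = alpha,
                             correction = "bonferroni")

  complete <- drop_incomplete_sites(filtered)
  cen <- center_matrix(complete)
  pca <- timed("pca", pca_decompose(cen))
  k_use <- k %||% select_components_by_variance(pca, variance_target)
  log_stage("retaining %d components (target %.2f of variance)",
            k_use, variance_target)
  ica <- timed("ica", infomax_ica(cen, k = k_use, seed = seed,
                                  learning_rate = learning_rate,
                                  max_iter = max_iter, tol = tol))

  profiles <- timed("profile_factors",
                    profile_factors(ica, phenotypes, alpha = alpha))
  sex_factor <- timed("identify_factor",
                      identify_sex_factor(profiles, target = target_phenotype,
                                          protected = protected,
                                          protected_alpha = protected_alpha,
                                          decomp = ica,
                                          groups = phenotypes[[gname]]))
  log_stage("identified factor %d (p = %.3g)", sex_factor$factor_index,
            sex_factor$target_p)

  corrected_complete <- timed("correct",
                              remove_factor(complete, ica,
                                            sex_factor$factor_index))
  # fold the corrected values back into the full QC-retained matrix so the
  # re-test runs on the identical site universe
  corrected_values <- filtered$values
  corrected_values[, colnames(corrected_complete$values)] <-
    corrected_complete$values
  corrected <- beta_matrix(corrected_values, subject_ids = filtered$subject_ids,
                           sites = filtered$sites, range_check = FALSE)
  attr(corrected, "n_out_of_range") <- attr(corrected_complete, "n_out_of_range")

  after <- timed("associate_after",
                 associate_phenotypes(corrected, phenotypes, variant = variant))
  summaries_after <- lapply(after, summarize_results, alpha = alpha,
                            correction = "bonferroni")
  comparison <- timed("compare",
                      compare_before_after(before, after, alpha = alpha,
                                           correction = "bonferroni"))

  cfg <- list(qc_mode = qc_mode, mean_threshold = mean_threshold,
              variance_threshold = variance_threshold,
              detection_threshold = detection_threshold,
              variant = variant, alpha = alpha,
              variance_target = variance_target, k = k_use, seed = seed,
              target_phenotype = target_phenotype,
              protected = protected, protected_alpha = protected_alpha,
              learning_rate = learning_rate, max_iter = max_iter, tol = tol)
  config_hash <- fnv1a_hash(paste(deparse(cfg), collapse = ""))

  result <- structure(list(qc_report = qc$report,
                           before = before,
                           summaries_before = summaries_before,
                           pca = pca,
                           k = k_use,
                           ica = ica,
                           profiles = profiles,
                           sex_factor = sex_factor,
                           corrected = corrected,
                           after = after,
                           summaries_after = summaries_after,
                           comparison = comparison,
                           seed = seed,
                           config = cfg,
                           config_hash = config_hash),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    timed("write_artifacts", write_pipeline_artifacts(result, out_dir))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (seed %d, config %s)\n", x$seed, x$config_hash))
  print(x$qc_report)
  cat(sprintf("factorization: k = %d, ICA converged = %s\n",
              x$k, x$ica$converged))
  cat(sprintf("sex factor: index %d, p = %.3g\n",
              x$sex_factor$factor_index, x$sex_factor$target_p))
  print(x$comparison)
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_qc_report(result$qc_report, file.path(dir, "qc_report.tsv"))
  for (nm in names(result$before)) {
    write_association_results(result$before[[nm]],
                              file.path(dir, sprintf("assoc_before_%s.tsv", nm)),
                              alpha = result$config$alpha)
    write_association_results(result$after[[nm]],
                              file.path(dir, sprintf("assoc_after_%s.tsv", nm)),
                              alpha = result$config$alpha)
  }
  write_decomposition(result$ica, file.path(dir, "ica"))
  prof <- as.data.frame(result$profiles)
  data.table::fwrite(prof, file.path(dir, "factor_profiles.tsv"),
                     sep = "\t", quote = FALSE)
  sf <- result$sex_factor
  if (!is.null(sf$subject_weights)) {
    data.table::fwrite(
      data.frame(subject_id = names(sf$subject_weights),
                 weight = sprintf("%.17g", sf$subject_weights)),
      file.path(dir, "sex_factor_weights.tsv"), sep = "\t", quote = FALSE)
  }
  if (!is.null(sf$z_scores)) {
    data.table::fwrite(
      data.frame(site_id = names(sf$z_scores$z),
                 z = sprintf("%.17g", sf$z_scores$z)),
      file.path(dir, "sex_factor_z_scores.tsv"), sep = "\t", quote = FALSE)
  }
  write_beta_table(result$corrected, file.path(dir, "corrected_beta.tsv"),
                   orientation = "sites_in_rows")
  data.table::fwrite(result$comparison$table,
                     file.path(dir, "comparison.tsv"), sep = "\t",
                     quote = FALSE)
  manifest <- list(package = "methylICA",
                   version = as.character(utils::packageVersion("methylICA")),
                   seed = result$seed,
                   config = result$config,
                   config_hash = result$config_hash,
                   sex_factor_index = result$sex_factor$factor_index,
                   k = result$k,
                   n_retained_sites = result$qc_report$n_retained)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
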