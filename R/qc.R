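# Site-level quality control: drop sites whose mean methylation or
# variance is too low to be informative, and sites whose detection
# P-values indicate failed measurement.

#' Filter uninformative methylation sites
#'
#' A site is removed when its mean beta value falls below the mean
#' cutoff, OR its variance falls below the variance cutoff, OR (when a
#' detection table is supplied) its mean detection P-value exceeds
#' `detection_threshold`. Two threshold modes are provided:
#'
#' * `"relative"`: `mean_threshold` is a fraction of the maximum
#'   attainable beta value (1.0), so the default 0.05 removes sites
#'   averaging below 5% methylation; `variance_threshold` is a fraction
#'   of the maximum observed per-site variance in the data set (default
#'   0.01, i.e. 1% of the most variable site).
#' * `"absolute"`: both thresholds are raw cutoffs on the mean and
#'   variance (e.g. 0.01 and 0.0001 for GoldenGate-style panels).
#'
#' @param data a [beta_matrix()].
#' @param mode `"relative"` or `"absolute"` (see above).
#' @param mean_threshold mean cutoff (fraction or raw value per `mode`).
#' @param variance_threshold variance cutoff (fraction or raw value).
#' @param detection_p optional named numeric vector of per-site mean
#'   detection P-values (names are site ids; every name must exist in
#'   `data`). Sites absent from the vector are not tested on this rule.
#' @param detection_threshold sites with mean detection P above this are
#'   removed (default 0.5: signal below negative controls half the time).
#' @return a list with elements `data` (the filtered `beta_matrix`,
#'   site order preserved) and `report` (a `qc_report`).
#' @export
qc_filter_sites <- function(data,
                            mode = c("relative", "absolute"),
                            mean_threshold = 0.05,
                            variance_threshold = 0.01,
                            detection_p = NULL,
                            detection_threshold = 0.5) {
  stopifnot(inherits(data, "beta_matrix"))
  mode <- match.arg(mode)
  if (mean_threshold < 0 || variance_threshold < 0) {
    stop_mica("QC thresholds must be non-negative", class = "bad_threshold")
  }
  x <- data$values
  site_mean <- colMeans(x, na.rm = TRUE)
  site_var <- col_vars(x)

  if (mode == "relative") {
    mean_cut <- mean_threshold * 1.0
    var_cut <- variance_threshold * max(site_var, na.rm = TRUE)
  } else {
    mean_cut <- mean_threshold
    var_cut <- variance_threshold
  }

  fail_det <- rep(FALSE, ncol(x))
  if (!is.null(detection_p)) {
    if (is.null(names(detection_p))) {
      stop_mica("detection_p must be a named vector keyed by site_id",
                class = "parse_error")
    }
    unknown <- setdiff(names(detection_p), data$sites$site_id)
    if (length(unknown)) {
      stop_mica("detection table contains unknown site ids: %s",
                paste(head(unknown, 5L), collapse = ", "),
                class = "unknown_sites")
    }
    idx <- match(names(detection_p), data$sites$site_id)
    fail_det[idx] <- !is.na(detection_p) & detection_p > detection_threshold
  }
  fail_mean <- site_mean < mean_cut
  fail_var <- !is.na(site_var) & site_var < var_cut

  # Attribute each removed site to a single rule (detection first, then
  # mean, then variance) so the report counts sum without double counting.
  removed_det <- fail_det
  removed_mean <- fail_mean & !removed_det
  removed_var <- fail_var & !removed_det & !removed_mean
  keep <- !(removed_det | removed_mean | removed_var)

  if (!any(keep)) {
    stop_mica("QC removed all %d sites; thresholds too aggressive?",
              ncol(x), class = "empty_result")
  }

  report <- structure(list(
    n_input_sites = ncol(x),
    n_removed_low_mean = sum(removed_mean),
    n_removed_low_variance = sum(removed_var),
    n_removed_detection = sum(removed_det),
    n_retained = sum(keep),
    thresholds_used = list(mode = mode,
                           mean_threshold = mean_threshold,
                           variance_threshold = variance_threshold,
                           mean_cutoff = mean_cut,
                           variance_cutoff = var_cut,
                           detection_threshold = if (is.null(detection_p))
                             NA_real_ else detection_threshold)
  ), class = "qc_report")

  list(data = subset_sites(data, which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  th <- x$thresholds_used
  cat("Site-level QC report\n")
  cat(sprintf("  mode: %s (mean cutoff %.6g, variance cutoff %.6g)\n",
              th$mode, th$mean_cutoff, th$variance_cutoff))
  cat(sprintf("  input sites:            %d\n", x$n_input_sites))
  cat(sprintf("  removed, detection P:   %d\n", x$n_removed_detection))
  cat(sprintf("  removed, low mean:      %d\n", x$n_removed_low_mean))
  cat(sprintf("  removed, low variance:  %d\n", x$n_removed_low_variance))
  cat(sprintf("  retained:               %d\n", x$n_retained))
  invisible(x)
}

#' Write a QC report as a machine-readable key-value file
#'
#' @param x a `qc_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(x, path) {
  stopifnot(inherits(x, "qc_report"))
  th <- x$thresholds_used
  kv <- c(n_input_sites = x$n_input_sites,
          n_removed_detection = x$n_removed_detection,
          n_removed_low_mean = x$n_removed_low_mean,
          n_removed_low_variance = x$n_removed_low_variance,
          n_retained = x$n_retained,
          mode = th$mode,
          mean_threshold = th$mean_threshold,
          variance_threshold = th$variance_threshold,
          mean_cutoff = th$mean_cutoff,
          variance_cutoff = th$variance_cutoff,
          detection_threshold = th$detection_threshold)
  writeLines(paste(names(kv), unname(kv), sep = "\t"), path)
  invisible(path)
}

#' Drop sites with any missing value
#'
#' Factorization requires a complete matrix; sites carrying missing beta
#' values are removed ahead of it (sitewise tests, by contrast, use
#' pairwise-complete subjects and keep such sites).
#'
#' @param data a [beta_matrix()].
#' @return a `beta_matrix` with only complete sites.
#' @export
drop_incomplete_sites <- function(data) {
  stopifnot(inherits(data, "beta_matrix"))
  keep <- colSums(is.na(data$values)) == 0L
  if (!any(keep)) {
    stop_mica("no complete sites remain", class = "empty_result")
  }
  if (all(keep)) return(data)
  subset_sites(data, which(keep))
}
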