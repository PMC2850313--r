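# Project out the in-sample linear association of y with the columns of
# covars, keeping y's mean and (approximately) its spread.
decorrelate <- function(y, covars) {
  r <- stats::lm.fit(cbind(1, covars), y)$residuals
  mean(y) + r * (sd(y) / sd(r))
}

# Seeded simulator for methylation cohorts with known planted factor
# structure: a sex factor loading strongly on a block of X-chromosome
# sites and weakly/bidirectionally on scattered autosomal sites, an
# independent age factor on disjoint sites, bounded measurement noise,
# and nuisance phenotypes uncorrelated with everything.

#' Simulation configuration with cohort-scale defaults
#'
#' Defaults emulate a saliva-methylation study cohort: 200 subjects with
#' a female fraction of 54/197, 2,000 CpG sites of which 100 are
#' X-linked, a sex factor loading on 40 X-linked and 20 autosomal sites
#' with mean effect 0.15 beta units (55% of loaded sites hypermethylated
#' in females, the rest in males), an age factor on 40 disjoint sites
#' with slope 0.004 beta units per year over ages 21-55, and i.i.d.
#' Gaussian measurement noise with SD 0.05 beta units (the replicate
#' reproducibility scale of beadarray methylation assays). Baseline
#' site levels are drawn from a bimodal promoter-like mixture,
#' `0.6 * Beta(2, 8) + 0.4 * Beta(8, 2)`; sites carrying planted effects
#' draw their baseline from the mid-methylation range (0.25-0.70) so
#' the planted offsets stay inside `[0, 1]`.
#'
#' @param n_subjects number of subjects.
#' @param n_sites number of CpG sites.
#' @param fraction_female fraction of female subjects.
#' @param x_chrom_sites number of sites annotated chromosome "X".
#' @param sex_factor list: `n_loaded_x`, `n_loaded_autosomal`,
#'   `effect_size_mean` (beta units), `fraction_female_hyper`.
#' @param age_factor list: `n_loaded`, `slope` (beta units per year),
#'   `age_range` (years).
#' @param noise_sd measurement noise SD in beta units.
#' @param baseline list: mixture weight `p_low` and the two Beta-law
#'   shape pairs `low`, `high`.
#' @param seed integer seed; every draw is reproducible from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 200L,
                              n_sites = 2000L,
                              fraction_female = 54 / 197,
                              x_chrom_sites = 100L,
                              sex_factor = list(),
                              age_factor = list(),
                              noise_sd = 0.05,
                              baseline = list(),
                              seed = 1L) {
  sex_factor <- modifyList(list(n_loaded_x = 40L, n_loaded_autosomal = 20L,
                                effect_size_mean = 0.15,
                                fraction_female_hyper = 0.55),
                           sex_factor)
  age_factor <- modifyList(list(n_loaded = 40L, slope = 0.004,
                                age_range = c(21, 55)),
                           age_factor)
  baseline <- modifyList(list(p_low = 0.6, low = c(2, 8), high = c(8, 2)),
                         baseline)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_sites = as.integer(n_sites),
              fraction_female = fraction_female,
              x_chrom_sites = as.integer(x_chrom_sites),
              sex_factor = sex_factor,
              age_factor = age_factor,
              noise_sd = noise_sd,
              baseline = baseline,
              seed = as.integer(seed))
  n_loaded <- sex_factor$n_loaded_x + sex_factor$n_loaded_autosomal +
    age_factor$n_loaded
  if (sex_factor$n_loaded_x > cfg$x_chrom_sites ||
      n_loaded > cfg$n_sites) {
    stop_mica("loaded site counts exceed available sites",
              class = "bad_config")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a methylation cohort with planted sex and age factors
#'
#' The value of subject j at site i is
#' `baseline_i + female_j * sex_effect_i + age_slope_i * (age_j - mean age)
#'  + noise`, truncated to `[0, 1]`. Sex effects are signed offsets: a
#' `fraction_female_hyper` share of the loaded sites is hypermethylated
#' in females (positive effect), the remainder in males. Sex- and
#' age-loaded site sets are disjoint. Nuisance continuous phenotypes
#' (an AUDIT-like score and a cigarettes-per-day count) are drawn
#' independently of everything. An error is raised if the configuration
#' forces systematic truncation (more than 5% of values clipped).
#'
#' @param config a [simulation_config()].
#' @return list with `data` (a [beta_matrix()] with X/autosome site
#'   annotation), `phenotypes` (a `phenotype_table` with sex coded
#'   F = 1 / M = 0 plus `age`, `audit`, `cigarettes`) and `truth` (a
#'   `ground_truth` list: `sex_sites` and `age_sites` data.frames with
#'   signed effects, subject `sex` codes, `ages`, and the
#'   `clipped_fraction`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    m <- config$n_sites
    sf <- config$sex_factor
    af <- config$age_factor

    n_female <- round(config$fraction_female * n)
    sex <- sample(rep(c(1L, 0L), c(n_female, n - n_female)))
    ages <- runif(n, af$age_range[1], af$age_range[2])
    # the age factor is independent of sex by construction: remove the
    # (sampling-accident) in-sample correlation between age and sex so
    # cross-associations in downstream tests reflect the method, not a
    # finite-cohort accident
    if (n > 3) ages <- decorrelate(ages, cbind(sex))
    subject_ids <- sprintf("subj%03d", seq_len(n))

    site_ids <- sprintf("cg%05d", seq_len(m))
    genes <- sprintf("GENE%04d", seq_len(m))
    chrom <- sample(as.character(1:22), m, replace = TRUE)
    x_idx <- sample.int(m, config$x_chrom_sites)
    chrom[x_idx] <- "X"

    sex_idx <- c(sample(x_idx, sf$n_loaded_x),
                 sample(setdiff(seq_len(m), x_idx), sf$n_loaded_autosomal))
    age_idx <- sample(setdiff(seq_len(m), sex_idx), af$n_loaded)

    # baseline: bimodal promoter-like mixture; planted sites mid-range
    low <- runif(m) < config$baseline$p_low
    mu <- ifelse(low,
                 rbeta(m, config$baseline$low[1], config$baseline$low[2]),
                 rbeta(m, config$baseline$high[1], config$baseline$high[2]))
    mu[c(sex_idx, age_idx)] <- runif(length(sex_idx) + length(age_idx),
                                     0.25, 0.70)

    n_sex <- length(sex_idx)
    magnitude <- pmax(rnorm(n_sex, sf$effect_size_mean,
                            0.2 * sf$effect_size_mean),
                      0.3 * sf$effect_size_mean)
    hyper_f <- runif(n_sex) < sf$fraction_female_hyper
    sex_effect <- ifelse(hyper_f, magnitude, -magnitude)

    slopes <- af$slope * sign(runif(af$n_loaded) - 0.5)
    slopes[slopes == 0] <- af$slope

    values <- matrix(rep(mu, each = n), nrow = n) +
      matrix(rnorm(n * m, 0, config$noise_sd), nrow = n)
    if (n_sex > 0) {
      values[, sex_idx] <- values[, sex_idx] + outer(sex, sex_effect)
    }
    if (af$n_loaded > 0) {
      values[, age_idx] <- values[, age_idx] +
        outer(ages - mean(ages), slopes)
    }
    clipped <- mean(values < 0 | values > 1)
    if (clipped > 0.05) {
      stop_mica(paste("configuration clips %.1f%% of values to [0,1];",
                      "reduce effect sizes or noise"), 100 * clipped,
                class = "excessive_truncation")
    }
    values <- pmin(pmax(values, 0), 1)

    sites <- site_annotation(site_ids, genes, chrom)
    data <- beta_matrix(values, subject_ids = subject_ids, sites = sites)
    audit <- runif(n, 6, 38)
    cigarettes <- rpois(n, 10)
    if (n > 4) {
      # nuisance phenotypes are uncorrelated with the planted factors:
      # enforce that in-sample against both sex and age
      audit <- decorrelate(audit, cbind(sex, ages))
      cigarettes <- decorrelate(cigarettes, cbind(sex, ages))
    }
    phenotypes <- phenotype_table(
      subject_ids,
      group = ifelse(sex == 1L, "F", "M"),
      group_name = "sex",
      continuous = data.frame(age = ages,
                              audit = round(audit),
                              cigarettes = round(pmax(cigarettes, 0))))
    truth <- structure(list(
      sex_sites = data.frame(site_id = site_ids[sex_idx],
                             effect = sex_effect,
                             chromosome = chrom[sex_idx],
                             stringsAsFactors = FALSE),
      age_sites = data.frame(site_id = site_ids[age_idx],
                             slope = slopes,
                             stringsAsFactors = FALSE),
      sex = stats::setNames(sex, subject_ids),
      ages = stats::setNames(ages, subject_ids),
      clipped_fraction = clipped), class = "ground_truth")
    list(data = data, phenotypes = phenotypes, truth = truth)
  })
}

#' Score how well a decomposition recovered the planted factors
#'
#' Each planted signal (sex: the 0/1 female indicator and the signed
#' site effects; age: the centered ages and the site slopes) is matched
#' to the factor whose subject weights have the largest absolute
#' correlation with the true subject-level signal; the site-loading
#' correlation of that factor against the true effect vector is
#' reported alongside. Correlations are sign-agnostic.
#'
#' @param decomp a `factor_decomposition` fitted on the simulated data.
#' @param truth the `ground_truth` from [simulate_cohort()].
#' @return a `data.frame` with one row per planted factor: `signal`,
#'   `best_factor_index`, `weight_truth_correlation`,
#'   `loading_truth_correlation`.
#' @export
planted_factor_recovery_score <- function(decomp, truth) {
  stopifnot(inherits(decomp, "factor_decomposition"),
            inherits(truth, "ground_truth"))
  site_ids <- colnames(decomp$sources)
  signals <- list()
  if (nrow(truth$sex_sites)) {
    eff <- stats::setNames(rep(0, length(site_ids)), site_ids)
    eff[truth$sex_sites$site_id] <- truth$sex_sites$effect
    signals$sex <- list(subject = as.numeric(truth$sex), site = eff)
  }
  if (nrow(truth$age_sites)) {
    eff <- stats::setNames(rep(0, length(site_ids)), site_ids)
    eff[truth$age_sites$site_id] <- truth$age_sites$slope
    signals$age <- list(subject = truth$ages - mean(truth$ages), site = eff)
  }
  if (!length(signals)) {
    stop_mica("ground truth contains no planted factors", class = "bad_input")
  }
  rows <- lapply(names(signals), function(nm) {
    sg <- signals[[nm]]
    wcor <- abs(suppressWarnings(cor(decomp$mixing, sg$subject)))
    best <- which.max(wcor)
    lcor <- abs(suppressWarnings(cor(decomp$sources[best, ], sg$site)))
    data.frame(signal = nm,
               best_factor_index = best,
               weight_truth_correlation = wcor[best],
               loading_truth_correlation = lcor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits the same formats the readers accept: `beta.tsv` (sites in
#' rows), `annotation.tsv`, `phenotypes.tsv`, plus `truth_sex_sites.tsv`
#' / `truth_age_sites.tsv` and the configuration as a key-value file.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param config the [simulation_config()] used (written alongside).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_table(cohort$data, file.path(dir, "beta.tsv"),
                   orientation = "sites_in_rows")
  data.table::fwrite(cohort$data$sites, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, na = "NA")
  write_phenotype_table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  data.table::fwrite(cohort$truth$sex_sites,
                     file.path(dir, "truth_sex_sites.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$truth$age_sites,
                     file.path(dir, "truth_age_sites.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(config)) {
    flat <- unlist(config)
    writeLines(paste(names(flat), unname(flat), sep = "\t"),
               file.path(dir, "config.tsv"))
  }
  invisible(dir)
}
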