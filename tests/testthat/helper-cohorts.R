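# Shared fixtures, all generated in code.

# A small, fast cohort with well-separated planted factors.
small_config <- function(seed = 1L, ...) {
  defaults <- list(n_subjects = 40L, n_sites = 400L,
                   x_chrom_sites = 40L,
                   sex_factor = list(n_loaded_x = 15L,
                                     n_loaded_autosomal = 10L,
                                     effect_size_mean = 0.2),
                   age_factor = list(n_loaded = 12L, slope = 0.005),
                   noise_sd = 0.04,
                   seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

small_cohort <- function(seed = 1L, ...) {
  simulate_cohort(small_config(seed = seed, ...))
}

# A toy beta matrix from explicit values (subjects x sites).
toy_bm <- function(values, chromosome = "unknown", gene = "") {
  values <- as.matrix(values)
  colnames(values) <- sprintf("cg%05d", seq_len(ncol(values)))
  rownames(values) <- sprintf("subj%03d", seq_len(nrow(values)))
  beta_matrix(values,
              sites = site_annotation(colnames(values), gene = gene,
                                      chromosome = chromosome))
}

# Low-noise data built from a known number of planted rank-one factors;
# used for rank/recovery checks.
planted_rank_data <- function(n = 60L, m = 200L, k = 3L, noise = 1e-3,
                              seed = 42L) {
  set.seed(seed)
  mix <- matrix(rnorm(n * k), n, k)
  # sparse, super-Gaussian site patterns with disjoint supports
  src <- matrix(0, k, m)
  for (i in seq_len(k)) {
    idx <- ((i - 1L) * floor(m / k)) + seq_len(floor(m / 4 / k))
    src[i, idx] <- rnorm(length(idx), mean = 2)
  }
  x <- mix %*% src + matrix(rnorm(n * m, 0, noise), n, m)
  rownames(x) <- sprintf("subj%03d", seq_len(n))
  colnames(x) <- sprintf("cg%05d", seq_len(m))
  list(x = x, mixing = mix, sources = src)
}

# Match two factor sets by maximal |correlation| of subject weights;
# returns the vector of matched correlations.
matched_weight_cors <- function(a, b) {
  cc <- abs(cor(a, b))
  sapply(seq_len(ncol(a)), function(i) max(cc[i, ]))
}
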