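# Latent factor model of the methylation matrix. The centered subjects x
# sites matrix X is factored as X = A %*% S: A ("mixing") holds the
# per-subject expression weight of each factor, S ("sources") the
# per-site pattern of each factor. PCA orders factors by explained
# variance; infomax ICA rotates a PCA-whitened basis so the site
# patterns are maximally statistically independent. Source rows are
# scaled to unit (population) variance; the scale lives in the mixing
# columns.

#' Center a beta matrix by site
#'
#' Removes each site's mean across subjects; the means are retained so
#' the data can be reconstructed and so factor removal can act on the
#' centered part only.
#'
#' @param data a [beta_matrix()] or plain numeric matrix (subjects x
#'   sites) without missing values.
#' @return list with `centered` (matrix) and `site_means` (named vector).
#' @export
center_matrix <- function(data) {
  x <- if (inherits(data, "beta_matrix")) data$values else as.matrix(data)
  if (anyNA(x)) {
    stop_mica("matrix contains missing values; run drop_incomplete_sites() first",
              class = "missing_values")
  }
  mu <- colMeans(x)
  list(centered = sweep(x, 2L, mu, `-`), site_means = mu)
}

new_factor_decomposition <- function(method, mixing, sources, site_means,
                                     variance_retained, explained = NULL,
                                     seed = NULL, converged = TRUE,
                                     iterations = 0L) {
  colnames(mixing) <- rownames(sources) <-
    sprintf("factor%02d", seq_len(ncol(mixing)))
  structure(list(method = method,
                 mixing = mixing,
                 sources = sources,
                 site_means = site_means,
                 variance_retained = variance_retained,
                 k = ncol(mixing),
                 explained = explained,
                 seed = seed,
                 converged = converged,
                 iterations = iterations),
            class = "factor_decomposition")
}

#' @export
print.factor_decomposition <- function(x, ...) {
  cat(sprintf("factor_decomposition (%s): %d subjects x %d sites, k = %d\n",
              x$method, nrow(x$mixing), ncol(x$sources), x$k))
  cat(sprintf("  variance retained: %.4f; converged: %s (%d iterations)\n",
              x$variance_retained, x$converged, x$iterations))
  invisible(x)
}

# Economy SVD of the centered matrix with near-zero singular values
# dropped (column centering alone costs one rank).
centered_svd <- function(centered) {
  sv <- svd(centered)
  keep <- sv$d > max(sv$d) * 1e-12
  if (!any(keep)) {
    stop_mica("degenerate input: matrix has no variance", class = "degenerate")
  }
  list(u = sv$u[, keep, drop = FALSE],
       d = sv$d[keep],
       v = sv$v[, keep, drop = FALSE])
}

# Orient each factor so its maximum-|loading| site has a positive
# loading; flips the matching mixing column to keep A %*% S unchanged.
orient_factors <- function(mixing, sources) {
  for (i in seq_len(nrow(sources))) {
    s <- sources[i, ]
    if (s[which.max(abs(s))] < 0) {
      sources[i, ] <- -s
      mixing[, i] <- -mixing[, i]
    }
  }
  list(mixing = mixing, sources = sources)
}

#' Principal component analysis of a centered methylation matrix
#'
#' Factors are ordered by decreasing explained variance and each source
#' row (site pattern) is scaled to unit population variance, with the
#' compensating scale absorbed into the mixing column, so
#' `mixing %*% sources` reconstructs the centered input exactly at full
#' rank. Deterministic up to the usual sign convention (the
#' maximum-|loading| site of each factor is oriented positive).
#'
#' @param centered output of [center_matrix()], or a centered matrix.
#' @return a `factor_decomposition` with `method = "pca"` and per-factor
#'   explained-variance fractions in `$explained`.
#' @export
pca_decompose <- function(centered) {
  site_means <- NULL
  if (is.list(centered) && !is.null(centered$centered)) {
    site_means <- centered$site_means
    centered <- centered$centered
  }
  site_means <- site_means %||% rep(0, ncol(centered))
  sv <- centered_svd(centered)
  explained <- sv$d^2 / sum(sv$d^2)
  m <- ncol(centered)
  # scale each v_i to unit population variance across sites
  sds <- apply(sv$v, 2L, function(v) sd_pop(sqrt(m) * v))
  sources <- t(sqrt(m) * sv$v) / sds            # k x m
  mixing <- sv$u %*% diag(sv$d * sds / sqrt(m), nrow = length(sv$d))
  rownames(mixing) <- rownames(centered)
  colnames(sources) <- colnames(centered)
  o <- orient_factors(mixing, sources)
  new_factor_decomposition("pca", o$mixing, o$sources, site_means,
                           variance_retained = 1, explained = explained)
}

#' Smallest component count retaining a target variance fraction
#'
#' @param decomp a PCA `factor_decomposition` (needs `$explained`).
#' @param target variance fraction to retain, in (0, 1].
#' @return integer K: the smallest K with cumulative explained variance
#'   at least `target`.
#' @export
select_components_by_variance <- function(decomp, target = 0.99) {
  stopifnot(inherits(decomp, "factor_decomposition"))
  if (is.null(decomp$explained)) {
    stop_mica("decomposition carries no explained-variance spectrum",
              class = "bad_input")
  }
  if (target <= 0 || target > 1) {
    stop_mica("target must be in (0, 1]", class = "bad_threshold")
  }
  cum <- cumsum(decomp$explained)
  which(cum >= target - 1e-12)[1L]
}

#' Infomax independent component analysis
#'
#' Infomax ICA on a PCA-whitened basis: the centered matrix is reduced
#' to its top `k` principal directions, the site patterns are whitened
#' to unit variance, and an unmixing matrix `W` is fitted by
#' natural-gradient ascent of the information-maximization objective.
#' By default the extended infomax update is used,
#' `W <- W + lr * (I - K tanh(U) U'/m - U U'/m) %*% W` with `U = W Z`
#' and `K` the diagonal of per-component kurtosis signs, which
#' separates super- and sub-Gaussian sources alike (this is the variant
#' implemented by the standard EEG/neuroimaging infomax codes). With
#' `extended = FALSE` the original Bell-Sejnowski logistic update
#' `W <- W + lr * (I + (1 - 2 g(U)) U'/m) %*% W` is used instead; it is
#' only stable for super-Gaussian (sparse, heavy-tailed) sources.
#' Iteration stops when the largest absolute weight update falls below
#' `tol` or at `max_iter`; the learning rate is halved whenever an
#' update diverges. Given a seed the result is fully reproducible.
#'
#' Factors are returned in decreasing order of the variance they carry,
#' with unit-variance source rows and the sign convention of
#' [pca_decompose()].
#'
#' @param centered output of [center_matrix()], or a centered matrix.
#' @param k number of components (at most the numerical rank, i.e.
#'   `min(subjects - 1, sites)` for a centered matrix); typically chosen
#'   with [select_components_by_variance()].
#' @param seed integer seed for the random orthonormal initialization of
#'   `W`.
#' @param learning_rate initial natural-gradient step size.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the maximum absolute weight
#'   change.
#' @param extended use the kurtosis-sign-switching extended update
#'   (default) or the plain logistic one.
#' @return a `factor_decomposition` with `method = "ica"`, honest
#'   `converged` flag and iteration count.
#' @export
infomax_ica <- function(centered, k, seed = 1L, learning_rate = 0.05,
                        max_iter = 2000L, tol = 1e-6, extended = TRUE) {
  site_means <- NULL
  if (is.list(centered) && !is.null(centered$centered)) {
    site_means <- centered$site_means
    centered <- centered$centered
  }
  site_means <- site_means %||% rep(0, ncol(centered))
  sv <- centered_svd(centered)
  rank <- length(sv$d)
  # for column-centered data rank <= subjects - 1, so this enforces the
  # usual k <= min(subjects - 1, sites) bound
  if (k > rank) {
    stop_mica("k = %d exceeds the numerical rank %d of the input", k, rank,
              class = "bad_k")
  }
  m <- ncol(centered)
  d_k <- sv$d[seq_len(k)]
  # whitened site patterns: k x m, rows ~ unit variance
  z0 <- sqrt(m) * t(sv$v[, seq_len(k), drop = FALSE])

  w <- with_seed(seed, {
    qr.Q(qr(matrix(rnorm(k * k), k, k)))
  })
  eye <- diag(k)
  lr <- learning_rate
  iter <- 0L
  converged <- FALSE
  grad_old <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    u <- w %*% z0
    if (extended) {
      u2 <- rowMeans(u^2)
      ksign <- sign(rowMeans(u^4) / pmax(u2^2, .Machine$double.eps) - 3)
      ksign[ksign == 0] <- 1
      grad <- (eye - (ksign * tanh(u)) %*% t(u) / m -
                 tcrossprod(u) / m) %*% w
    } else {
      y <- 1 / (1 + exp(-u))
      grad <- (eye + ((1 - 2 * y) %*% t(u)) / m) %*% w
    }
    dw <- lr * grad
    step <- max(abs(dw))
    if (!is.finite(step) || step > 1e3) {
      lr <- lr / 2           # anneal on divergence, retry this step
      if (lr < 1e-12) break
      grad_old <- NULL
      next
    }
    # anneal when the gradient direction reverses (oscillation)
    if (!is.null(grad_old) && sum(grad * grad_old) < 0) lr <- lr * 0.9
    grad_old <- grad
    w <- w + dw
    if (step < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "infomax ICA did not reach tol = %g within %d iterations (last step %g)",
      tol, max_iter, max(abs(lr * grad))))
  }

  z <- w %*% z0                                   # k x m source estimates
  a <- sv$u[, seq_len(k), drop = FALSE] %*%
    (diag(d_k, nrow = k) %*% solve(w)) / sqrt(m)  # X_c ~ a %*% z
  sds <- apply(z, 1L, sd_pop)
  if (any(sds == 0)) {
    stop_mica("ICA produced a constant source row", class = "degenerate")
  }
  sources <- z / sds
  mixing <- a * rep(sds, each = nrow(a))
  # order factors by the variance they carry in the data
  ord <- order(colSums(mixing^2), decreasing = TRUE)
  mixing <- mixing[, ord, drop = FALSE]
  sources <- sources[ord, , drop = FALSE]
  rownames(mixing) <- rownames(centered)
  colnames(sources) <- colnames(centered)
  o <- orient_factors(mixing, sources)
  new_factor_decomposition("ica", o$mixing, o$sources, site_means,
                           variance_retained = sum(d_k^2) / sum(sv$d^2),
                           seed = seed, converged = converged,
                           iterations = iter)
}

#' Standardized per-site contributions of a factor
#'
#' The Z score of a site is its source loading standardized over all
#' sites (population standard deviation); ranking by |Z| gives the
#' sites that drive the factor.
#'
#' @param decomp a `factor_decomposition`.
#' @param factor_index which factor.
#' @return a `site_z_scores` list with `factor_index` and the named
#'   numeric vector `z`.
#' @export
site_z_scores <- function(decomp, factor_index) {
  stopifnot(inherits(decomp, "factor_decomposition"))
  if (factor_index < 1L || factor_index > decomp$k) {
    stop_mica("factor_index %d out of range 1..%d", factor_index, decomp$k,
              class = "bad_index")
  }
  s <- decomp$sources[factor_index, ]
  sdev <- sd_pop(s)
  if (sdev == 0) {
    stop_mica("source row %d is constant; Z scores undefined", factor_index,
              class = "degenerate")
  }
  structure(list(factor_index = as.integer(factor_index),
                 z = (s - mean(s)) / sdev),
            class = "site_z_scores")
}

#' @export
print.site_z_scores <- function(x, ...) {
  top <- head(order(abs(x$z), decreasing = TRUE), 5L)
  cat(sprintf("site Z scores for factor %d (|Z| up to %.2f)\n",
              x$factor_index, max(abs(x$z))))
  cat("  top sites:",
      paste(sprintf("%s (%.2f)", names(x$z)[top], x$z[top]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Persist a factor decomposition as a directory of TSV files
#'
#' Writes `mixing.tsv`, `sources.tsv`, `site_means.tsv` and
#' `metadata.tsv` (key-value) so a run can be audited and resumed.
#'
#' @param decomp a `factor_decomposition`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(decomp, dir) {
  stopifnot(inherits(decomp, "factor_decomposition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, path, id_name) {
    df <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE,
                                         scientific = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c(id_name, colnames(m))
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  }
  wr(decomp$mixing, file.path(dir, "mixing.tsv"), "subject_id")
  wr(t(decomp$sources), file.path(dir, "sources.tsv"), "site_id")
  data.table::fwrite(
    data.frame(site_id = names(decomp$site_means),
               site_mean = sprintf("%.17g", decomp$site_means)),
    file.path(dir, "site_means.tsv"), sep = "\t", quote = FALSE)
  meta <- c(method = decomp$method,
            k = decomp$k,
            variance_retained = sprintf("%.17g", decomp$variance_retained),
            seed = decomp$seed %||% "NA",
            converged = decomp$converged,
            iterations = decomp$iterations)
  writeLines(paste(names(meta), unname(meta), sep = "\t"),
             file.path(dir, "metadata.tsv"))
  if (!is.null(decomp$explained)) {
    writeLines(c("factor\texplained_fraction",
                 paste(seq_along(decomp$explained),
                       sprintf("%.17g", decomp$explained), sep = "\t")),
               file.path(dir, "explained.tsv"))
  }
  invisible(dir)
}

#' Read back a decomposition written by [write_decomposition()]
#'
#' @param dir directory containing the TSV files.
#' @return a `factor_decomposition`.
#' @export
read_decomposition <- function(dir) {
  rd <- function(name) {
    df <- data.table::fread(file.path(dir, name), sep = "\t",
                            data.table = FALSE, colClasses = list(character = 1L))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1L]]
    m
  }
  mixing <- rd("mixing.tsv")
  sources <- t(rd("sources.tsv"))
  mu_df <- data.table::fread(file.path(dir, "site_means.tsv"),
                             data.table = FALSE)
  site_means <- stats::setNames(as.numeric(mu_df$site_mean), mu_df$site_id)
  meta_lines <- strsplit(readLines(file.path(dir, "metadata.tsv")), "\t")
  meta <- stats::setNames(vapply(meta_lines, `[`, "", 2L),
                          vapply(meta_lines, `[`, "", 1L))
  explained <- NULL
  if (file.exists(file.path(dir, "explained.tsv"))) {
    ex <- data.table::fread(file.path(dir, "explained.tsv"),
                            data.table = FALSE)
    explained <- as.numeric(ex$explained_fraction)
  }
  new_factor_decomposition(meta[["method"]], mixing, sources, site_means,
                           variance_retained = as.numeric(meta[["variance_retained"]]),
                           explained = explained,
                           seed = if (meta[["seed"]] == "NA") NULL
                                  else as.integer(meta[["seed"]]),
                           converged = as.logical(meta[["converged"]]),
                           iterations = as.integer(meta[["iterations"]]))
}
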