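# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to integer
#'
#' Base `round()` rounds half to even; overlap percentages are reported
#' with conventional half-up rounding so 81.48 -> 81 and 7.69 -> 8.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Column means/variances with NA support
#'
#' Sample (n-1 denominator) per-column variance; columns with fewer than
#' two observed values get NA.
#' @noRd
col_vars <- function(x) {
  n <- colSums(!is.na(x))
  mu <- colMeans(x, na.rm = TRUE)
  ss <- colSums(sweep(x, 2L, mu, `-`)^2, na.rm = TRUE)
  out <- ss / (n - 1L)
  out[n < 2L] <- NA_real_
  out
}

# Population (n denominator) standard deviation of a vector.
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Run code with a private RNG stream
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state
#' so library calls do not perturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used to
# stamp pipeline artifacts with a configuration fingerprint.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply by the FNV prime, split into 16-bit halves
    # to stay inside exact double-precision integer range.
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_mica <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "methylICA_error")))
}
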