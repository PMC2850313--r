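# S3 container for a subjects x sites matrix of methylation beta values
# plus per-site annotation (gene, chromosome, position).

VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y", "MT", "unknown")

#' Normalize chromosome labels
#'
#' Strips a leading `chr` prefix, upper-cases sex/mitochondrial labels and
#' maps anything outside `1..22, X, Y, MT` to `"unknown"`.
#'
#' @param x character vector of raw chromosome labels.
#' @return character vector with values in
#'   `c("1".."22", "X", "Y", "MT", "unknown")`.
#' @examples
#' normalize_chromosome(c("chr1", "chrX", "y", "M", "contig7"))
#' @export
normalize_chromosome <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "unknown"
  x <- sub("^[Cc][Hh][Rr]", "", trimws(x))
  x <- toupper(x)
  x[x %in% c("M", "MT")] <- "MT"
  x[!(x %in% VALID_CHROMOSOMES)] <- "unknown"
  x
}

#' Construct a site annotation table
#'
#' @param site_id unique site identifiers (e.g. Illumina cg IDs).
#' @param gene gene symbol per site; `""` when unannotated.
#' @param chromosome chromosome label, normalized via
#'   [normalize_chromosome()].
#' @param position optional base-pair position (non-negative integer).
#' @return a `data.frame` with columns `site_id`, `gene`, `chromosome`,
#'   `position`.
#' @export
site_annotation <- function(site_id, gene = "", chromosome = "unknown",
                            position = NA_integer_) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id)) {
    dup <- unique(site_id[duplicated(site_id)])
    stop_mica("duplicate site identifiers: %s",
              paste(head(dup, 5L), collapse = ", "),
              class = "duplicate_ids")
  }
  if (any(!is.na(position) & position < 0)) {
    stop_mica("site positions must be non-negative", class = "bad_annotation")
  }
  data.frame(site_id = site_id,
             gene = rep_len(as.character(gene), length(site_id)),
             chromosome = normalize_chromosome(
               rep_len(as.character(chromosome), length(site_id))),
             position = rep_len(as.integer(position), length(site_id)),
             stringsAsFactors = FALSE)
}

#' Construct a beta-value matrix
#'
#' The canonical orientation is subjects in rows, sites in columns. Values
#' must be methylation fractions in `[0, 1]` (or `NA`); matrices produced
#' by [remove_factor()] may carry values slightly outside that range and
#' are built with `range_check = FALSE`.
#'
#' @param values numeric matrix, subjects x sites.
#' @param subject_ids unique subject identifiers (defaults to rownames).
#' @param sites site annotation `data.frame` as built by
#'   [site_annotation()]; defaults to bare annotations from colnames.
#' @param range_check reject values outside `[0, 1]`?
#' @return an object of class `beta_matrix` with elements `values`,
#'   `subject_ids` and `sites`.
#' @export
beta_matrix <- function(values, subject_ids = rownames(values),
                        sites = NULL, range_check = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("S%03d", seq_len(nrow(values)))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values)) {
    stop_mica("subject_ids length (%d) != number of rows (%d)",
              length(subject_ids), nrow(values), class = "bad_dimensions")
  }
  if (anyDuplicated(subject_ids)) {
    dup <- unique(subject_ids[duplicated(subject_ids)])
    stop_mica("duplicate subject identifiers: %s",
              paste(head(dup, 5L), collapse = ", "),
              class = "duplicate_ids")
  }
  if (is.null(sites)) {
    ids <- colnames(values) %||% sprintf("site%05d", seq_len(ncol(values)))
    sites <- site_annotation(ids)
  }
  stopifnot(is.data.frame(sites),
            all(c("site_id", "gene", "chromosome") %in% names(sites)))
  if (nrow(sites) != ncol(values)) {
    stop_mica("sites table has %d rows but matrix has %d columns",
              nrow(sites), ncol(values), class = "bad_dimensions")
  }
  if (range_check) {
    bad <- which(!is.na(values) & (values < 0 | values > 1))
    if (length(bad)) {
      bad_sites <- unique(sites$site_id[(bad - 1L) %/% nrow(values) + 1L])
      stop_mica("beta values outside [0,1] at site(s): %s",
                paste(head(bad_sites, 5L), collapse = ", "),
                class = "value_out_of_range")
    }
  }
  rownames(values) <- subject_ids
  colnames(values) <- sites$site_id
  structure(list(values = values,
                 subject_ids = subject_ids,
                 sites = sites),
            class = "beta_matrix")
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' @export
as.matrix.beta_matrix <- function(x, ...) x$values

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d subjects x %d sites\n",
              nrow(x$values), ncol(x$values)))
  chroms <- table(x$sites$chromosome)
  cat("  chromosomes:",
      paste(sprintf("%s(%d)", names(chroms), chroms), collapse = " "), "\n")
  n_na <- sum(is.na(x$values))
  if (n_na) cat(sprintf("  missing values: %d\n", n_na))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  value range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Subset a beta matrix by site index or id
#'
#' @param x a `beta_matrix`.
#' @param sites integer, logical or character index into the site axis.
#' @return a `beta_matrix` restricted to the selected sites (order kept).
#' @export
subset_sites <- function(x, sites) {
  stopifnot(inherits(x, "beta_matrix"))
  if (is.character(sites)) sites <- match(sites, x$sites$site_id)
  if (anyNA(sites)) stop_mica("unknown site identifiers", class = "unknown_sites")
  beta_matrix(x$values[, sites, drop = FALSE],
              subject_ids = x$subject_ids,
              sites = x$sites[sites, , drop = FALSE],
              range_check = FALSE)
}
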