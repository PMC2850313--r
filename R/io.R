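# Delimited-text readers/writers for beta matrices, phenotype tables,
# site annotations and detection-P tables. GEO series-matrix-like layouts
# (sites in rows, subjects in columns) are supported via `orientation`.

read_delim_table <- function(path, missing_token = "NA") {
  if (!file.exists(path)) {
    stop_mica("file not found: %s", path, class = "missing_file")
  }
  data.table::fread(path, header = TRUE, na.strings = missing_token,
                    data.table = FALSE, colClasses = list(character = 1L),
                    showProgress = FALSE)
}

#' Read a methylation beta-value matrix from delimited text
#'
#' Accepts TSV or CSV (separator sniffed by `data.table::fread`) with one
#' header row and identifiers in the first column. The result is always
#' oriented subjects x sites regardless of the on-disk orientation.
#'
#' @param path file path.
#' @param orientation `"sites_in_rows"` (GEO series-matrix layout: one row
#'   per CpG site, one column per subject) or `"subjects_in_rows"`.
#' @param missing_token string marking missing values (default `"NA"`).
#' @param annotation optional site annotation `data.frame` (see
#'   [read_site_annotation()]) joined onto the matrix by `site_id`.
#' @return a [beta_matrix()].
#' @export
read_beta_table <- function(path,
                            orientation = c("sites_in_rows",
                                            "subjects_in_rows"),
                            missing_token = "NA",
                            annotation = NULL) {
  orientation <- match.arg(orientation)
  df <- read_delim_table(path, missing_token)
  if (ncol(df) < 2L) {
    stop_mica("beta table %s has no value columns", path, class = "parse_error")
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_mica("duplicate identifiers in %s: %s", path,
              paste(head(dup, 5L), collapse = ", "), class = "duplicate_ids")
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(!is.na(vals[[j]]) &
                     is.na(suppressWarnings(as.numeric(vals[[j]]))))
      stop_mica("non-numeric value in %s at row '%s', column '%s'",
                path, ids[bad[1L] %||% 1L], names(vals)[j],
                class = "parse_error")
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "sites_in_rows") m <- t(m)
  bad <- which(!is.na(m) & (m < 0 | m > 1))
  if (length(bad)) {
    bad_sites <- unique(colnames(m)[(bad - 1L) %/% nrow(m) + 1L])
    stop_mica("beta values outside [0,1] in %s at site(s): %s", path,
              paste(head(bad_sites, 5L), collapse = ", "),
              class = "value_out_of_range")
  }
  sites <- site_annotation(colnames(m))
  bm <- beta_matrix(m, subject_ids = rownames(m), sites = sites)
  if (!is.null(annotation)) bm <- set_site_annotation(bm, annotation)
  bm
}

#' Write a beta matrix as delimited text
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the matrix exactly.
#'
#' @param x a [beta_matrix()].
#' @param path output file; the separator is tab unless the path ends in
#'   `.csv`.
#' @param orientation on-disk layout (see [read_beta_table()]).
#' @param missing_token string used for missing values.
#' @return `path`, invisibly.
#' @export
write_beta_table <- function(x, path,
                             orientation = c("sites_in_rows",
                                             "subjects_in_rows"),
                             missing_token = "NA") {
  stopifnot(inherits(x, "beta_matrix"))
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- x$values
  if (orientation == "sites_in_rows") {
    m <- t(m)
    id_name <- "site_id"
  } else {
    id_name <- "subject_id"
  }
  fmt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  fmt[is.na(m)] <- missing_token
  lines <- c(paste(c(id_name, colnames(m)), collapse = sep),
             paste(rownames(m), apply(fmt, 1L, paste, collapse = sep),
                   sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a site annotation table
#'
#' Expects columns `site_id`, `gene`, `chromosome` and optionally
#' `position`; chromosome labels are normalized.
#'
#' @param path file path (TSV/CSV).
#' @return a site annotation `data.frame`.
#' @export
read_site_annotation <- function(path) {
  df <- read_delim_table(path)
  need <- c("site_id", "gene", "chromosome")
  if (!all(need %in% names(df))) {
    stop_mica("annotation %s must have columns %s", path,
              paste(need, collapse = ", "), class = "parse_error")
  }
  site_annotation(df$site_id, df$gene, df$chromosome,
                  if ("position" %in% names(df)) df$position else NA_integer_)
}

#' Attach site annotation to a beta matrix
#'
#' Sites absent from the annotation keep gene `""` and chromosome
#' `"unknown"`.
#'
#' @param x a [beta_matrix()].
#' @param annotation annotation `data.frame` keyed by `site_id`.
#' @return the annotated `beta_matrix`.
#' @export
set_site_annotation <- function(x, annotation) {
  stopifnot(inherits(x, "beta_matrix"))
  idx <- match(x$sites$site_id, annotation$site_id)
  hit <- !is.na(idx)
  x$sites$gene[hit] <- annotation$gene[idx[hit]]
  x$sites$chromosome[hit] <- normalize_chromosome(annotation$chromosome[idx[hit]])
  if ("position" %in% names(annotation)) {
    x$sites$position[hit] <- as.integer(annotation$position[idx[hit]])
  }
  x
}

#' Read a phenotype table
#'
#' One row per subject; the first column (or a column named
#' `subject_id`) holds subject identifiers. The grouping phenotype must
#' have exactly two observed levels and is recoded to `{0, 1}`; with
#' female/male-style labels the female level is coded 1 (so "group 1"
#' means females throughout the package), otherwise the
#' lexicographically second level is coded 1. All other numeric columns
#' are kept as continuous phenotypes with missing values allowed.
#'
#' @param path file path (TSV/CSV).
#' @param group_name name of the binary grouping column (e.g. `"sex"`).
#' @param group_levels optional length-2 character vector
#'   `c(level0, level1)` fixing the coding explicitly.
#' @param missing_token string marking missing values.
#' @return a `phenotype_table`: a `data.frame` with `subject_id`, the
#'   coded group column and the continuous columns, plus attributes
#'   `group_name` and `level_map`.
#' @export
read_phenotype_table <- function(path, group_name, group_levels = NULL,
                                 missing_token = "NA") {
  df <- read_delim_table(path, missing_token)
  id_col <- if ("subject_id" %in% names(df)) "subject_id" else names(df)[1L]
  subject_ids <- as.character(df[[id_col]])
  rest <- df[, setdiff(names(df), id_col), drop = FALSE]
  if (!group_name %in% names(rest)) {
    stop_mica("phenotype table has no column '%s'", group_name,
              class = "missing_phenotype")
  }
  phenotype_table(subject_ids, group = rest[[group_name]],
                  group_name = group_name, group_levels = group_levels,
                  continuous = rest[, setdiff(names(rest), group_name),
                                    drop = FALSE])
}

#' Construct a phenotype table
#'
#' @param subject_ids unique subject identifiers.
#' @param group raw values of the binary grouping phenotype.
#' @param group_name its name.
#' @param group_levels optional `c(level0, level1)` coding order.
#' @param continuous `data.frame` of continuous phenotypes (may be empty).
#' @return a `phenotype_table` (see [read_phenotype_table()]).
#' @export
phenotype_table <- function(subject_ids, group, group_name = "group",
                            group_levels = NULL, continuous = NULL) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) {
    dup <- unique(subject_ids[duplicated(subject_ids)])
    stop_mica("duplicate subject identifiers: %s",
              paste(head(dup, 5L), collapse = ", "), class = "duplicate_ids")
  }
  group <- as.character(group)
  obs <- sort(unique(group[!is.na(group)]))
  if (length(obs) != 2L) {
    stop_mica("grouping phenotype '%s' has %d observed level(s); exactly 2 required",
              group_name, length(obs), class = "bad_group_levels")
  }
  if (is.null(group_levels)) {
    female_like <- tolower(obs) %in% c("f", "female", "fem")
    group_levels <- if (any(female_like)) {
      c(obs[!female_like], obs[female_like])
    } else {
      obs
    }
  }
  if (!setequal(group_levels, obs)) {
    stop_mica("group_levels %s do not match observed levels %s",
              paste(group_levels, collapse = "/"),
              paste(obs, collapse = "/"), class = "bad_group_levels")
  }
  coded <- ifelse(is.na(group), NA_integer_,
                  ifelse(group == group_levels[2L], 1L, 0L))
  out <- data.frame(subject_id = subject_ids, stringsAsFactors = FALSE)
  out[[group_name]] <- coded
  if (!is.null(continuous) && ncol(continuous)) {
    for (nm in names(continuous)) {
      out[[nm]] <- suppressWarnings(as.numeric(continuous[[nm]]))
    }
  }
  attr(out, "group_name") <- group_name
  level_map <- c(0L, 1L)
  names(level_map) <- group_levels
  attr(out, "level_map") <- level_map
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a phenotype table as TSV
#'
#' The coded group column is written back using its original labels.
#'
#' @param x a `phenotype_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(x, path) {
  stopifnot(inherits(x, "phenotype_table"))
  out <- as.data.frame(x)
  gname <- attr(x, "group_name")
  lm <- attr(x, "level_map")
  out[[gname]] <- names(lm)[match(out[[gname]], lm)]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Names of the continuous phenotypes in a phenotype table
#' @param x a `phenotype_table`.
#' @return character vector of column names.
#' @export
continuous_phenotypes <- function(x) {
  setdiff(names(x), c("subject_id", attr(x, "group_name")))
}

#' Align a phenotype table with a beta matrix
#'
#' Explicit join by subject id: the returned table has rows in the same
#' order as the matrix's subjects. Subjects missing from either side are
#' an error.
#'
#' @param data a [beta_matrix()].
#' @param phenotypes a `phenotype_table`.
#' @return the reordered `phenotype_table`.
#' @export
align_phenotypes <- function(data, phenotypes) {
  stopifnot(inherits(data, "beta_matrix"),
            inherits(phenotypes, "phenotype_table"))
  idx <- match(data$subject_ids, phenotypes$subject_id)
  if (anyNA(idx)) {
    miss <- data$subject_ids[is.na(idx)]
    stop_mica("subjects missing from phenotype table: %s",
              paste(head(miss, 5L), collapse = ", "),
              class = "misaligned_subjects")
  }
  out <- phenotypes[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_name") <- attr(phenotypes, "group_name")
  attr(out, "level_map") <- attr(phenotypes, "level_map")
  class(out) <- class(phenotypes)
  out
}

#' Read a per-site detection P-value table
#'
#' Expects columns `site_id` and `detection_p` (mean detection P across
#' subjects for each site).
#'
#' @param path file path.
#' @return named numeric vector of mean detection P-values.
#' @export
read_detection_table <- function(path) {
  df <- read_delim_table(path)
  if (!all(c("site_id", "detection_p") %in% names(df))) {
    stop_mica("detection table %s must have columns site_id, detection_p",
              path, class = "parse_error")
  }
  stats::setNames(as.numeric(df$detection_p), as.character(df$site_id))
}
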