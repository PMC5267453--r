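#' Construct and validate a beta-value matrix
#'
#' A beta matrix holds DNA-methylation beta values (methylated signal /
#' total signal, a fraction in \[0, 1\]) for CpG sites in rows and samples
#' in columns. Missing values are allowed and encoded as `NA`; values
#' outside \[0, 1\] are rejected.
#'
#' @param values Numeric matrix, sites x samples. `NA` entries mark
#'   missing measurements.
#' @param site_ids Character vector of unique CpG identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers;
#'   defaults to `colnames(values)`.
#' @return A numeric matrix of class `"beta_matrix"` with site ids as row
#'   names and sample ids as column names.
#' @examples
#' b <- beta_matrix(matrix(c(0.1, 0.9, 0.5, 0.2, 0.8, 0.5), nrow = 3),
#'                  site_ids = c("cg1", "cg2", "cg3"),
#'                  sample_ids = c("s1", "s2"))
#' @export
beta_matrix <- function(values, site_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(site_ids) || is.null(sample_ids))
    stop("site and sample identifiers are required")
  site_ids <- as.character(site_ids)
  sample_ids <- as.character(sample_ids)
  if (length(site_ids) != nrow(values))
    stop("length of 'site_ids' (", length(site_ids),
         ") does not match the number of rows (", nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("length of 'sample_ids' (", length(sample_ids),
         ") does not match the number of columns (", ncol(values), ")")
  dup <- site_ids[duplicated(site_ids)]
  if (length(dup))
    stop("duplicated site id(s): ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop("beta value out of [0, 1] at site '", site_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "': ",
         values[bad[1, , drop = FALSE]])
  dimnames(values) <- list(site_ids, sample_ids)
  class(values) <- c("beta_matrix", class(matrix()))
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("Beta-value matrix:", nrow(x), "CpG sites x", ncol(x), "samples\n")
  n_na <- sum(is.na(x))
  if (n_na > 0) cat("  missing entries:", n_na, "\n")
  cat("  samples:", paste(utils::head(colnames(x), 5), collapse = ", "),
      if (ncol(x) > 5) "..." else "", "\n")
  invisible(x)
}

#' Define tumor and normal sample groups
#'
#' @param tumor_ids Character vector of tumor sample identifiers.
#' @param normal_ids Character vector of normal (control) sample
#'   identifiers; may be empty for control-free workflows.
#' @return An object of class `"sample_groups"`.
#' @export
sample_groups <- function(tumor_ids, normal_ids = character()) {
  tumor_ids <- as.character(tumor_ids)
  normal_ids <- as.character(normal_ids)
  if (anyDuplicated(tumor_ids) || anyDuplicated(normal_ids))
    stop("sample ids within a group must be unique")
  both <- intersect(tumor_ids, normal_ids)
  if (length(both))
    stop("sample(s) in both groups: ", paste(both, collapse = ", "))
  structure(list(tumor_ids = tumor_ids, normal_ids = normal_ids),
            class = "sample_groups")
}

#' @export
print.sample_groups <- function(x, ...) {
  cat("Sample groups:", length(x$tumor_ids), "tumor,",
      length(x$normal_ids), "normal\n")
  invisible(x)
}

# Checks that every id in 'groups' resolves against the beta matrix.
check_groups <- function(beta, groups) {
  stopifnot(inherits(groups, "sample_groups"))
  miss <- setdiff(c(groups$tumor_ids, groups$normal_ids), colnames(beta))
  if (length(miss))
    stop("sample id(s) not found in the beta matrix: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

# Drops sites with any missing value among the given samples; messages the
# count. Returns the row-subset matrix.
drop_incomplete_sites <- function(beta, sample_ids, context = "analysis") {
  sub <- beta[, sample_ids, drop = FALSE]
  bad <- rowSums(is.na(sub)) > 0
  if (any(bad))
    message(sum(bad), " site(s) with missing values dropped from ",
            context)
  sub[!bad, , drop = FALSE]
}

resolve_sep <- function(dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  if (dialect == "tab") "\t" else ","
}

#' Read a beta-value matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of CpG site ids.
#' Lines starting with `#` are treated as comments. Cells must be numeric
#' in \[0, 1\] or the missing-value token.
#'
#' @param path Path to the file.
#' @param dialect `"tab"` (default) or `"comma"`.
#' @param na Missing-value token (default `"NA"`).
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, dialect = c("tab", "comma"), na = "NA") {
  sep <- resolve_sep(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop("expected a site-id column plus at least one sample column")
  site_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  num[cells == na] <- NA_real_
  bad <- which(is.na(num) & cells != na, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell '", cells[bad[1, , drop = FALSE]],
         "' at row ", bad[1, 1], " (site '", site_ids[bad[1, 1]],
         "'), column ", bad[1, 2], " (sample '", sample_ids[bad[1, 2]],
         "')")
  out_of_range <- which(!is.na(num) & (num < 0 | num > 1), arr.ind = TRUE)
  if (nrow(out_of_range))
    stop("beta value out of [0, 1] at row ", out_of_range[1, 1],
         ", column ", out_of_range[1, 2], ": ",
         num[out_of_range[1, , drop = FALSE]])
  beta_matrix(num, site_ids = site_ids, sample_ids = sample_ids)
}

#' Write a beta-value matrix to delimited text
#'
#' @param beta A [beta_matrix()].
#' @param path Output path.
#' @param dialect `"tab"` or `"comma"`.
#' @param header_lines Optional character vector written as leading `#`
#'   comment lines (provenance header).
#' @export
write_beta_matrix <- function(beta, path, dialect = c("tab", "comma"),
                              header_lines = NULL) {
  sep <- resolve_sep(dialect)
  df <- data.frame(site_id = rownames(beta), as.data.frame(unclass(beta)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("site_id", colnames(beta))
  write_table(df, path, dialect = dialect, header_lines = header_lines)
}

#' Write a result table as delimited text
#'
#' Plain writer used for all tabular outputs: header row, no quoting,
#' `NA` for missing, full numeric precision so that tables round-trip
#' through [read_table()].
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param dialect `"tab"` or `"comma"`.
#' @param header_lines Optional `#` comment lines written before the
#'   header.
#' @export
write_table <- function(rows, path, dialect = c("tab", "comma"),
                        header_lines = NULL) {
  sep <- resolve_sep(dialect)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_lines) && length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  rows <- as.data.frame(rows)
  # full-precision serialization of numeric columns
  out <- rows
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- format(out[[j]], digits = 17,
                                                 trim = TRUE,
                                                 scientific = NA)
  utils::write.table(out, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(NULL)
}

#' Read a delimited result table
#'
#' Counterpart to [write_table()]; `#` comment lines are skipped and
#' column types are inferred.
#'
#' @param path Path to the file.
#' @param dialect `"tab"` or `"comma"`.
#' @return A data frame.
#' @export
read_table <- function(path, dialect = c("tab", "comma")) {
  sep <- resolve_sep(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    comment.char = "#", quote = "",
                    stringsAsFactors = FALSE)
}

#' Read a tumor-purity table
#'
#' Two-column delimited file: `sample_id`, `purity` with purities in
#' (0, 1].
#'
#' @param path Path to the file.
#' @param dialect `"tab"` or `"comma"`.
#' @return A named numeric vector of purities.
#' @export
read_purity_table <- function(path, dialect = c("tab", "comma")) {
  df <- read_table(path, dialect = dialect)
  if (ncol(df) < 2) stop("purity table needs columns: sample_id, purity")
  lam <- as.numeric(df[[2]])
  names(lam) <- as.character(df[[1]])
  validate_purity(lam)
}

#' Validate a purity vector
#'
#' @param lambda Named numeric vector of purity fractions.
#' @return The validated vector.
#' @export
validate_purity <- function(lambda) {
  if (is.null(names(lambda)) || any(names(lambda) == ""))
    stop("purities must be named by sample id")
  if (anyDuplicated(names(lambda)))
    stop("duplicated sample id(s) in purity table")
  if (any(is.na(lambda)))
    stop("missing purity value(s)")
  if (any(lambda <= 0 | lambda > 1))
    stop("purities must lie in (0, 1]; offending sample(s): ",
         paste(names(lambda)[lambda <= 0 | lambda > 1], collapse = ", "))
  lambda
}

#' Read an iDMC list
#'
#' Delimited file with columns `site_id` and `direction`
#' (`hyper`/`hypo`); extra columns are kept.
#'
#' @param path Path to the file.
#' @param dialect `"tab"` or `"comma"`.
#' @return A data frame of class `"idmc_set"`.
#' @export
read_idmc_list <- function(path, dialect = c("tab", "comma")) {
  df <- read_table(path, dialect = dialect)
  if (!all(c("site_id", "direction") %in% colnames(df)))
    stop("iDMC list needs columns: site_id, direction")
  as_idmc_set(df)
}

as_idmc_set <- function(df) {
  df$site_id <- as.character(df$site_id)
  df$direction <- as.character(df$direction)
  if (!all(df$direction %in% c("hyper", "hypo")))
    stop("direction must be 'hyper' or 'hypo'")
  if (anyDuplicated(df$site_id))
    stop("duplicated site id(s) in iDMC set")
  class(df) <- c("idmc_set", "data.frame")
  df
}
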