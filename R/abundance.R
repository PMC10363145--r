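## Abundance matrices and sample metadata: the tabular backbone of the
## pipeline. An abundance table is a plain numeric matrix (analytes x
## samples, log-scale values) wrapped in a light S3 class that enforces
## unique identifiers; metadata is a validated data.frame keyed by sample.

#' Construct an abundance table
#'
#' An `abundance_table` is a numeric matrix of log-scale abundance values
#' with analytes as rows and samples as columns. Row and column names are
#' the analyte and sample identifiers and must be unique non-empty strings.
#' Missing values are allowed (`NA`) and are handled only by
#' [filter_complete_analytes()].
#'
#' @param values Numeric matrix with unique rownames (analytes) and unique
#'   colnames (samples).
#' @return An object of class `abundance_table` (a matrix).
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
#' abundance_table(m)
#' @export
abundance_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    fail("abundance values must be a numeric matrix")
  }
  an <- rownames(values)
  sn <- colnames(values)
  if (is.null(an) || is.null(sn) || any(!nzchar(an)) || any(!nzchar(sn))) {
    fail("abundance matrix must carry non-empty analyte rownames and sample colnames")
  }
  dup_a <- unique(an[duplicated(an)])
  if (length(dup_a)) {
    fail("duplicate analyte identifiers: %s", paste(dup_a, collapse = ", "))
  }
  dup_s <- unique(sn[duplicated(sn)])
  if (length(dup_s)) {
    fail("duplicate sample identifiers: %s", paste(dup_s, collapse = ", "))
  }
  structure(values, class = c("abundance_table", class(values)))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d analytes x %d samples (%d missing values)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

# Strip the class for plain matrix work.
ab_values <- function(x) {
  class(x) <- setdiff(class(x), "abundance_table")
  x
}

#' Construct and validate sample metadata
#'
#' Sample annotations used throughout the pipeline: experimental group
#' (e.g., Control vs one or more interventions), sex, and age in months
#' (treated as a categorical variable at month resolution).
#'
#' @param df Data frame with columns `sample_id`, `group`, `sex`,
#'   `age_months`.
#' @return A validated data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "group", "sex", "age_months")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    fail("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$sex <- as.character(df$sex)
  df$age_months <- as.character(df$age_months)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) {
    fail("duplicate sample_id in metadata: %s", paste(dup, collapse = ", "))
  }
  if (anyNA(df[need])) fail("metadata contains missing values")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

# Align metadata rows to a table's samples; every sample must have exactly
# one metadata row.
match_metadata <- function(table, meta) {
  sn <- colnames(table)
  missing <- setdiff(sn, meta$sample_id)
  if (length(missing)) {
    fail("samples without metadata: %s", paste(missing, collapse = ", "))
  }
  meta[match(sn, meta$sample_id), , drop = FALSE]
}

#' Read an abundance matrix from TSV/CSV
#'
#' Expects a header row and the identifier in the first column. Empty
#' strings, `"NA"` and `"NaN"` are parsed as missing. The default
#' orientation has analytes as rows; use `orientation = "samples-rows"` for
#' transposed files.
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param orientation `"analytes-rows"` (default) or `"samples-rows"`.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, orientation = c("analytes-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA", "NaN"),
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  ids <- as.character(raw[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    fail("duplicate identifiers in %s: %s", path, paste(dup, collapse = ", "))
  }
  body <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body),
                dimnames = list(ids, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad)) {
    fail("non-numeric value at row '%s', column '%s' in %s",
         ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]], path)
  }
  if (orientation == "samples-rows") num <- t(num)
  dlog("read_abundance: %d analytes x %d samples from %s",
       nrow(num), ncol(num), path)
  abundance_table(num)
}

#' Write an abundance matrix to TSV
#'
#' Inverse of [read_abundance()]: identifier first column, header row,
#' missing values written as `NA`. Full double precision is preserved so
#' read-write-read is an identity up to 1e-12.
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @param id_column Name for the identifier column header.
#' @export
write_abundance <- function(table, path, id_column = "analyte_id") {
  df <- data.frame(id = rownames(table),
                   format(ab_values(table), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `group`, `sex`, `age_months`.
#' @return A [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  sample_metadata(df)
}

#' Write sample metadata to TSV
#' @param meta A [sample_metadata()] data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
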