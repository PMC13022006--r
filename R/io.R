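#' Table schemas used by the pipeline
#'
#' Each schema lists required and optional columns for a delimited-text
#' table. Delimiter (comma or tab) is auto-detected, `#`-prefixed header
#' comments are skipped, unknown columns warn, missing required columns
#' error.
#'
#' @return Named list of schemas.
#' @export
table_schemas <- function() {
  list(
    aa_profile = list(
      required = c("sample_id", "d15n_phe", "d15n_glu", "d15n_ala"),
      optional = c("station", "year", "size_fraction", "habitat",
                   "sd_phe", "sd_glu", "sd_ala", "n_replicates"),
      numeric = c("year", "d15n_phe", "d15n_glu", "d15n_ala",
                  "sd_phe", "sd_glu", "sd_ala", "n_replicates")),
    endmember = list(
      required = c("organism", "group", "n_source",
                   "d15n_phe", "d15n_glu", "d15n_ala"),
      optional = character(0),
      numeric = c("d15n_phe", "d15n_glu", "d15n_ala")),
    ctd = list(
      required = c("depth"),
      optional = c("temperature", "salinity", "sigma_theta", "oxygen",
                   "fluorescence", "station"),
      numeric = c("depth", "temperature", "salinity", "sigma_theta",
                  "oxygen", "fluorescence")),
    nutrients = list(
      required = c("depth", "nox"),
      optional = c("po4", "si", "bottom_depth", "station"),
      numeric = c("depth", "nox", "po4", "si", "bottom_depth")))
}

.detect_sep <- function(path) {
  ln <- readLines(path, n = 50L, warn = FALSE)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) stop("empty table: ", path)
  if (lengths(regmatches(ln[1], gregexpr("\t", ln[1]))) > 0) "\t" else ","
}

#' Read a schema-checked delimited table
#'
#' @param path File path (UTF-8, comma- or tab-delimited, `#` comments).
#' @param schema A schema name from [table_schemas()], a schema list, or
#'   NULL to skip checking.
#' @return Data frame with typed columns; empty cells become NA.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("", "NA"),
                          fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    if (is.character(schema)) schema <- table_schemas()[[schema]]
    missing <- setdiff(schema$required, names(df))
    if (length(missing))
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    known <- c(schema$required, schema$optional)
    extra <- setdiff(names(df), known)
    if (length(extra))
      warning("unknown column(s) kept as-is: ",
              paste(extra, collapse = ", "))
    for (col in intersect(schema$numeric, names(df)))
      df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Write a table with a provenance comment header
#'
#' Tab-delimited UTF-8 with `#` comment lines recording the package
#' version and any metadata (seed, configuration hash) supplied; the
#' round trip through [read_table()] is the identity.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param meta Named list written as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, meta = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# sestonmix %s",
                     as.character(utils::packageVersion("sestonmix"))), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an amino-acid delta15N profile table
#' @param path File path.
#' @return Schema-checked data frame (see [table_schemas()]).
#' @export
read_aa_table <- function(path) read_table(path, "aa_profile")

#' Read a literature end-member table
#' @param path File path.
#' @return Schema-checked data frame.
#' @export
read_endmember_table <- function(path) read_table(path, "endmember")

#' Read a ratio matrix written as a delimited table
#'
#' Rows are classes (first column holds the class name), columns the
#' pigments with their standard headers.
#'
#' @param path File path.
#' @return Classes x pigments numeric matrix.
#' @export
read_ratio_matrix <- function(path) {
  df <- read_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!"Chl a" %in% colnames(m)) stop("ratio matrix lacks a Chl a column")
  if (any(m[, "Chl a"] != 1)) stop("Chl a ratios must all equal 1")
  m
}

#' Read a pigment concentration table
#'
#' @param path File path; a `sample_id` column plus pigment columns.
#' @return List with `pigments` matrix and `meta` data frame of the
#'   non-pigment columns.
#' @export
read_pigment_table <- function(path) {
  df <- read_table(path)
  pig <- intersect(pigment_names(), names(df))
  if (!length(pig)) stop("no recognised pigment columns in ", path)
  m <- as.matrix(df[, pig, drop = FALSE])
  storage.mode(m) <- "double"
  if ("sample_id" %in% names(df)) rownames(m) <- df$sample_id
  list(pigments = m, meta = df[, setdiff(names(df), pig), drop = FALSE])
}
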