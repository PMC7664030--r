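#' Declare the expected columns of an input table
#'
#' A schema is a named character vector mapping column names to semantic
#' types: `"character"`, `"numeric"`, `"integer"`, or `"binary"` (0/1).
#' A trailing `"?"` (e.g. `"integer?"`) marks the column nullable: empty
#' or `NA` cells pass through as `NA` instead of rejecting the row.
#' [read_table()] validates and coerces against it.
#'
#' @param ... Named type strings, e.g. `drug_id = "character"`.
#' @return A named character vector of class `qsmart_schema`.
#' @examples
#' table_schema(drug_id = "character", log_ic50 = "numeric")
#' @export
table_schema <- function(...) {
  s <- c(...)
  ok <- c("character", "numeric", "integer", "binary")
  if (is.null(names(s)) || any(names(s) == "") ||
      !all(sub("\\?$", "", s) %in% ok))
    stop("schema must be named entries with types among: ",
         paste(ok, collapse = ", "), " (optionally suffixed '?')",
         call. = FALSE)
  structure(s, class = "qsmart_schema")
}

# Schemas for the standard pipeline inputs.
qsmart_schemas <- function() {
  list(
    responses = table_schema(drug_id = "character",
                             cell_line_id = "character",
                             log_ic50 = "numeric",
                             source_flag = "binary"),
    mutations = table_schema(cell_line_id = "character", gene = "character",
                             wt = "character", position = "integer?",
                             mut = "character"),
    ppi = table_schema(protein1 = "character", protein2 = "character",
                       combined_score = "numeric"),
    annotations = table_schema(gene = "character", entity = "character",
                               level = "character"),
    hierarchy = table_schema(child = "character", parent = "character",
                             namespace = "character")
  )
}

#' Read and validate a delimited input table
#'
#' Reads a CSV or TSV file (delimiter inferred from the file extension,
#' header row required) and validates it against a schema. Rows whose cells
#' fail numeric/binary coercion are dropped and reported by line number via
#' a message; structural problems (missing column, empty file) are errors.
#'
#' @param path File path ending in `.csv` (comma) or `.tsv`/`.txt` (tab).
#' @param schema A [table_schema()].
#' @return A data frame with columns coerced to the declared types; the
#'   rejected source line numbers (if any) are attached as attribute
#'   `"rejected_lines"`.
#' @export
read_table <- function(path, schema) {
  stopifnot(inherits(schema, "qsmart_schema"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0L && ncol(df) == 0L)
    stop("empty input file: ", path, call. = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[names(schema)]
  bad <- rep(FALSE, nrow(df))
  for (cl in names(schema)) {
    nullable <- grepl("\\?$", schema[[cl]])
    ty <- sub("\\?$", "", schema[[cl]])
    if (ty == "character") next
    suppressWarnings(v <- as.numeric(df[[cl]]))
    fail <- is.na(v) & !is.na(df[[cl]]) & df[[cl]] != ""
    if (ty %in% c("integer", "binary"))
      fail <- fail | (!is.na(v) & v != round(v))
    if (ty == "binary")
      fail <- fail | (!is.na(v) & !v %in% c(0, 1))
    empty <- is.na(df[[cl]]) | df[[cl]] == ""
    bad <- bad | fail | (empty & !nullable)
  }
  if (any(bad)) {
    # +1 for the header row: report source-file line numbers
    message("read_table: rejected ", sum(bad), " row(s) at line(s) ",
            paste(which(bad) + 1L, collapse = ", "), " in ", basename(path))
  }
  out <- df[!bad, , drop = FALSE]
  for (cl in names(schema)) {
    out[[cl]] <- switch(sub("\\?$", "", schema[[cl]]),
      character = out[[cl]],
      numeric = as.numeric(out[[cl]]),
      integer = suppressWarnings(as.integer(out[[cl]])),
      binary = suppressWarnings(as.integer(out[[cl]]))
    )
  }
  rownames(out) <- NULL
  attr(out, "rejected_lines") <- if (any(bad)) which(bad) + 1L else integer(0)
  out
}

#' Construct a feature matrix
#'
#' The central container of the pipeline: a numeric matrix whose rows are
#' drug-by-cell-line responses and whose named columns are features, plus
#' per-column metadata recording the feature level (`drug`, `residue`,
#' `motif`, `domain`, `gene`, `family`, `pathway`, `sample`, `interaction`)
#' and, for interaction columns, the two component features. Residue-level
#' columns are a tagged subset of the cell-line features, so the
#' drug-by-mutation candidate set is recoverable from the metadata alone.
#'
#' @param values Numeric matrix; rownames are response keys, colnames are
#'   unique feature names; no missing values.
#' @param meta Data frame with columns `feature`, `level`, and optionally
#'   `component_a`/`component_b` (NA for non-interaction columns), one row
#'   per column of `values` in the same order.
#' @return An object of class `qsmart_features`.
#' @export
feature_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("feature columns must be uniquely named", call. = FALSE)
  if (anyNA(values)) stop("feature matrix contains missing values",
                          call. = FALSE)
  if (!all(c("feature", "level") %in% names(meta)))
    stop("meta must have 'feature' and 'level' columns", call. = FALSE)
  if (is.null(meta$component_a)) meta$component_a <- NA_character_
  if (is.null(meta$component_b)) meta$component_b <- NA_character_
  meta <- meta[c("feature", "level", "component_a", "component_b")]
  if (!identical(meta$feature, colnames(values)))
    stop("meta rows must match matrix columns in order", call. = FALSE)
  inter <- meta$level == "interaction"
  comps <- c(meta$component_a[inter], meta$component_b[inter])
  if (length(comps) && !all(comps %in% meta$feature))
    stop("interaction component(s) absent from column metadata: ",
         paste(setdiff(comps, meta$feature), collapse = ", "), call. = FALSE)
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "qsmart_features")
}

#' @export
print.qsmart_features <- function(x, ...) {
  lv <- table(x$meta$level)
  cat(sprintf("<qsmart_features> %d responses x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(names(lv), lv, sep = ":", collapse = ", ")))
  invisible(x)
}

# subset columns, keeping metadata aligned; interaction components of kept
# columns are retained too so the container invariant holds
subset_features <- function(fm, keep) {
  stopifnot(inherits(fm, "qsmart_features"))
  keep <- unique(keep)
  inter <- fm$meta$feature %in% keep & fm$meta$level == "interaction"
  keep <- unique(c(keep, fm$meta$component_a[inter],
                   fm$meta$component_b[inter]))
  idx <- fm$meta$feature %in% keep
  feature_matrix(fm$values[, fm$meta$feature[idx], drop = FALSE],
                 fm$meta[idx, , drop = FALSE])
}

#' Write / read a feature matrix
#'
#' `write_feature_matrix()` serializes the values as a TSV (first column
#' `response_id`, full double precision) and the column metadata as a
#' sidecar `<path>.meta.tsv`; `read_feature_matrix()` reverses it. The
#' round trip is exact: every value survives bit-for-bit via `%.17g`
#' formatting.
#'
#' @param fm A [feature_matrix()].
#' @param path Output TSV path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a `qsmart_features`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "qsmart_features"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("response_id", colnames(fm$values)), collapse = "\t"),
             con)
  if (nrow(fm$values) > 0) {
    body <- apply(fm$values, 1, function(r)
      paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(paste(rownames(fm$values), body, sep = "\t"), con)
  }
  meta_path <- paste0(path, ".meta.tsv")
  utils::write.table(fm$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  meta <- utils::read.delim(paste0(path, ".meta.tsv"),
                            colClasses = "character", na.strings = "")
  vals <- as.matrix(as.data.frame(lapply(df[-1], as.numeric),
                                  check.names = FALSE, optional = TRUE))
  if (nrow(df) == 0L)
    vals <- matrix(numeric(0), 0, ncol(df) - 1L,
                   dimnames = list(NULL, names(df)[-1]))
  rownames(vals) <- df[[1]]
  colnames(vals) <- names(df)[-1]
  feature_matrix(vals, meta)
}
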