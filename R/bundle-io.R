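# Directory serialization of input bundles: one CSV per table, plain text
# throughout, so simulated screens can be inspected, edited, and re-run
# from the command line.

#' Write / read an input bundle directory
#'
#' `write_bundle()` writes each table of a bundle as a CSV (matrices with a
#' leading `cell_line_id` column), the kinase list as a text file, and the
#' ground truth (if present) as JSON. `read_bundle()` reverses it, running
#' each table through its schema validator.
#'
#' @param bundle A `qsmart_bundle` (see [simulate_bundle()]).
#' @param dir Directory path (created if missing).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()`
#'   returns a `qsmart_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, quote = FALSE)
  wr(bundle$responses[c("drug_id", "cell_line_id", "log_ic50",
                        "source_flag")], "responses")
  wr(bundle$drugs, "drugs")
  wr(bundle$cells, "cells")
  wr(bundle$mutations, "mutations")
  wr(bundle$annotations, "annotations")
  wr(bundle$hierarchy, "hierarchy")
  wr(bundle$ppi, "ppi")
  for (nm in c("expression", "cnv")) {
    m <- bundle[[nm]]
    if (is.null(m)) next
    wr(data.frame(cell_line_id = rownames(m), m, check.names = FALSE),
       nm)
  }
  writeLines(bundle$kinases, file.path(dir, "kinases.txt"))
  if (!is.null(bundle$ground_truth))
    jsonlite::write_json(bundle$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  sch <- qsmart_schemas()
  fp <- function(name) file.path(dir, paste0(name, ".csv"))
  read_mat <- function(name) {
    if (!file.exists(fp(name))) return(NULL)
    df <- utils::read.csv(fp(name), check.names = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- df[[1]]
    m
  }
  drugs <- utils::read.csv(fp("drugs"), check.names = FALSE)
  cells <- utils::read.csv(fp("cells"), check.names = FALSE,
                           colClasses = "character")
  cells$wgs_flag <- as.integer(cells$wgs_flag)
  cells$has_expression <- as.integer(cells$has_expression)
  gt <- if (file.exists(file.path(dir, "ground_truth.json")))
    jsonlite::read_json(file.path(dir, "ground_truth.json"),
                        simplifyVector = TRUE) else NULL
  structure(list(
    responses = read_table(fp("responses"), sch$responses),
    drugs = drugs, cells = cells,
    mutations = read_table(fp("mutations"), sch$mutations),
    expression = read_mat("expression"), cnv = read_mat("cnv"),
    annotations = read_table(fp("annotations"), sch$annotations),
    hierarchy = read_table(fp("hierarchy"), sch$hierarchy),
    ppi = read_table(fp("ppi"), sch$ppi),
    kinases = readLines(file.path(dir, "kinases.txt")),
    ground_truth = gt
  ), class = "qsmart_bundle")
}
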