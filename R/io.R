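# Plain-text I/O: expression/design TSV, GMT annotation maps.

#' Write and read a gene-by-sample expression matrix as TSV
#'
#' Genes are rows (first column `gene`), samples are columns.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output/input TSV path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns the matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write and read a sample design table as TSV
#'
#' @param design Sample design data.frame (see [gonad_design()]).
#' @param path Output/input TSV path.
#' @return `write_design_tsv()` returns `path` invisibly;
#'   `read_design_tsv()` the data.frame.
#' @export
write_design_tsv <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write and read a term-to-gene annotation map in GMT format
#'
#' GMT: one term per line, tab-separated — term id, description, member
#' genes. Reading is delegated to [fgsea::gmtPathways()].
#'
#' @param annotation Named list term -> gene-id vector.
#' @param path GMT file path.
#' @return `write_gmt()` returns `path` invisibly; `read_gmt()` the named
#'   list.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(names(annotation), function(term) {
    paste(c(term, term, annotation[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
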