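# Read QC: the bespoke post-trimming filter (N-containing reads and reads
# with an excess of low-quality positions), TPM conversion, the per-group
# sequencing summary table, and the expressed-gene filter.

#' Read a FASTQ file into a read table
#'
#' Thin wrapper over [Biostrings::readQualityScaledDNAStringSet()]
#' (Phred+33, gzip-transparent).
#'
#' @param path FASTQ file, optionally gzipped.
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # the reader warns about dropping (empty) metadata columns on coercion
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality` (Phred+33).
#' @param path Output file; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  # the constructor warns about dropping (empty) metadata columns
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(reads$quality)
  ))
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

# integer Phred scores of one Phred+33 quality string
.phred_scores <- function(quality) utf8ToInt(quality) - 33L

#' Filter reads containing undetermined bases or excess low-quality positions
#'
#' A read is removed if it contains at least one `N`, or — for N-free reads —
#' if strictly more than `max_lowq_positions` of its positions have Phred
#' quality below `quality_threshold`. A read with exactly
#' `max_lowq_positions` sub-threshold positions is kept. The N rule is
#' applied first, so the two removal counts partition the removed reads.
#' Input order of kept reads is preserved.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33), as from [read_fastq()] or [simulate_fastq()].
#' @param max_lowq_positions Maximum tolerated number of low-quality
#'   positions (default 10).
#' @param quality_threshold Phred score below which a position counts as
#'   low-quality (default 20).
#' @return List with `kept` (the surviving reads, original columns),
#'   `n_removed_N`, and `n_removed_lowq`.
#' @export
#' @examples
#' reads <- simulate_fastq(100, 50, frac_with_N = 0.1, seed = 7)
#' filter_reads(reads)$n_removed_N
filter_reads <- function(reads, max_lowq_positions = 10L,
                         quality_threshold = 20L) {
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len))
    stop("sequence/quality length mismatch for read(s): ",
         paste(reads$read_id[bad_len], collapse = ", "), call. = FALSE)

  has_N <- grepl("N", reads$sequence, fixed = TRUE)
  n_lowq <- vapply(reads$quality,
                   function(q) sum(.phred_scores(q) < quality_threshold),
                   integer(1), USE.NAMES = FALSE)
  lowq <- !has_N & n_lowq > max_lowq_positions
  list(kept = reads[!has_N & !lowq, , drop = FALSE],
       n_removed_N = sum(has_N),
       n_removed_lowq = sum(lowq))
}

# round half away from zero, as printed summary tables conventionally do
# (base round() rounds half to even)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize per-group sequencing read counts
#'
#' Aggregates per-group raw/clean/high-quality read counts into a summary
#' table with an `All` row of exact integer totals. Percentages are
#' clean/raw and hq/clean, rounded half-up to 2 decimals.
#'
#' @param records data.frame with columns `group`, `raw_reads`,
#'   `clean_reads`, `hq_reads` (one row per sample group).
#' @return data.frame with the input rows plus a final `All` row, and
#'   derived `clean_pct`, `hq_pct` columns.
#' @export
summarize_qc <- function(records) {
  req <- c("group", "raw_reads", "clean_reads", "hq_reads")
  stopifnot(all(req %in% names(records)))
  with(records, {
    if (any(raw_reads < 0 | clean_reads < 0 | hq_reads < 0))
      stop("read counts must be non-negative", call. = FALSE)
    bad <- hq_reads > clean_reads | clean_reads > raw_reads
    if (any(bad))
      stop("hq <= clean <= raw violated for group(s): ",
           paste(group[bad], collapse = ", "), call. = FALSE)
  })
  out <- records[, req]
  out <- rbind(out, data.frame(group = "All",
                               raw_reads = sum(records$raw_reads),
                               clean_reads = sum(records$clean_reads),
                               hq_reads = sum(records$hq_reads)))
  out$clean_pct <- round_half_up(100 * out$clean_reads / out$raw_reads)
  out$hq_pct <- round_half_up(100 * out$hq_reads / out$clean_reads)
  out
}

#' Per-group read counts of the M. lateralis gonadal RNA-seq study
#'
#' The published per-group raw, clean (post adapter-trimming) and
#' high-quality (post N/low-quality filtering) read counts for the 40
#' gonadal libraries (NCBI BioProject PRJNA862073): 10 groups, 35-60 dpf,
#' testis (`_T`) and ovary (`_O`) from 45 dpf on.
#'
#' @return data.frame with columns `group`, `n_replicates`, `raw_reads`,
#'   `clean_reads`, `hq_reads`.
#' @export
surfclam_read_counts <- function() {
  path <- system.file("extdata", "surfclam_read_counts.tsv",
                      package = "gonadnet", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Convert raw counts to transcripts per million (TPM)
#'
#' Per sample, each gene's count is divided by its length in bp to give a
#' read rate, and rates are scaled to sum to 1e6.
#'
#' @param counts Non-negative gene-by-sample count matrix with rownames.
#' @param gene_lengths Positive gene lengths in bp, named by gene or in row
#'   order.
#' @return Gene-by-sample TPM matrix; every column sums to 1e6.
#' @export
#' @examples
#' counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' counts_to_tpm(counts, c(a = 1000, b = 2000))
counts_to_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    if (!all(rownames(counts) %in% names(gene_lengths)))
      stop("gene_lengths missing for some genes", call. = FALSE)
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths must match the number of genes", call. = FALSE)
  if (any(gene_lengths <= 0))
    stop("gene lengths must be > 0", call. = FALSE)

  rate <- counts / gene_lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero))
    stop("TPM undefined for all-zero sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  tpm <- sweep(rate, 2L, tot / 1e6, "/")
  attr(tpm, "unit") <- "TPM"
  tpm
}

#' Keep genes expressed in at least one sample group
#'
#' A gene is retained when its mean TPM within at least one design group
#' reaches `min_mean_tpm`.
#'
#' @param expr Gene-by-sample TPM matrix.
#' @param design Sample design covering all columns of `expr` (needs
#'   `sample_id` and `group`).
#' @param min_mean_tpm Group-mean TPM threshold (default 1).
#' @return The filtered matrix; the number of genes kept is reported via
#'   `message()`.
#' @export
filter_expressed_genes <- function(expr, design, min_mean_tpm = 1) {
  stopifnot(all(colnames(expr) %in% design$sample_id))
  grp <- design$group[match(colnames(expr), design$sample_id)]
  keep <- rep(FALSE, nrow(expr))
  for (g in unique(grp)) {
    keep <- keep | rowMeans(expr[, grp == g, drop = FALSE]) >= min_mean_tpm
  }
  if (!any(keep)) warning("no genes pass the expression filter")
  message(sum(keep), " of ", nrow(expr), " genes expressed in at least one group")
  expr[keep, , drop = FALSE]
}
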