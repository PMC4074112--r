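#' Read and write pipeline files
#'
#' Thin wrappers around the standard readers: reads are FASTA
#' ([Biostrings::readDNAStringSet()]), tables are plain TSV.
#'
#' @param path File path.
#' @return `read_reads_fasta` a named `DNAStringSet`; `read_blast_hits` a
#'   hit data.frame (query_id, gi, taxonomy, pct_identity, evalue, aln_len);
#'   `read_ecm_list` a character vector (one genus per line).
#' @name motupipe-io
NULL

#' @rdname motupipe-io
#' @export
read_reads_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname motupipe-io
#' @param reads Named character vector or `DNAStringSet`.
#' @export
write_reads_fasta <- function(reads, path) {
  if (!methods::is(reads, "XStringSet"))
    reads <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(reads, path)
  invisible(path)
}

#' @rdname motupipe-io
#' @export
read_blast_hits <- function(path) {
  h <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "gi", "taxonomy", "pct_identity", "evalue")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("read_blast_hits: missing column(s): ",
                         paste(miss, collapse = ", "))
  h
}

#' @rdname motupipe-io
#' @param x A data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname motupipe-io
#' @export
read_ecm_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
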