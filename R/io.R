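#' FASTA and FASTQ input/output
#'
#' Thin wrappers around Biostrings readers/writers bridging to the plain
#' data.frame form used throughout the package.
#'
#' @param seqs named character vector of sequences.
#' @param path file path (`.gz` accepted by the readers).
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33 string).
#' @return `read_fasta`: named character vector; `read_fastq`: data.frame;
#'   the writers return `path` invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname write_fasta
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tab-separated table input/output
#'
#' @param x data.frame.
#' @param path file path.
#' @return `read_tsv_table`: data.frame; the writer returns `path`
#'   invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
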