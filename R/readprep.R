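#' Trimming and pair-filter parameters
#'
#' @param q_min minimum Phred quality retained at read ends (bases below it
#'   are stripped from both ends until the first/last base passes).
#' @param min_len pairs containing a read shorter than this are eliminated
#'   (boundary inclusive: a 36-nt read survives at the default).
#' @param adapter 3' adapter; the longest read suffix exactly equal to an
#'   adapter prefix (at least `min_overlap` bases) is removed first.
#' @param min_overlap minimum adapter overlap considered.
#' @return object of class `tg_pair_filter_params`.
#' @export
pair_filter_params <- function(q_min = 16L, min_len = 36L,
                               adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                               min_overlap = 5L) {
  if (q_min < 0L) stop("q_min must be >= 0")
  if (min_len < 1L) stop("min_len must be >= 1")
  structure(list(q_min = as.integer(q_min), min_len = as.integer(min_len),
                 adapter = adapter, min_overlap = as.integer(min_overlap)),
            class = "tg_pair_filter_params")
}

#' Trim a single read
#'
#' Adapter removal first (longest exact 3' suffix matching an adapter
#' prefix), then low-quality bases are stripped from both ends until the
#' terminal bases meet `q_min`. Interior bases are never touched; the result
#' may be empty. The operation is idempotent and always returns a contiguous
#' substring of the input.
#'
#' @param read list with `id`, `sequence` and `qualities` (integer Phred
#'   vector of the same length).
#' @param params a [pair_filter_params()].
#' @return the trimmed read in the same form.
#' @export
trim_read <- function(read, params = pair_filter_params()) {
  stopifnot(nchar(read$sequence) == length(read$qualities))
  res <- .cpp_trim_reads(read$sequence, intToUtf8(read$qualities + 33L),
                         params$adapter, params$q_min, params$min_overlap)
  qual <- if (nchar(res$qual[1])) utf8ToInt(res$qual[1]) - 33L else integer(0)
  list(id = read$id, sequence = res$seq[1], qualities = qual)
}

#' Trim a stream of reads
#'
#' Vectorized [trim_read()] over a data.frame with Phred+33 quality strings.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param params a [pair_filter_params()].
#' @return the trimmed data.frame.
#' @export
trim_reads <- function(reads, params = pair_filter_params()) {
  res <- .cpp_trim_reads(reads$seq, reads$qual, params$adapter,
                         params$q_min, params$min_overlap)
  data.frame(id = reads$id, seq = as.character(res$seq),
             qual = as.character(res$qual), stringsAsFactors = FALSE)
}

#' Filter trimmed pairs on minimum mate length
#'
#' A pair is kept iff both mates are at least `min_len` bases long.
#'
#' @param read1,read2 trimmed mate data.frames (`id`, `seq`, `qual`),
#'   parallel to each other.
#' @param params a [pair_filter_params()].
#' @return list with surviving `read1`, `read2` and a `stats` row
#'   (`input`, `kept`, `dropped` pair counts).
#' @export
filter_pairs <- function(read1, read2, params = pair_filter_params()) {
  if (nrow(read1) != nrow(read2)) stop("mismatched mate stream lengths")
  keep <- nchar(read1$seq) >= params$min_len & nchar(read2$seq) >= params$min_len
  list(read1 = read1[keep, , drop = FALSE],
       read2 = read2[keep, , drop = FALSE],
       stats = data.frame(input = nrow(read1), kept = sum(keep),
                          dropped = sum(!keep)))
}

#' Trim both mates and filter pairs in one step
#'
#' @param reads a `tg_read_set` (or list with `read1`/`read2` data.frames).
#' @param params a [pair_filter_params()].
#' @return as [filter_pairs()].
#' @export
prep_pairs <- function(reads, params = pair_filter_params()) {
  filter_pairs(trim_reads(reads$read1, params),
               trim_reads(reads$read2, params), params)
}
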