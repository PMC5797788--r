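#' Build a k-mer seed index over a reference set
#'
#' Every k-mer of every contig is indexed with its positions. The index is
#' held in native memory and is rebuilt cheaply per session; it cannot be
#' serialized.
#'
#' @param refs a `tg_reference_set`, or a named character vector of contig
#'   sequences.
#' @param k k-mer size (<= 31, and no larger than the shortest contig).
#' @return object of class `tg_seed_index`.
#' @export
build_index <- function(refs, k = 21L) {
  seqs <- if (inherits(refs, "tg_reference_set")) refs$seqs else refs
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("contigs must be named")
  if (k > min(nchar(seqs)))
    stop("k exceeds the shortest contig length")
  ptr <- .cpp_build_index(names(seqs), unname(seqs), as.integer(k))
  structure(list(ptr = ptr, names = names(seqs), k = as.integer(k),
                 seqs = seqs), class = "tg_seed_index")
}

#' Map reads with the ungapped seed-and-extend aligner
#'
#' Seeds (k-mers sampled along the read and its reverse complement) propose
#' candidate diagonals; each is scored by its maximum-scoring contiguous
#' segment (match +1, mismatch -4, no gaps), i.e. an exact ungapped local
#' alignment, so any score-reducing terminal segment is soft-clipped. The
#' best-scoring placement is reported; ties across placements collapse the
#' mapping quality to 0 (unique placements get 60).
#'
#' @param index a [build_index()] result.
#' @param reads data.frame with `id` and `seq` (and optionally `qual`).
#' @param stride distance between successive seed k-mers along the read.
#' @param mate mate index recorded in the output (1 or 2).
#' @return alignment data.frame: `qname`, `mate`, `contig`, `pos` (1-based
#'   leftmost mapped base), `strand`, `cigar` over `{S, M}` relative to the
#'   stored orientation, `mapq` (0/60), `nm`, `score`, `seq` (mapped
#'   orientation), clip decomposition columns, and `mapped`.
#' @export
map_reads <- function(index, reads, stride = 11L, mate = 1L) {
  hits <- .cpp_map_reads(index$ptr, reads$seq, as.integer(stride))
  cig <- parse_cigar(hits$cigar)
  data.frame(qname = reads$id, mate = as.integer(mate),
             contig = index$names[hits$contig], pos = hits$pos,
             strand = hits$strand, cigar = hits$cigar,
             mapq = ifelse(hits$n_best == 1L, 60L, 0L),
             nm = hits$nm, score = hits$score, n_best = hits$n_best,
             seq = hits$seq,
             left_clip = cig$left_clip, m_len = cig$m_len,
             right_clip = cig$right_clip,
             mapped = !is.na(hits$contig), stringsAsFactors = FALSE)
}

#' Map read pairs
#'
#' Maps both mates and flags proper pairs: mates on the same contig, on
#' opposite strands, in forward/reverse orientation, with an implied
#' fragment span within `insert_mean + 4 * insert_sd`.
#'
#' @param index a [build_index()] result.
#' @param read1,read2 mate data.frames (`id`, `seq`).
#' @param params a [read_sim_params()] supplying the insert-size prior.
#' @param stride seed stride, see [map_reads()].
#' @return alignment data.frame for both mates with a `proper` flag.
#' @export
map_read_pairs <- function(index, read1, read2, params = read_sim_params(),
                           stride = 11L) {
  a1 <- map_reads(index, read1, stride, mate = 1L)
  a2 <- map_reads(index, read2, stride, mate = 2L)
  span_max <- params$insert_mean + 4 * params$insert_sd
  same <- !is.na(a1$contig) & !is.na(a2$contig) & a1$contig == a2$contig
  opp <- same & a1$strand != a2$strand
  lo <- pmin(a1$pos, a2$pos)
  hi <- pmax(a1$pos + a1$m_len - 1L, a2$pos + a2$m_len - 1L)
  proper <- opp & (hi - lo + 1L) <= span_max
  proper[is.na(proper)] <- FALSE
  a1$proper <- proper
  a2$proper <- proper
  rbind(a1, a2)
}

#' Map one read pair
#'
#' @param r1,r2 mate sequences (character scalars).
#' @param index a [build_index()] result.
#' @param params a [read_sim_params()].
#' @return two-row alignment data.frame, see [map_read_pairs()].
#' @export
map_pair <- function(r1, r2, index, params = read_sim_params()) {
  map_read_pairs(index,
                 data.frame(id = "pair", seq = r1, stringsAsFactors = FALSE),
                 data.frame(id = "pair", seq = r2, stringsAsFactors = FALSE),
                 params)
}

#' Write alignments as SAM text
#'
#' Minimal valid SAM: `@HD`/`@SQ` header over the reference contigs,
#' standard flag bits (paired, proper, strand, mate number), CIGAR, MAPQ and
#' `NM` tag. Mate fields are filled for records sharing a `qname`.
#'
#' @param aln alignment data.frame from [map_read_pairs()].
#' @param refs the `tg_reference_set` (for `@SQ` lines).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", refs$contigs$name, refs$contigs$length))
  o <- order(aln$qname, aln$mate)
  a <- aln[o, ]
  # mate lookup: records are qname-paired after ordering
  n <- nrow(a)
  flag <- integer(n)
  rnext <- rep("*", n); pnext <- integer(n)
  for (i in seq_len(n)) {
    f <- 1L  # paired
    if (isTRUE(a$proper[i])) f <- f + 2L
    if (!a$mapped[i]) f <- f + 4L
    j <- if (i %% 2L == 1L) i + 1L else i - 1L
    has_mate <- j >= 1L && j <= n && a$qname[j] == a$qname[i]
    if (has_mate && !a$mapped[j]) f <- f + 8L
    if (a$mapped[i] && a$strand[i] == "-") f <- f + 16L
    if (has_mate && a$mapped[j] && a$strand[j] == "-") f <- f + 32L
    f <- f + if (a$mate[i] == 1L) 64L else 128L
    flag[i] <- f
    if (has_mate && a$mapped[j]) {
      rnext[i] <- if (!is.na(a$contig[i]) && a$contig[j] == a$contig[i]) "="
                  else a$contig[j]
      pnext[i] <- a$pos[j]
    }
  }
  seq_out <- ifelse(is.na(a$seq), "*", a$seq)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d",
                   a$qname, flag,
                   ifelse(a$mapped, a$contig, "*"),
                   ifelse(a$mapped, a$pos, 0L), ifelse(a$mapped, a$mapq, 0L),
                   ifelse(a$mapped, a$cigar, "*"), rnext, pnext, 0L,
                   seq_out, "*",
                   ifelse(a$mapped, a$nm, 0L))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read SAM text into the internal alignment form
#'
#' Accepts alignments produced by [write_sam()] or by an external aligner
#' (SAM text, single-run `M` CIGARs with optional soft clips; hard clips,
#' indels and supplementary records are not modelled).
#'
#' @param path SAM file.
#' @return alignment data.frame as from [map_read_pairs()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 0L)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("NM:i:", "", tag[1])) else NA_integer_
  }, 0L)
  contig <- vapply(f, `[`, "", 3)
  cigar <- vapply(f, `[`, "", 6)
  mapped <- bitwAnd(flag, 4L) == 0L
  cig <- parse_cigar(ifelse(mapped, cigar, NA_character_))
  data.frame(
    qname = vapply(f, `[`, "", 1),
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    contig = ifelse(mapped, contig, NA_character_),
    pos = ifelse(mapped, vapply(f, function(x) as.integer(x[4]), 0L), NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    NA_character_),
    cigar = ifelse(mapped, cigar, NA_character_),
    mapq = vapply(f, function(x) as.integer(x[5]), 0L),
    nm = nm, score = NA_integer_,
    n_best = ifelse(vapply(f, function(x) as.integer(x[5]), 0L) > 0L, 1L, 2L),
    seq = vapply(f, `[`, "", 10),
    left_clip = cig$left_clip, m_len = cig$m_len, right_clip = cig$right_clip,
    mapped = mapped,
    proper = bitwAnd(flag, 2L) > 0L,
    stringsAsFactors = FALSE)
}
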