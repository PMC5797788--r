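# Independent alignment oracle: exhaustive gap-free Smith-Waterman via
# Biostrings::pairwiseAlignment (local, match +1 / mismatch -4, gaps
# disabled by a prohibitive opening penalty) over every contig and strand.
sw_oracle <- function(read, refs) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = TRUE)
  best <- NULL
  for (ct in names(refs)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else revcomp(read)
      pa <- Biostrings::pairwiseAlignment(q, refs[[ct]], type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 1e6)
      sc <- Biostrings::score(pa)
      if (is.null(best) || sc > best$score)
        best <- list(score = sc, contig = ct, strand = strand,
                     pos = Biostrings::start(Biostrings::subject(pa)),
                     qstart = Biostrings::start(Biostrings::pattern(pa)),
                     qend = Biostrings::end(Biostrings::pattern(pa)))
    }
  }
  best
}

# A 150-mer drawn from the references with a few substitutions; 30% are
# chimeric (junction-like) and half are reverse-complemented.
random_oracle_read <- function(refs) {
  ct <- sample(names(refs), 1)
  L <- nchar(refs[[ct]])
  p <- sample(L - 149, 1)
  r <- substr(refs[[ct]], p, p + 149)
  for (e in seq_len(sample(0:3, 1))) {
    i <- sample(150, 1)
    substr(r, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(r, i, i)), 1)
  }
  if (runif(1) < 0.3) {
    ct2 <- sample(names(refs), 1)
    p2 <- sample(nchar(refs[[ct2]]) - 200, 1)
    k <- sample(40:110, 1)
    r <- paste0(substr(r, 1, k), substr(refs[[ct2]], p2, p2 + 149 - k - 1))
  }
  if (runif(1) < 0.5) r <- revcomp(r)
  r
}
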