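test_that("index construction respects the k-mer counting bound", {
  refs <- c(A = paste(rep("ACGT", 100), collapse = ""))
  expect_silent(build_index(refs, k = 8))
  expect_error(build_index(c(A = "ACGTAC"), k = 21), "k exceeds")
})

test_that("error-free reads from unique sequence map full length in place", {
  run <- small_run()
  refs <- run$refs
  idx <- build_index(refs)
  set.seed(5)
  for (i in 1:20) {
    ct <- sample(refs$contigs$name, 1)
    p <- sample(nchar(refs$seqs[[ct]]) - 149, 1)
    r <- substr(refs$seqs[[ct]], p, p + 149)
    m <- map_reads(idx, data.frame(id = "r", seq = r))
    expect_true(m$mapped)
    expect_equal(m$cigar, "150M")
    expect_equal(m$nm, 0L)
    # reads inside the duplicated ORF block are ambiguous (either homolog
    # may be reported); all others are unique and map in place
    otg <- refs$loci$arc_orf_tg; o15 <- refs$loci$arc_orf_chr15
    in_dup <- (ct == "transgene" && p >= otg$start && p + 149 <= otg$end) ||
      (ct == "chr15" && p >= o15$start && p + 149 <= o15$end)
    if (in_dup) {
      expect_equal(m$mapq, 0L)
      homolog_pos <- if (ct == "transgene") p - otg$start + o15$start
                     else p - o15$start + otg$start
      expect_true((m$contig == ct && m$pos == p) ||
                    (m$contig %in% c("chr15", "transgene") &&
                       m$pos == homolog_pos))
    } else {
      expect_equal(m$mapq, 60L)
      expect_equal(m$contig, ct)
      expect_equal(m$pos, p)
    }
  }
})

test_that("reads wholly inside the Arc ORF block tie across both homologs", {
  refs <- small_run()$refs
  idx <- build_index(refs)
  o15 <- refs$loci$arc_orf_chr15
  r <- substr(refs$seqs[["chr15"]], o15$start + 100, o15$start + 249)
  m <- map_reads(idx, data.frame(id = "r", seq = r))
  expect_equal(m$mapq, 0L)
  expect_gte(m$n_best, 2L)
})

test_that("a junction read soft-clips at the homology tract on chr12", {
  sc <- small_scenario()
  refs <- small_run()$refs
  chr12 <- refs$seqs[["chr12"]]
  tg <- refs$seqs[["transgene"]]
  L <- global_to_local(refs, "chr12", sc$left_bp)
  read <- paste0(substr(chr12, L - 59, L), substr(tg, 1, 90))
  # restricted to the chromosome, the best placement aligns the 60 flank
  # bases plus up to h_left = 4 homology bases, clipping the rest
  idx12 <- build_index(refs$seqs["chr12"])
  m <- map_reads(idx12, data.frame(id = "jr", seq = read))
  expect_equal(m$pos, L - 59)
  expect_gte(m$m_len, 60L)
  expect_lte(m$m_len, 64L)
  expect_equal(m$left_clip, 0L)
  expect_equal(m$m_len + m$right_clip, 150L)
  o <- sw_oracle(read, refs$seqs["chr12"])
  expect_equal(m$m_len, o$qend - o$qstart + 1L)
  # genome-wide, the transgene side wins (90 > 64 matches)
  idx <- build_index(refs)
  mg <- map_reads(idx, data.frame(id = "jr", seq = read))
  expect_equal(mg$contig, "transgene")
})

test_that("reported placements match the exhaustive Smith-Waterman scan", {
  set.seed(77)
  refA <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  refB <- paste(sample(c("A", "C", "G", "T"), 2500, TRUE), collapse = "")
  refs <- c(A = refA, B = refB)
  idx <- build_index(refs)
  for (i in 1:120) {
    r <- random_oracle_read(refs)
    m <- map_reads(idx, data.frame(id = "r", seq = r))
    o <- sw_oracle(r, refs)
    expect_true(m$mapped)
    expect_equal(m$contig, o$contig)
    expect_equal(m$pos, o$pos)
    expect_equal(m$left_clip, o$qstart - 1L)
    expect_equal(m$left_clip + m$m_len, o$qend)
    expect_equal(m$score, o$score)
  }
})

test_that("soft-clip and M lengths always sum to the read length", {
  run <- small_run()
  a <- run$aln[run$aln$mapped, ]
  expect_true(all(a$left_clip + a$m_len + a$right_clip == nchar(a$seq)))
})

test_that("proper-pair flags respect orientation and insert size", {
  run <- small_run()
  a <- run$aln
  prop1 <- a[a$mate == 1L & a$proper, ]
  prop2 <- a[a$mate == 2L & a$proper, ]
  m <- match(prop1$qname, prop2$qname)
  expect_true(all(prop1$contig == prop2$contig[m]))
  expect_true(all(prop1$strand != prop2$strand[m]))
  expect_gt(mean(a$proper), 0.9)
})

test_that("SAM round trip preserves the alignment fields", {
  run <- small_run()
  a <- head(run$aln[order(run$aln$qname, run$aln$mate), ], 200)
  f <- tempfile(fileext = ".sam")
  write_sam(a, run$refs, f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "@SQ")))
  b <- read_sam(f)
  b <- b[order(b$qname, b$mate), ]
  a <- a[order(a$qname, a$mate), ]
  for (col in c("qname", "contig", "pos", "strand", "cigar", "nm", "seq"))
    expect_equal(b[[col]], a[[col]], ignore_attr = TRUE)
})

test_that("reads shorter than k come back unmapped", {
  idx <- build_index(small_run()$refs)
  m <- map_reads(idx, data.frame(id = "tiny", seq = "ACGTACGTACGT"))
  expect_false(m$mapped)
})
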