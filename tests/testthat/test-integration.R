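test_that("informative-pair extraction applies the transgene-or-Arc criterion", {
  run <- small_run()
  aln <- run$aln; refs <- run$refs
  pairs <- extract_informative_pairs(aln, refs)
  arc <- refs$loci$arc_locus
  hits <- pairs$mapped & (pairs$contig == "transgene" |
    (pairs$contig == arc$contig & pairs$pos <= arc$end &
       pairs$pos + pairs$m_len - 1L >= arc$start))
  # every retained pair has at least one qualifying mate
  ok_by_pair <- tapply(hits, pairs$qname, any)
  expect_true(all(ok_by_pair))
  # no qualifying pair was lost
  sel <- aln$mapped & (aln$contig == "transgene" |
    (aln$contig == arc$contig & aln$pos <= arc$end &
       aln$pos + aln$m_len - 1L >= arc$start))
  expect_setequal(unique(pairs$qname), unique(aln$qname[sel]))
  # pairs confined to the control window are excluded
  expect_false(any(tapply(pairs$contig == "chr6", pairs$qname, all)))
})

test_that("candidate region brackets the insertion and honors the padding", {
  run <- small_run()
  pairs <- extract_informative_pairs(run$aln, run$refs)
  reg <- locate_candidate_region(pairs, run$refs)
  expect_identical(reg$status, "candidate")
  expect_identical(reg$contig, "chr12")
  expect_equal(reg$end - reg$start + 1L, 8000L)
  expect_true(reg$global_start <= 78138000 && 78138000 <= reg$global_end)
})

test_that("wildtype input yields no candidate and a clean no-call", {
  run <- sim_and_map(small_scenario(zygosity = "wt"), seed = 42)
  pairs <- extract_informative_pairs(run$aln, run$refs)
  reg <- locate_candidate_region(pairs, run$refs)
  expect_identical(reg$status, "no_candidate")
  call <- call_integration(run$aln, run$refs)
  expect_identical(call$status, "no_call")
})

test_that("the homozygous deletion appears as a zero-depth run of the expected size", {
  run <- small_run()
  pairs <- extract_informative_pairs(run$aln, run$refs)
  reg <- locate_candidate_region(pairs, run$refs)
  gap <- detect_coverage_gap(run$aln, reg, run$refs)
  # junction reads cover the homology bases, so the zero-depth run is the
  # deletion minus h_left + h_right = 1808 - 9 = 1799 bp
  expect_lte(abs(gap$length - 1799L), 6L)
  expect_equal(gap$gap_mean_depth, 0)
  expect_gt(gap$flank_median, 5)
})

test_that("depth-drop mode flags the deleted interval in a hemizygote", {
  run <- sim_and_map(small_scenario(zygosity = "hemizygous"), seed = 13)
  pairs <- extract_informative_pairs(run$aln, run$refs)
  reg <- locate_candidate_region(pairs, run$refs)
  expect_error(detect_coverage_gap(run$aln, reg, run$refs,
                                   mode = "homozygous"),
               "no qualifying")
  gap <- detect_coverage_gap(run$aln, reg, run$refs, mode = "depth_drop")
  sc <- small_scenario()
  dl <- global_to_local(run$refs, "chr12", sc$left_bp)
  dr <- global_to_local(run$refs, "chr12", sc$right_bp)
  expect_true(gap$start < dr && gap$end > dl)  # overlaps the deletion
})

test_that("breakpoints resolve to single-base accuracy with 4/5-bp homology", {
  run <- small_run()
  call <- call_integration(run$aln, run$refs)
  expect_identical(call$status, "call")
  expect_equal(call$left_bp, 78137441)
  expect_equal(call$right_bp, 78139250)
  expect_equal(call$h_left, 4L)
  expect_equal(call$h_right, 5L)
  expect_equal(call$deletion_length, 1808L)
  expect_identical(call$orientation, "+")
  expect_identical(call$zygosity, "homozygous")
  # convention consistency: left_bp + h_left = left clip consensus (local),
  # right_bp - h_right = right clip consensus
  expect_equal(global_to_local(run$refs, "chr12", call$left_bp) + call$h_left,
               unname(call$clip_consensus["left"]))
  expect_equal(global_to_local(run$refs, "chr12", call$right_bp) - call$h_right,
               unname(call$clip_consensus["right"]))
})

test_that("zero planted homology reduces the convention to the raw clips", {
  run <- sim_and_map(small_scenario(h_left = 0L, h_right = 0L), seed = 19)
  call <- call_integration(run$aln, run$refs)
  expect_identical(call$status, "call")
  expect_equal(call$h_left, 0L)
  expect_equal(call$h_right, 0L)
  expect_equal(global_to_local(run$refs, "chr12", call$left_bp),
               unname(call$clip_consensus["left"]))
  expect_equal(call$left_bp, 78137441)
  expect_equal(call$right_bp, 78139250)
})

test_that("a reverse-orientation array is called with orientation '-'", {
  run <- sim_and_map(small_scenario(orientation = "-"), seed = 23)
  call <- call_integration(run$aln, run$refs)
  expect_identical(call$status, "call")
  expect_identical(call$orientation, "-")
  expect_equal(call$left_bp, 78137441)
  expect_equal(call$right_bp, 78139250)
  expect_equal(call$h_left, 4L)
  expect_equal(call$h_right, 5L)
})

test_that("thin coverage flags the call as low confidence", {
  run <- sim_and_map(small_scenario(), seed = 29, coverage = 2)
  call <- call_integration(run$aln, run$refs)
  if (identical(call$status, "call")) {
    expect_true(call$low_confidence || all(call$support >= 2))
  } else {
    succeed("2x coverage can legitimately yield no junction evidence")
  }
})

test_that("the deletion-length identity holds on every call", {
  for (s in c(7, 19, 23)) {
    run <- if (s == 7) small_run() else sim_and_map(small_scenario(), seed = s)
    call <- call_integration(run$aln, run$refs)
    expect_identical(call$status, "call")
    expect_equal(call$deletion_length, call$right_bp - call$left_bp - 1L)
  }
})

test_that("secondary-site scan is empty by default and finds a spiked site", {
  run <- small_run()
  call <- call_integration(run$aln, run$refs)
  expect_equal(nrow(call$secondary_sites), 0L)

  refs <- run$refs
  al2 <- build_transgenic_allele(refs,
                                 secondary_insertion = list(contig = "chr6",
                                                            pos = 20000L))
  reads <- simulate_read_pairs(al2, read_sim_params(coverage = 13.5 / 2),
                               seed = 31)
  pp <- prep_pairs(reads)
  aln2 <- map_read_pairs(build_index(refs), pp$read1, pp$read2)
  call2 <- call_integration(aln2, refs)
  expect_identical(call2$status, "call")
  expect_equal(call2$left_bp, 78137441)
  expect_equal(nrow(call2$secondary_sites), 1L)
  expect_identical(call2$secondary_sites$contig, "chr6")
  expect_lte(abs(call2$secondary_sites$start - 20000L), 600L)
})

test_that("in-silico PCR distinguishes wildtype and junction primer sets", {
  run <- small_run()
  refs <- run$refs
  chr12 <- refs$seqs[["chr12"]]
  tg <- refs$seqs[["transgene"]]
  sc <- small_scenario()
  L <- global_to_local(refs, "chr12", sc$left_bp)
  R <- global_to_local(refs, "chr12", sc$right_bp)
  hap_tg <- run$allele$haplotypes[["chr12_h1"]]

  fwd_wt <- substr(chr12, L - 300, L - 274)
  rev_wt <- revcomp(substr(chr12, R + 274, R + 300))
  # the wildtype set spans the deleted interval: product on the wildtype
  # chromosome only (the transgenic allele pushes the primers ~35 kb apart)
  expect_equal(insilico_pcr(chr12, fwd_wt, rev_wt),
               (R + 300) - (L - 300) + 1L)
  expect_length(insilico_pcr(hap_tg, fwd_wt, rev_wt), 0)

  # junction set: one primer in the flank, one inside the transgene
  rev_j <- revcomp(substr(tg, 400, 426))
  expect_length(insilico_pcr(chr12, fwd_wt, rev_j), 0)
  expect_equal(insilico_pcr(hap_tg, fwd_wt, rev_j), 300L + 426L + 1L)

  # swapped primer orientation finds the same product
  expect_equal(insilico_pcr(hap_tg, rev_j, fwd_wt), 300L + 426L + 1L)
  expect_length(insilico_pcr(chr12, "GGGGGGGGGGGGGGGGGGGG", fwd_wt), 0)
  expect_error(insilico_pcr(chr12, "", fwd_wt), "non-empty")
})
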