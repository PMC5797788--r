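test_that("reference set has the stated geometry and planted homology", {
  sc <- integration_scenario()
  refs <- build_reference_set(sc, seed = 3)

  expect_equal(nchar(refs$seqs[["transgene"]]), 11829L)
  expect_true(all(grepl("^[ACGT]+$", unlist(refs$seqs))))
  # ORF block is an exact copy of the chr15 segment inside the Arc locus
  o15 <- refs$loci$arc_orf_chr15; otg <- refs$loci$arc_orf_tg
  expect_identical(substr(refs$seqs[["chr15"]], o15$start, o15$end),
                   substr(refs$seqs[["transgene"]], otg$start, otg$end))
  # planted microhomology: transgene prefix/suffix equal the chr12 bases
  # flanking the breakpoints, and are maximal (the next base differs)
  chr12 <- refs$seqs[["chr12"]]
  tg <- refs$seqs[["transgene"]]
  L <- global_to_local(refs, "chr12", sc$left_bp)
  R <- global_to_local(refs, "chr12", sc$right_bp)
  expect_identical(substr(tg, 1, 4), substr(chr12, L + 1, L + 4))
  expect_false(substr(tg, 5, 5) == substr(chr12, L + 5, L + 5))
  expect_identical(substr(tg, 11829 - 4, 11829), substr(chr12, R - 5, R - 1))
  expect_false(substr(tg, 11829 - 5, 11829 - 5) ==
                 substr(chr12, R - 6, R - 6))
})

test_that("disabling homology removes the forced junction identity", {
  sc <- integration_scenario(h_left = 0L, h_right = 0L)
  refs <- build_reference_set(sc, seed = 5)
  chr12 <- refs$seqs[["chr12"]]; tg <- refs$seqs[["transgene"]]
  L <- global_to_local(refs, "chr12", sc$left_bp)
  expect_false(substr(tg, 1, 1) == substr(chr12, L + 1, L + 1))
  expect_false(substr(tg, 1, 1) == substr(chr12, L, L))
})

test_that("reference generation is deterministic in the seed", {
  r1 <- build_reference_set(seed = 11)
  r2 <- build_reference_set(seed = 11)
  r3 <- build_reference_set(seed = 12)
  expect_identical(r1$seqs, r2$seqs)
  expect_false(identical(r1$seqs, r3$seqs))
})

test_that("transgenic allele length follows the window/deletion/copy identity", {
  for (C in c(1L, 15L)) {
    for (zyg in c("homozygous", "hemizygous", "wt")) {
      sc <- integration_scenario(copies = C, zygosity = zyg)
      refs <- build_reference_set(sc, seed = 2)
      al <- build_transgenic_allele(refs)
      exp_len <- 80000L - 1808L + C * 11829L
      expect_equal(al$tg_allele_length, exp_len)
      h1 <- nchar(al$haplotypes[["chr12_h1"]])
      h2 <- nchar(al$haplotypes[["chr12_h2"]])
      if (zyg == "homozygous") expect_equal(c(h1, h2), rep(exp_len, 2))
      if (zyg == "hemizygous") expect_equal(c(h1, h2), c(exp_len, 80000L))
      if (zyg == "wt") {
        expect_identical(al$haplotypes[["chr12_h1"]], refs$seqs[["chr12"]])
        expect_identical(al$haplotypes[["chr12_h2"]], refs$seqs[["chr12"]])
      }
    }
  }
  # the defaults reproduce the worked sizes
  refs <- build_reference_set(integration_scenario(), seed = 2)
  expect_equal(nchar(build_transgenic_allele(refs)$haplotypes[["chr12_h1"]]),
               255627L)
})

test_that("read simulation matches its sampling model", {
  refs <- build_reference_set(small_scenario(), seed = 4)
  al <- build_transgenic_allele(refs)
  params <- read_sim_params(coverage = 4)
  rs <- simulate_read_pairs(al, params, seed = 21)
  lens <- nchar(al$haplotypes)
  expected_pairs <- 4 * sum(lens) / (2 * 150)
  expect_lt(abs(nrow(rs$read1) - expected_pairs) / expected_pairs, 0.05)

  # error-free reads are exact (reverse-complemented) substrings of their
  # source haplotype
  p0 <- read_sim_params(coverage = 0.5, q_max = 41, q_drop = 0, q_sd = 0)
  rs0 <- simulate_read_pairs(al, p0, seed = 22)
  # q = 41 still implies error rate 10^-4.1; verify against the truth table
  frag <- substring(al$haplotypes[rs0$truth$hap], rs0$truth$start,
                    rs0$truth$end)
  long <- rs0$truth$frag_len >= 150
  expect_true(mean(substr(frag[long], 1, 150) == rs0$read1$seq[long]) > 0.95)
  r2rc <- revcomp(rs0$read2$seq[long])
  expect_true(mean(vapply(which(long), function(i) {
    f <- frag[i]
    substr(f, nchar(f) - 149, nchar(f)) ==
      revcomp(rs0$read2$seq[i])
  }, TRUE)) > 0.95)
})

test_that("short fragments read through into the adapter at both 3' ends", {
  refs <- build_reference_set(small_scenario(), seed = 4)
  al <- build_transgenic_allele(refs)
  params <- read_sim_params(coverage = 0.3, insert_mean = 120, insert_sd = 0,
                            q_max = 41, q_drop = 0, q_sd = 0)
  rs <- simulate_read_pairs(al, params, seed = 23)
  ad30 <- substr(params$adapter, 1, 30)
  match1 <- substr(rs$read1$seq, 121, 150) == ad30
  match2 <- substr(rs$read2$seq, 121, 150) == ad30
  # sequencing errors may touch a few adapter copies
  expect_true(mean(match1) > 0.9)
  expect_true(mean(match2) > 0.9)
})

test_that("read simulation is byte-deterministic in the seed", {
  refs <- build_reference_set(small_scenario(), seed = 4)
  al <- build_transgenic_allele(refs)
  p <- read_sim_params(coverage = 1)
  a <- simulate_read_pairs(al, p, seed = 31)
  b <- simulate_read_pairs(al, p, seed = 31)
  expect_identical(a$read1, b$read1)
  expect_identical(a$read2, b$read2)
  expect_identical(a$truth, b$truth)
})

test_that("qPCR plate follows the dilution model", {
  # noiseless wildtype: equal copy number, equal Ct
  spec <- qpcr_plate_spec(noise_sd = 0, copies = 15L)
  ct <- simulate_qpcr_plate(spec, seed = 1)
  wt <- ct[ct$genotype == "wt", ]
  expect_equal(wt$ct[wt$target == "ArcORF"], wt$ct[wt$target == "control"])
  # homozygous, C = 15, E = 2: dCt = log2(32/2) = 4
  homo <- ct[ct$genotype == "homozygous", ]
  expect_equal(unique(homo$ct[homo$target == "control"] -
                        homo$ct[homo$target == "ArcORF"]), 4)
  # noiseless replicates are identical
  expect_equal(length(unique(homo$ct[homo$target == "ArcORF"])), 1L)
  expect_error(qpcr_plate_spec(efficiency = 1), "efficiency")
})

test_that("decay series follows first-order kinetics", {
  s0 <- decay_series_spec(times = c(0, 30, 60), t_half = 30,
                          log_noise_sd = 0, replicates = 1L)
  d <- simulate_decay_series(s0, seed = 1)
  expect_equal(d$fraction[d$time == 0], 1.0)
  expect_equal(d$fraction[d$time == 30], 0.5)
  s1 <- decay_series_spec(times = 60, t_half = 45, log_noise_sd = 0,
                          replicates = 1L)
  expect_equal(simulate_decay_series(s1, seed = 1)$fraction, 2^(-4 / 3))
  expect_error(decay_series_spec(t_half = -1), "t_half")
})

test_that("FISH stack geometry, ground truth and decay-region construction", {
  # density zero -> background-only truth
  sp0 <- fish_image_spec(field_um = 51.2, um_per_px = 0.4, bands = NULL,
                         uniform_density = 0)
  st0 <- render_fish_stack(sp0, seed = 1)
  expect_equal(nrow(st0$truth$puncta), 0L)
  expect_equal(dim(st0$stack), c(128, 128, 4))

  # noiseless decay region: ratio is exactly the planted fraction
  spf <- fish_actd_spec(fraction = 0.75, shot_noise = FALSE,
                        read_noise_sd = 0)
  stf <- render_fish_stack(spf, seed = 2)
  expect_equal(region_remaining_fraction(max_project(stf)), 75,
               tolerance = 1e-10)
  expect_error(fish_actd_spec(fraction = 1.5), "fraction")
})
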