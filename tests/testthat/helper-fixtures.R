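# Desk-scale fixtures shared across test files. The "small" scenario keeps
# the printed breakpoint coordinates but shrinks the chr12 window and copy
# count so module tests stay fast; the default scenario is exercised in the
# acceptance tests.

small_scenario <- function(...) {
  integration_scenario(chr12_start = 78130001L, chr12_len = 20000L,
                       copies = 3L, control_len = 40000L,
                       control_locus_len = 30000L, ...)
}

# run simulation + readprep + mapping for a scenario; cache the default
# small homozygous run since several files inspect it
sim_and_map <- function(scenario, seed = 1L, coverage = 13.5) {
  refs <- build_reference_set(scenario, seed = derive2(seed, 1))
  allele <- build_transgenic_allele(refs)
  params <- read_sim_params(coverage = coverage / 2)
  reads <- simulate_read_pairs(allele, params, seed = derive2(seed, 2))
  pp <- prep_pairs(reads)
  aln <- map_read_pairs(build_index(refs), pp$read1, pp$read2,
                        read_sim_params(coverage = coverage))
  list(refs = refs, allele = allele, reads = reads, prepped = pp, aln = aln)
}

derive2 <- function(seed, i) (seed * 1000L + i) %% 2100000000L

.small_cache <- new.env()
small_run <- function() {
  if (is.null(.small_cache$run))
    .small_cache$run <- sim_and_map(small_scenario(), seed = 7L)
  .small_cache$run
}
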