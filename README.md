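# tgsite

Locating a multi-copy transgene's genomic integration site from paired-end
whole-genome sequencing, and quantifying mRNA expression and decay from
fluorescence in-situ hybridization (FISH) images.

`tgsite` is written for the common situation in transgenic-mouse work where
a construct — here an *EGFP-Arc* fusion driven by the *Arc* 7-kb promoter —
has integrated somewhere in the genome as a tandem multi-copy array, and
one needs to know *where*, *how many copies*, and *what the transgenic
mRNA's decay kinetics look like*. Because the raw animal data behind such a
study are rarely portable, the package ships first-class synthetic-data
generators that emulate the study design with known ground truth, so every
analysis step is testable end to end.

## What the package computes

**Genomics arm.** Reads are adapter- and quality-trimmed (q < 16 stripped
from both ends; pairs with a mate shorter than 36 nt eliminated), mapped
with a compact ungapped seed-and-extend aligner (or any external aligner
via SAM), and the integration site is recovered in the stages a structural
variant caller would use:

1. *Informative pairs* — pairs with a mate on the transgene or in the
   endogenous *Arc* locus (Chr15:74,669,000–74,682,000) are extracted; the
   transgene carries an exact copy of the *Arc* ORF, so multi-mapping
   ambiguity is deliberately kept.
2. *Candidate region* — their off-locus counterpart mates are clustered
   and padded to an 8-kb candidate region.
3. *Coverage gap* — a homozygous deletion appears as a zero-depth run; a
   depth-drop mode handles hemizygotes.
4. *Split-read breakpoints* — soft-clipped reads at the gap edges give a
   clip consensus per side; clipped sequences are matched to the transgene
   termini, and the junction microhomology `h` is the maximal shared
   fragment between the transgene terminus and the adjacent reference
   bases. With homology attributed to the transgene, `left_bp` = left clip
   consensus − `h_left` and `right_bp` = right clip consensus + `h_right`,
   so `deletion = right_bp − left_bp − 1` is exact.
5. *Copy number* — total ORF dosage per diploid genome is estimated by
   read depth, `2 · Σ(mean ORF-homolog depth) / mean(control depth)`, and
   by qPCR emulation, `2 · E^{ΔΔCt}` with
   `ΔCt = Ct(control) − Ct(ORF)`; copies per locus are
   `(total − 2) / n_loci`.
6. *Confirmation* — in-silico PCR over wildtype and junction primer sets,
   plus a genome-wide scan for secondary integration sites.

**Imaging/kinetics arm.** Maximum-intensity projection of 4-slice z-stacks
(0.55 µm spacing), puncta counting by the classic rescale–invert–threshold
–particle-count recipe, laminar line profiles (10-µm sampling, ~10 averaged
parallel placements, middle-molecular-layer anchoring), remaining-signal
ratios in a circular transcription-blockade region (damaged core excluded),
and half-life estimation by zero-intercept least squares on
`ln f = −(ln 2 / t½) · t`.

## Worked example

The default scenario plants the characterized locus — breakpoints at
Chr12:78,137,441 and 78,139,250 (an 1,808-bp deletion), 4- and 5-bp
junction microhomologies, 15 tandem copies, homozygous — and sequences it
at 13.5× with 150-bp paired-end reads:

```r
library(tgsite)
bundle <- run_locus_pipeline(seed = 1)
print(bundle)
#> Locus-discovery report (seed 1)
#> Transgene integration call
#>   chr12:78,137,441-78,139,250  (deletion 1,808 bp)
#>   microhomology 4 / 5 bp, orientation '+', homozygous
#>   junction support: left 2, right 8; secondary sites: 0
#> Copy-number estimate (depth): total 32.50 ORF copies/diploid genome
#>   homozygous: 15.25 copies per locus (rounds to 15)
#> Copy-number estimate (qpcr): total 31.67 ORF copies/diploid genome
#>   homozygous: 14.84 copies per locus (rounds to 15)
#>   between-sample sd: 0.36
#>   pairs: 16003 simulated, 16003 kept after trimming/filtering
```

The caller has recovered the planted breakpoints at single-base
resolution, the deletion length, the microhomologies, and ~15 copies per
locus from both estimators. The decay arm:

```r
obs <- simulate_decay_series(decay_series_spec(log_noise_sd = 0), seed = 1)
fit_half_life(obs)
#> Exponential decay fit (zero intercept)
#>   t1/2 = 45 min (SE 5.95e-16), n = 12
```

`write_reports(bundle, "out/")` writes TSV/JSON reports with full seed and
configuration provenance.

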