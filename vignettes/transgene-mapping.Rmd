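---
title: "Methods: transgene integration-site discovery and FISH decay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transgene integration-site discovery and FISH decay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgsite)
```

# The problem

A transgenic mouse line carries an *EGFP-Arc* construct (11,829 bp: *Arc*
7-kb promoter, 5'UTR, EGFP fused to the *Arc* ORF, 3'UTR) integrated as a
tandem array at an unknown genomic position. Integration of such arrays
typically deletes a stretch of the host chromosome and leaves short
*microhomologies* — sequence shared between the construct terminus and the
chromosomal flank — that make the exact junction ambiguous within a few
bases. The analysis recovers, from ~13.5x paired-end whole-genome
sequencing, the integration chromosome and single-base breakpoints, the
size of the co-occurring deletion, the per-junction microhomology lengths,
and the number of tandem copies; a second arm quantifies mRNA abundance
and decay from FISH images after actinomycin-D (Act-D) transcription
block.

Because this package is exercised entirely on synthetic data, every
quantity it recovers has a known planted truth, and the test suite is a
parameter-recovery study rather than a comparison against animals.

# The synthetic genome

Chromosome-scale coordinates are preserved without chromosome-scale
simulation by modelling three windows with global offsets:

* **chr12**, 80 kb (78,100,001–78,180,000), carrying the insertion locus;
* **chr15**, 20 kb, containing the endogenous *Arc* locus
  (74,669,000–74,682,000) and, inside it, the 1,200-bp ORF segment that is
  copied *verbatim* into the transgene — this reproduces the real
  multi-mapping ambiguity that motivates extracting pairs by "transgene OR
  *Arc* locus";
* a **control** window, 80 kb of unique sequence whose central 60 kb serve
  as the 2-copy depth-normalization locus. The control window matches the
  chr12 window in size so that the mild coverage depletion simulated at
  window edges cancels in the depth ratio; a short control window would
  bias the copy-number estimate upward by a percent or two and, with a
  short normalization interval, dominate its sampling noise.

Transgene component lengths (promoter 7,000; 5'UTR 200; EGFP marker 750;
ORF 1,200; 3'UTR the remaining 2,679) are conventional placeholders; only
the 11,829 total and the ORF identity with chr15 matter downstream.

**Homology planting.** For the default (+) orientation the first
`h_left = 4` bases of the transgene are set equal to the chr12 bases
immediately after `left_bp`, and the last `h_right = 5` bases to those
immediately before `right_bp`. Two further constraints make the planted
homology *exactly* maximal rather than a lower bound: the next transgene
base is forced to differ from the continuing chr12 base (so alignment
extension stops at the homology edge), and a small repair loop mutates any
retained-flank base that would let the maximal-shared-fragment computation
exceed the planted length. Without the repair, roughly one scenario in a
few hundred would plant h = 4 but present h = 5 to a correct caller.

**Library model.** Fragments are Normal(350, 50) bp (a typical PCR-free
prep; configurable), floored at 30 bp; 150-bp mates are read from both
ends, reading through into the adapter when the fragment is shorter than
the read. Per-base Phred qualities follow a gently decaying profile
(37 to 30 across the read) and substitution errors are drawn at
`10^(-q/10)` per base. Indel errors are not modelled — the soft-clip logic
this package needs is exercised by junction-spanning reads, not by indels
— and this is a known limitation for transfer to real data. `coverage` is
the haploid-reference-equivalent depth; the pipeline sequences the diploid
haplotype pool at `coverage / 2` per haplotype so that reference-projected
depth equals the nominal 13.5x.

# The caller

**Mapping.** The built-in aligner indexes 21-mers and scores each
candidate diagonal by its maximum-scoring contiguous segment (match +1,
mismatch −4, no gaps) — an exact ungapped local alignment. Any
score-reducing terminal segment is therefore soft-clipped, whatever its
length; zero-sum prefixes are retained, mirroring a Smith–Waterman
traceback, which is what makes the aligner provably equivalent to the
gap-free `pairwiseAlignment` oracle in the test suite. (An earlier design
clipped only terminal segments of at least 8 bases; pure local-alignment
semantics are simpler, match the oracle exactly, and keep absorbed
junction tails out of the coverage gap.) Mapping quality is collapsed to
the only distinction downstream logic uses: 60 for a unique best
placement, 0 for ties, with the tie itself reported. Gapped alignment is
out of scope because the generator plants no indels; with real data an
external aligner can substitute — the caller consumes SAM.

**Candidate region.** Counterpart mates of informative pairs are
clustered (positions closer than 2 kb merge); clusters are ranked by
support and padded symmetrically to 8 kb. Mates within 1 kb of the *Arc*
locus are ignored as ordinary insert-size proximity — on a desk-scale
window the locus edge would otherwise masquerade as a cluster, an
artifact a chromosome-scale analysis would not see. The caller walks the
ranked clusters until one yields both a coverage gap and junction
evidence, so a secondary insertion without a deletion cannot hijack the
primary call.

**Coverage gap.** In homozygous mode the gap is the longest run of
zero-depth positions (>= 500 bp). Junction reads align across the planted
homology, so the zero-depth run is the deletion minus
`h_left + h_right` — 1,799 bp at the defaults — and the gap edges sit
exactly at the clip consensus positions. In depth-drop mode (hemizygotes)
the raw depth is first smoothed with an 801-bp running mean, and the
threshold is 0.75 of the region median — the midpoint between the
hemizygous (0.5x) and diploid (1.0x) hypotheses. Read-scale
autocorrelation makes raw depth far too noisy for a fractional threshold:
with ~6.75x in the deleted interval the smoothed profile still wanders by
more than one depth unit, which is why the window is long and the
threshold central. Smoothed gap edges are only accurate to a few hundred
bases, so breakpoint search widens accordingly.

**Breakpoints and microhomology.** Soft-clipped reads (clip >= 8 bp)
whose clip position falls near a gap edge vote for a per-side consensus
(ties: more reads, then leftmost). The microhomology is computed from the
reference and the transgene alone — `h` is the maximal k such that the k
bases of the transgene terminus equal the k reference bases adjacent to
the consensus clip — and clipped sequences are then required to match the
corresponding transgene terminus within one mismatch (both orientations
are tried; the one supported by more reads is reported). Homology bases
are attributed to the transgene: `left_bp` = left clip consensus −
`h_left`, `right_bp` = right clip consensus + `h_right`. This is the one
convention under which the printed coordinates (78,137,441 / 78,139,250)
and the printed deletion (1,808 bp) satisfy
`deletion = right − left − 1` simultaneously. The 4-bp and 5-bp
homologies are assigned to the left and right junctions in genomic order.
Sides with fewer than 2 junction reads flag the call low-confidence but do
not suppress it.

**Zygosity.** Homozygous when mean in-gap depth is below 0.1 of the
flanking median, else heterozygous.

**Secondary sites.** Transgene-anchored mates outside the known loci are
clustered; clusters of >= 3 distinct pairs are reported. The default
scenario reports none; a transgene copy spiked into the control window is
reported as exactly one site in the tests.

# Copy number

The read-depth estimator sums the *mean M-base depths* of the ORF-bearing
homolog intervals (transgene ORF block and chr15 ORF) and normalizes by
the control-locus mean: `total = 2 · Σ(mean depth) / control`. Summing
per-homolog means — rather than averaging over the pooled length — counts
every ORF-derived read once no matter where the aligner placed its
multi-mapping reads, and yields 2 + 2C for a homozygote by construction.
mapq-0 alignments are deliberately included; dropping them would deflate
the estimate to near zero. Copies per locus are `(total − 2) / n_loci`
(one transgenic locus if hemizygous, two if homozygous).

At 13.5x the 1,200-bp ORF collects only ~850 fragments, so the per-locus
estimate carries an irreducible sampling sd of roughly half a copy; the
tests therefore check integer rounding at the default run and a <= 1-copy
bias across C in {1, 5, 15, 30}, not exactness per seed.

The qPCR emulation follows the standard ΔΔCt model with efficiency E = 2,
baseline Ct 22, triplicate wells with 0.05-cycle replicate noise (a
well-run SYBR assay), and a 4 wildtype / 4 hemizygous / 8 homozygous
panel mirroring a genotyping cohort. The estimator averages per-sample
`2 · E^{ΔΔCt}` over the genotype of interest against the wildtype
calibrator mean.

# Imaging and kinetics

The 63x puncta field is a 204.8-µm square (the reported "total area of
204.8 µm²" is dimensionally inconsistent for a 63x field; it is read as a
side length) at 0.2 µm/px, four slices 0.55 µm apart. Laminar bands (GCL
60, IML 40, MML 60, OML 44.8 µm) carry puncta at 0.005–0.03 µm⁻²,
rendered as 2-D Gaussians (PSF sigma 0.25 µm) weighted across slices by an
axial Gaussian (sigma 0.6 µm), over band-specific backgrounds with Poisson
shot noise and mean-zero Gaussian read noise.

Puncta counting reproduces the rescale → 8-bit → invert → threshold →
particle-count recipe. The original procedure adjusted the threshold by
eye per image; here it is a fixed parameter whose automatic default is the
robust background (median) plus four robust standard deviations
(MAD-based, floored at one gray level so a noise-free image is not
degenerate), reported in the output because it replaces a manual step.
Components of fewer than 4 pixels are discarded; connectivity is
8-connected. Two puncta closer than about twice the PSF sigma merge and
count once — documented behavior, checked in the tests. Inversion is
retained for fidelity although counting is performed on the bright side
of the same threshold.

Line profiles sample bilinearly every 10 µm along ~10 parallel placements
10 µm apart and average them; positions can be anchored so the middle
molecular layer sits at 150 µm (300-µm lines) or 125 µm (250-µm lines),
aligning cases with different cell-layer widths.

The Act-D blockade image is a single wide-field 20x-style frame (819.2 µm
at 0.8 µm/px): a uniform labeling field, a 400-µm-diameter region (within
the reported 300–500 µm) whose signal is scaled by the remaining fraction
f before noise, and a 150-µm damaged core excluded from measurement. A
single slice matters: max-projecting independent Poisson noise across
slices inflates low-signal regions relative to high-signal ones and would
bias the ratio upward by about a point. The measured quantity is
`100 · mean(region ∖ core) / mean(outside)`, unbiased for `100 f` under
the noise model. The transgenic 60-min default plants
`f = 2^{-60/144.57} = 0.75`, the fraction implied by the reported ~75%
remaining at 60 min; the corresponding half-life constant is derived from
that identity, alongside 45 min for the culture scenario and 30 min for
the wildtype in-vivo scenario.

Half-life fitting is zero-intercept least squares of `ln f` on `t`:
`t½ = −ln 2 · Σt² / Σ(t · ln f)`, with a delta-method standard error and
an optional free-intercept `lm` fit for diagnostics. Forcing the curve
through (0, 1) matches data normalized to an unblocked reference;
fractions above 1 are retained, not clipped, to avoid downward bias.
Degenerate inputs (no time > 0, all fractions >= 1, non-positive
fractions) raise immediate errors rather than returning a number.

# Problem sizes and determinism

The default pipeline simulates ~16,000 read pairs (two 255,627-bp
transgenic chr12 haplotypes plus the chr15 and control windows at 13.5x)
and completes in well under a minute on one core; module tests use a
20-kb chr12 window with 3 copies. The test suite repeats the full default
run over 20 seeds for recovery, 20 wildtype seeds as negative control,
and 500 random reads against the gap-free Smith–Waterman oracle. Every
generator accepts a seed and is byte-deterministic given it; the pipeline
fans per-stage seeds out from one top-level seed, and report bundles
carry the seed and a configuration hash so a bundle reproduces itself.

# Limitations

* No indel sequencing errors, optical duplicates, GC bias or chimeric
  artifacts; passing tests show correctness of the method's logic, not
  robustness to every real-library pathology.
* Tandem copies are counted, never structurally resolved — internal array
  junctions are invisible to 150-bp reads by design.
* The aligner is ungapped and desk-scale; at real scale an external
  aligner should produce the SAM input.
* Puncta counting has no cell segmentation and no declumping; merged
  puncta undercount at high density.
* Group comparisons (ANOVA and friends) are out of scope; the package
  emits per-group summaries only.
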