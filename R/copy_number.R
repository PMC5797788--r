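#' Read-depth transgene copy-number estimate
#'
#' Total Arc-ORF copies per diploid genome are estimated as
#' `2 * (sum of mean M-base depths over the ORF-bearing homolog intervals) /
#' (mean depth over the unique control locus)`. Summing the homolog
#' intervals (the transgene's ORF block and the endogenous chr15 ORF)
#' counts every ORF-derived read once regardless of where the aligner
#' placed its multi-mapping (mapq 0) reads, which are deliberately
#' included — excluding them would deflate the estimate. Copies per locus
#' follow from zygosity: `(total - 2) / n_loci` with one transgenic locus
#' when hemizygous and two when homozygous.
#'
#' @param aln alignment data.frame.
#' @param refs the `tg_reference_set` (supplies the default intervals).
#' @param zygosity `"homozygous"`, `"hemizygous"` or `"wt"`.
#' @param orf_intervals list of list(`contig`, `start`, `end`) ORF homolog
#'   intervals; defaults to the transgene and chr15 ORF blocks.
#' @param control_interval the normalizer interval; defaults to the control
#'   locus.
#' @return object of class `tg_copy_estimate`.
#' @export
depth_copy_number <- function(aln, refs,
                              zygosity = c("homozygous", "hemizygous", "wt"),
                              orf_intervals = NULL, control_interval = NULL) {
  zygosity <- match.arg(zygosity)
  if (is.null(orf_intervals))
    orf_intervals <- list(refs$loci$arc_orf_tg, refs$loci$arc_orf_chr15)
  if (is.null(control_interval)) control_interval <- refs$loci$control
  mean_depth <- function(iv) {
    recs <- aln[aln$mapped & aln$contig == iv$contig, , drop = FALSE]
    mean(.cpp_depth(recs$pos, recs$m_len, iv$start, iv$end))
  }
  orf_sum <- sum(vapply(orf_intervals, mean_depth, 0))
  ctrl <- mean_depth(control_interval)
  if (ctrl <= 0) stop("zero depth over the control interval")
  total <- 2 * orf_sum / ctrl
  n_loci <- switch(zygosity, wt = 0L, hemizygous = 1L, homozygous = 2L)
  per_locus <- if (n_loci > 0L) (total - 2) / n_loci else 0
  structure(list(method = "depth", total = total, per_locus = per_locus,
                 per_locus_int = as.integer(round(per_locus)),
                 orf_depth = orf_sum, control_depth = ctrl,
                 zygosity = zygosity, dispersion = NA_real_),
            class = "tg_copy_estimate")
}

#' Delta-delta-Ct transgene copy-number estimate
#'
#' Per sample, the relative Arc-ORF quantity is `E^(ddCt)` with
#' `dCt = mean Ct(control) - mean Ct(ArcORF)` and `ddCt = dCt(sample) -
#' mean dCt(calibrator)`; total copies per diploid genome are `2 * E^(ddCt)`
#' since the wildtype calibrator carries two ORF copies. Copies per locus
#' follow from each sample's genotype.
#'
#' @param ct_table data.frame from [simulate_qpcr_plate()] (or the same
#'   shape: `sample`, `genotype`, `target` in `ArcORF`/`control`,
#'   `replicate`, `ct`).
#' @param efficiency amplification factor E per cycle, in (1, 2].
#' @param calibrator genotype label of the calibrator samples.
#' @param genotype genotype whose samples are averaged for the headline
#'   per-locus estimate; defaults to the highest-dosage transgenic genotype
#'   present.
#' @return object of class `tg_copy_estimate` with a per-sample table in
#'   `$samples`.
#' @export
qpcr_copy_number <- function(ct_table, efficiency = 2, calibrator = "wt",
                             genotype = NULL) {
  if (efficiency <= 1) stop("efficiency must exceed 1")
  need <- c("sample", "genotype", "target", "ct")
  stopifnot(all(need %in% names(ct_table)))
  samples <- unique(ct_table[, c("sample", "genotype")])
  has_both <- vapply(samples$sample, function(s) {
    tg <- ct_table$target[ct_table$sample == s]
    all(c("ArcORF", "control") %in% tg)
  }, TRUE)
  if (!all(has_both)) stop("every sample needs both ArcORF and control wells")
  if (!any(samples$genotype == calibrator)) stop("no calibrator samples")

  dct <- vapply(samples$sample, function(s) {
    d <- ct_table[ct_table$sample == s, ]
    mean(d$ct[d$target == "control"]) - mean(d$ct[d$target == "ArcORF"])
  }, 0)
  ddct <- dct - mean(dct[samples$genotype == calibrator])
  total <- 2 * efficiency^ddct
  n_loci <- c(wt = 0L, hemizygous = 1L, homozygous = 2L)[samples$genotype]
  per_locus <- ifelse(n_loci > 0L, (total - 2) / pmax(n_loci, 1L), 0)
  tab <- data.frame(sample = samples$sample, genotype = samples$genotype,
                    dct = dct, ddct = ddct, total = total,
                    n_loci = n_loci, per_locus = per_locus,
                    stringsAsFactors = FALSE)
  if (is.null(genotype)) {
    genotype <- if ("homozygous" %in% tab$genotype) "homozygous"
                else if ("hemizygous" %in% tab$genotype) "hemizygous"
                else calibrator
  }
  sel <- tab[tab$genotype == genotype, ]
  structure(list(method = "qpcr", total = mean(sel$total),
                 per_locus = mean(sel$per_locus),
                 per_locus_int = as.integer(round(mean(sel$per_locus))),
                 zygosity = genotype,
                 dispersion = if (nrow(sel) > 1) stats::sd(sel$per_locus)
                              else NA_real_,
                 samples = tab),
            class = "tg_copy_estimate")
}

#' @export
print.tg_copy_estimate <- function(x, ...) {
  cat(sprintf("Copy-number estimate (%s): total %.2f ORF copies/diploid genome\n",
              x$method, x$total))
  cat(sprintf("  %s: %.2f copies per locus (rounds to %d)\n",
              x$zygosity, x$per_locus, x$per_locus_int))
  if (!is.na(x$dispersion))
    cat(sprintf("  between-sample sd: %.2f\n", x$dispersion))
  invisible(x)
}
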