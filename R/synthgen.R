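#' Build the synthetic reference set
#'
#' Generates the desk-scale reference contigs with global coordinate
#' offsets: the chr12 window around the insertion site, the chr15 window
#' containing the endogenous Arc locus, the unique control window, and the
#' 11,829-bp transgene (7-kb promoter, 5'UTR, EGFP marker, Arc ORF, 3'UTR).
#' The Arc ORF block is an exact copy of a chr15 segment, reproducing the
#' multi-mapping ambiguity that motivates pair extraction by "transgene OR
#' Arc locus".
#'
#' Junction microhomologies are planted: under the scenario's orientation,
#' the first `h_left` bases of the (oriented) transgene equal the chr12
#' bases immediately following `left_bp`, and the last `h_right` bases equal
#' the chr12 bases immediately preceding `right_bp`. Flanking bases are
#' additionally forced unequal so that the planted homology is exactly the
#' maximal shared fragment, not a lower bound.
#'
#' @param scenario an [integration_scenario()].
#' @param seed integer seed; the same seed reproduces the set byte for byte.
#' @return object of class `tg_reference_set`: contig table with global
#'   offsets, sequences, named loci (Arc locus, ORF homologs, control locus)
#'   and the scenario.
#' @export
build_reference_set <- function(scenario = integration_scenario(), seed = 1L) {
  with_seed(seed, {
    sc <- scenario
    chr12 <- random_dna(sc$chr12_len)
    chr15 <- random_dna(sc$chr15_len)
    ctrl <- random_dna(sc$control_len)

    # transgene layout in contig coordinates
    orf_c15_start <- sc$arc_orf_start - sc$chr15_start + 1L
    orf_block <- substr(chr15, orf_c15_start, orf_c15_start + sc$orf_len - 1L)
    utr3_len <- sc$transgene_len - sc$promoter_len - sc$utr5_len -
      sc$egfp_len - sc$orf_len
    tg <- paste0(random_dna(sc$promoter_len), random_dna(sc$utr5_len),
                 random_dna(sc$egfp_len), orf_block, random_dna(utr3_len))

    # plant junction microhomology on the allele-oriented insert
    L <- sc$left_bp - sc$chr12_start + 1L   # local last retained left base
    R <- sc$right_bp - sc$chr12_start + 1L  # local first retained right base
    A <- if (sc$orientation == "+") tg else revcomp(tg)
    Alen <- nchar(A)
    hL <- sc$h_left; hR <- sc$h_right
    if (hL > 0L) A <- str_assign(A, 1L, substr(chr12, L + 1L, L + hL))
    if (hR > 0L)
      A <- str_assign(A, Alen - hR + 1L, substr(chr12, R - hR, R - 1L))
    # extension stops: first mismatch exactly one base past each homology
    b <- substr(chr12, L + hL + 1L, L + hL + 1L)
    if (substr(A, hL + 1L, hL + 1L) == b)
      A <- str_assign(A, hL + 1L, other_base(b))
    b <- substr(chr12, R - hR - 1L, R - hR - 1L)
    if (substr(A, Alen - hR, Alen - hR) == b)
      A <- str_assign(A, Alen - hR, other_base(b))
    # cap the maximal shared fragment at the planted length by repairing
    # retained-flank bases that would extend it
    repeat {
      hh <- shared_prefix_len(A, chr12, L + hL, max_h = 30L)
      if (hh <= hL) break
      p <- L + hL - hh + 1L
      chr12 <- str_assign(chr12, p, other_base(substr(A, 1L, 1L),
                                               substr(chr12, p, p)))
    }
    repeat {
      hh <- shared_suffix_len(A, chr12, R - hR, max_h = 30L)
      if (hh <= hR) break
      p <- R - hR + hh - 1L
      chr12 <- str_assign(chr12, p, other_base(substr(A, Alen, Alen),
                                               substr(chr12, p, p)))
    }
    tg <- if (sc$orientation == "+") A else revcomp(A)

    contigs <- data.frame(
      name = c("chr12", "chr15", sc$control_chrom, "transgene"),
      global_start = c(sc$chr12_start, sc$chr15_start, sc$control_start, 1L),
      length = c(sc$chr12_len, sc$chr15_len, sc$control_len, sc$transgene_len),
      stringsAsFactors = FALSE)
    seqs <- c(chr12 = chr12, chr15 = chr15, ctrl, transgene = tg)
    names(seqs)[3] <- sc$control_chrom

    orf_tg_start <- sc$promoter_len + sc$utr5_len + sc$egfp_len + 1L
    ctrl_pad <- (sc$control_len - sc$control_locus_len) %/% 2L
    loci <- list(
      arc_locus = list(contig = "chr15",
                       start = sc$arc_locus[1] - sc$chr15_start + 1L,
                       end = sc$arc_locus[2] - sc$chr15_start + 1L),
      arc_orf_chr15 = list(contig = "chr15", start = orf_c15_start,
                           end = orf_c15_start + sc$orf_len - 1L),
      arc_orf_tg = list(contig = "transgene", start = orf_tg_start,
                        end = orf_tg_start + sc$orf_len - 1L),
      control = list(contig = sc$control_chrom, start = ctrl_pad + 1L,
                     end = ctrl_pad + sc$control_locus_len))

    structure(list(contigs = contigs, seqs = seqs, transgene_name = "transgene",
                   loci = loci, scenario = sc, seed = seed),
              class = "tg_reference_set")
  })
}

# maximal k <= max_h with A[1..k] == chr[c-k+1..c]
shared_prefix_len <- function(A, chr, c, max_h = 30L) {
  h <- 0L
  for (k in seq_len(min(max_h, c))) {
    if (substr(A, 1L, k) == substr(chr, c - k + 1L, c)) h <- k
  }
  h
}

# maximal k <= max_h with A[len-k+1..len] == chr[c..c+k-1]
shared_suffix_len <- function(A, chr, c, max_h = 30L) {
  n <- nchar(A); h <- 0L
  for (k in seq_len(min(max_h, nchar(chr) - c + 1L))) {
    if (substr(A, n - k + 1L, n) == substr(chr, c, c + k - 1L)) h <- k
  }
  h
}

#' Convert local contig coordinates to global genome coordinates
#' @param refs a `tg_reference_set`.
#' @param contig contig name.
#' @param pos 1-based local position(s).
#' @return global coordinate(s).
#' @export
local_to_global <- function(refs, contig, pos) {
  off <- refs$contigs$global_start[match(contig, refs$contigs$name)]
  off + pos - 1L
}

#' @rdname local_to_global
#' @export
global_to_local <- function(refs, contig, pos) {
  off <- refs$contigs$global_start[match(contig, refs$contigs$name)]
  pos - off + 1L
}

#' @export
print.tg_reference_set <- function(x, ...) {
  cat("Synthetic reference set (", nrow(x$contigs), " contigs)\n", sep = "")
  for (i in seq_len(nrow(x$contigs)))
    cat(sprintf("  %-10s %7s bp  (global start %s)\n", x$contigs$name[i],
                format(x$contigs$length[i], big.mark = ","),
                format(x$contigs$global_start[i], big.mark = ",")))
  invisible(x)
}

#' Assemble the transgenic haplotypes
#'
#' Reconstructs the allele implied by the scenario: chr12 left flank up to
#' `left_bp`, then `copies` tandem transgene units in the scenario
#' orientation, then the right flank from `right_bp` on (the intervening
#' chr12 bases are deleted). Zygosity controls the haplotype mixture;
#' the chr15 and control windows are carried unchanged on both genome
#' copies.
#'
#' @param refs a `tg_reference_set` built from the same scenario.
#' @param scenario the scenario; defaults to the one in `refs`.
#' @param secondary_insertion optional list(`contig`, `pos`, `copies`)
#'   spiking an additional insertion (no deletion) of the transgene after
#'   local position `pos` of `contig` on one haplotype, for testing the
#'   genome-wide secondary-site scan.
#' @return object of class `tg_allele_set` with the named haplotype pool
#'   (`*_h1`, `*_h2`) and the expected transgenic-allele length.
#' @export
build_transgenic_allele <- function(refs, scenario = refs$scenario,
                                    secondary_insertion = NULL) {
  if (!identical(scenario[c("left_bp", "right_bp", "copies", "orientation")],
                 refs$scenario[c("left_bp", "right_bp", "copies", "orientation")]))
    stop("scenario does not match the one the reference set was built from")
  sc <- scenario
  chr12 <- refs$seqs[["chr12"]]
  tg <- refs$seqs[[refs$transgene_name]]
  A <- if (sc$orientation == "+") tg else revcomp(tg)
  L <- sc$left_bp - sc$chr12_start + 1L
  R <- sc$right_bp - sc$chr12_start + 1L
  tg_allele <- paste0(substr(chr12, 1L, L), strrep(A, sc$copies),
                      substr(chr12, R, nchar(chr12)))
  chr12_haps <- switch(sc$zygosity,
    wt = c(chr12, chr12),
    hemizygous = c(tg_allele, chr12),
    homozygous = c(tg_allele, tg_allele))
  haps <- c(chr12_h1 = chr12_haps[1], chr12_h2 = chr12_haps[2],
            chr15_h1 = refs$seqs[["chr15"]], chr15_h2 = refs$seqs[["chr15"]],
            ctrl_h1 = refs$seqs[[sc$control_chrom]],
            ctrl_h2 = refs$seqs[[sc$control_chrom]])
  if (!is.null(secondary_insertion)) {
    si <- secondary_insertion
    key <- paste0(if (si$contig == "chr12") "chr12" else
                  if (si$contig == "chr15") "chr15" else "ctrl", "_h1")
    s <- haps[[key]]
    haps[[key]] <- paste0(substr(s, 1L, si$pos),
                          strrep(A, if (is.null(si$copies)) 1L else si$copies),
                          substr(s, si$pos + 1L, nchar(s)))
  }
  expected_len <- sc$chr12_len - deletion_length(sc$left_bp, sc$right_bp) +
    sc$copies * sc$transgene_len
  structure(list(haplotypes = haps, scenario = sc,
                 tg_allele_length = expected_len),
            class = "tg_allele_set")
}

#' Simulate a paired-end sequencing library
#'
#' Draws fragments uniformly from the supplied haplotype pool (sizes
#' Normal(`insert_mean`, `insert_sd`), floored at 30 bp), reads both ends
#' (mate 2 reverse-complemented), reads through into the adapter when the
#' fragment is shorter than the read, assigns Phred qualities from the
#' profile and injects substitution errors with per-base probability
#' `10^(-q/10)`. `coverage` is the expected mean depth over the pool, so the
#' fragment count is `coverage * total_length / (2 * read_len)`.
#'
#' @param haplotypes named character vector of haplotype sequences, or a
#'   `tg_allele_set`.
#' @param params a [read_sim_params()].
#' @param seed integer seed (byte-identical output for equal seeds).
#' @return object of class `tg_read_set`: `read1` and `read2` data.frames
#'   (`id`, `seq`, `qual` as Phred+33 strings) and a `truth` table of source
#'   coordinates.
#' @export
simulate_read_pairs <- function(haplotypes, params = read_sim_params(),
                                seed = 1L) {
  if (inherits(haplotypes, "tg_allele_set")) haplotypes <- haplotypes$haplotypes
  if (length(haplotypes) == 0 || any(nchar(haplotypes) == 0))
    stop("empty haplotypes")
  if (params$coverage <= 0) stop("coverage must be positive")
  with_seed(seed, {
    rl <- params$read_len
    lens <- nchar(haplotypes)
    n_frag <- round(params$coverage * sum(lens) / (2 * rl))
    hi <- sample.int(length(haplotypes), n_frag, replace = TRUE, prob = lens)
    frag <- pmax(30, round(rnorm(n_frag, params$insert_mean, params$insert_sd)))
    frag <- pmin(frag, lens[hi])
    start <- floor(runif(n_frag) * (lens[hi] - frag + 1)) + 1

    fragseq <- character(n_frag)
    for (h in seq_along(haplotypes)) {
      idx <- which(hi == h)
      if (length(idx))
        fragseq[idx] <- substring(haplotypes[[h]], start[idx],
                                  start[idx] + frag[idx] - 1)
    }
    r1 <- substr(fragseq, 1, rl)
    r2 <- revcomp(substring(fragseq, pmax(1, frag - rl + 1), frag))
    short <- which(frag < rl)
    if (length(short)) {  # 3' adapter read-through
      fill <- paste0(params$adapter, strrep("A", rl))
      r1[short] <- substr(paste0(fragseq[short], fill), 1, rl)
      r2[short] <- substr(paste0(revcomp(fragseq[short]), fill), 1, rl)
    }

    qmean <- params$q_max - params$q_drop * ((seq_len(rl) - 1) / (rl - 1))^2
    n_reads <- 2L * n_frag
    Q <- matrix(pmin(41, pmax(2, round(rnorm(n_reads * rl,
                                             mean = rep(qmean, times = n_reads),
                                             sd = params$q_sd)))),
                nrow = n_reads, byrow = TRUE)
    seqs <- c(r1, r2)
    emask <- matrix(runif(n_reads * rl) < 10^(-Q / 10), nrow = n_reads)
    for (i in which(rowSums(emask) > 0)) {
      s <- seqs[i]
      for (p in which(emask[i, ])) {
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, p, p)), 1)
      }
      seqs[i] <- s
    }
    qual <- vapply(seq_len(n_reads), function(i) intToUtf8(Q[i, ] + 33L), "")

    ids <- sprintf("frag%07d", seq_len(n_frag))
    structure(list(
      read1 = data.frame(id = ids, seq = seqs[seq_len(n_frag)],
                         qual = qual[seq_len(n_frag)], stringsAsFactors = FALSE),
      read2 = data.frame(id = ids, seq = seqs[n_frag + seq_len(n_frag)],
                         qual = qual[n_frag + seq_len(n_frag)],
                         stringsAsFactors = FALSE),
      truth = data.frame(id = ids, hap = names(haplotypes)[hi], start = start,
                         end = start + frag - 1, frag_len = frag,
                         stringsAsFactors = FALSE),
      params = params, seed = seed), class = "tg_read_set")
  })
}

#' Simulate a qPCR genotyping plate
#'
#' @param spec a [qpcr_plate_spec()].
#' @param seed integer seed.
#' @return data.frame(`sample`, `genotype`, `target` in `ArcORF`/`control`,
#'   `replicate`, `ct`).
#' @export
simulate_qpcr_plate <- function(spec = qpcr_plate_spec(), seed = 1L) {
  with_seed(seed, {
    E <- spec$efficiency
    orf_copies <- c(wt = 2, hemizygous = 2 + spec$copies,
                    homozygous = 2 + 2 * spec$copies)
    grid <- expand.grid(replicate = seq_len(spec$replicates),
                        target = c("ArcORF", "control"),
                        sample = spec$panel$sample,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$genotype <- spec$panel$genotype[match(grid$sample, spec$panel$sample)]
    copies <- ifelse(grid$target == "control", 2,
                     orf_copies[grid$genotype])
    grid$ct <- spec$baseline_ct - log(copies / 2) / log(E) +
      rnorm(nrow(grid), 0, spec$noise_sd)
    grid[, c("sample", "genotype", "target", "replicate", "ct")]
  })
}

#' Simulate a decay series
#'
#' First-order decay with multiplicative log-normal noise:
#' `fraction = 2^(-t / t_half) * exp(eps)`.
#'
#' @param spec a [decay_series_spec()].
#' @param seed integer seed.
#' @return data.frame(`time`, `replicate`, `fraction`).
#' @export
simulate_decay_series <- function(spec = decay_series_spec(), seed = 1L) {
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(spec$replicates), time = spec$times,
                        KEEP.OUT.ATTRS = FALSE)
    f <- fraction_remaining(grid$time, spec$t_half) *
      exp(rnorm(nrow(grid), 0, spec$log_noise_sd))
    data.frame(time = grid$time, replicate = grid$replicate,
               fraction = pmax(f, .Machine$double.xmin))
  })
}
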