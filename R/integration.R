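#' Extract informative read pairs
#'
#' A pair is informative when at least one mate maps to the transgene
#' contig or into the endogenous Arc locus interval. Ambiguous (mapq 0)
#' placements count — the Arc-ORF multi-mapping is exactly what makes these
#' pairs informative.
#'
#' @param aln alignment data.frame (both mates).
#' @param refs the `tg_reference_set`.
#' @return the subset of `aln` belonging to informative pairs.
#' @export
extract_informative_pairs <- function(aln, refs) {
  if (!refs$transgene_name %in% refs$contigs$name)
    stop("unknown transgene contig")
  arc <- refs$loci$arc_locus
  on_tg <- aln$mapped & aln$contig == refs$transgene_name
  on_arc <- aln$mapped & aln$contig == arc$contig &
    aln$pos <= arc$end & (aln$pos + aln$m_len - 1L) >= arc$start
  sel <- !is.na(on_tg) & (on_tg | on_arc)
  keep <- aln$qname %in% unique(aln$qname[sel])
  out <- aln[keep, , drop = FALSE]
  class(out) <- c("tg_informative_pairs", class(out))
  out
}

#' Locate the candidate integration region
#'
#' Clusters the off-locus counterpart mates of informative pairs (records
#' not on the transgene and outside the Arc locus) and pads the densest
#' cluster symmetrically to a fixed-width candidate region.
#'
#' @param pairs informative pairs from [extract_informative_pairs()].
#' @param refs the `tg_reference_set`.
#' @param cluster_window width (bp) of the sliding window used to find the
#'   densest mate cluster.
#' @param pad_to final region width (bp); the characterized locus was
#'   reported from an 8-kb region.
#' @param min_pairs minimum clustered mates required for a candidate.
#' @param locus_margin counterparts this close (bp) to the Arc locus are
#'   still "around the locus" (ordinary insert-size proximity, not
#'   integration evidence) and are excluded from clustering.
#' @return object of class `tg_candidate_region` (contig, local and global
#'   interval, support count), or a `"no_candidate"` status object for
#'   wildtype-like input.
#' @export
locate_candidate_region <- function(pairs, refs, cluster_window = 2000L,
                                    pad_to = 8000L, min_pairs = 3L,
                                    locus_margin = 1000L) {
  if (nrow(pairs) == 0) stop("empty pair set")
  arc <- refs$loci$arc_locus
  off <- pairs$mapped & pairs$contig != refs$transgene_name &
    !(pairs$contig == arc$contig & pairs$pos <= arc$end + locus_margin &
        (pairs$pos + pairs$m_len - 1L) >= arc$start - locus_margin)
  off[is.na(off)] <- FALSE
  cand <- pairs[off, , drop = FALSE]
  regions <- cluster_regions(cand, refs, cluster_window, pad_to, min_pairs)
  if (!length(regions))
    return(structure(list(status = "no_candidate"),
                     class = "tg_candidate_region"))
  regions[[1]]
}

# All counterpart clusters as padded candidate regions, ranked by support.
# Greedy: clusters are merged runs of positions closer than cluster_window.
cluster_regions <- function(cand, refs, cluster_window, pad_to, min_pairs) {
  out <- list()
  for (ct in unique(cand$contig)) {
    pos <- sort(cand$pos[cand$contig == ct] +
                  cand$m_len[cand$contig == ct] %/% 2L)
    grp <- cumsum(c(1L, as.integer(diff(pos) > cluster_window)))
    for (g in unique(grp)) {
      p <- pos[grp == g]
      if (length(p) < min_pairs) next
      center <- round(median(p))
      clen <- refs$contigs$length[match(ct, refs$contigs$name)]
      start <- center - pad_to %/% 2L + 1L
      start <- max(1L, min(start, clen - pad_to + 1L))
      out[[length(out) + 1L]] <- structure(
        list(status = "candidate", contig = ct, start = start,
             end = start + pad_to - 1L,
             global_start = local_to_global(refs, ct, start),
             global_end = local_to_global(refs, ct, start + pad_to - 1L),
             n_support = length(p)),
        class = "tg_candidate_region")
    }
  }
  out[order(-vapply(out, `[[`, 0L, "n_support"))]
}

#' Detect the deletion as a coverage gap
#'
#' Computes per-position aligned-base (M) depth over the candidate region
#' and reports the longest qualifying low-coverage run. `homozygous` mode
#' looks for depth at or below `depth_max` (zero by default); `depth_drop`
#' mode, for hemizygous loci, looks for depth below `drop_frac` of the
#' region's median depth.
#'
#' @param aln alignment data.frame.
#' @param region a `tg_candidate_region`.
#' @param refs the `tg_reference_set`.
#' @param depth_max maximum depth inside a homozygous gap.
#' @param min_len minimum gap length (bp).
#' @param mode `"homozygous"` or `"depth_drop"`.
#' @param drop_frac depth fraction threshold for `depth_drop` mode; the
#'   default 0.75 splits the hemizygous (0.5x) and diploid (1.0x) depth
#'   hypotheses symmetrically.
#' @param smooth_bp running-mean window (bp) applied to the depth profile in
#'   `depth_drop` mode before thresholding (raw depth is too noisy for a
#'   fractional threshold); gap edges are then approximate to about half
#'   this window.
#' @return object of class `tg_coverage_gap` (local and global interval,
#'   length, flank median depth, mean depth inside the gap, mode).
#' @export
detect_coverage_gap <- function(aln, region, refs, depth_max = 0L,
                                min_len = 500L,
                                mode = c("homozygous", "depth_drop"),
                                drop_frac = 0.75, smooth_bp = 801L) {
  mode <- match.arg(mode)
  if (!identical(region$status, "candidate")) stop("no candidate region")
  recs <- aln[aln$mapped & aln$contig == region$contig, , drop = FALSE]
  depth <- .cpp_depth(recs$pos, recs$m_len, region$start, region$end)
  med <- median(depth)
  low <- if (mode == "homozygous") {
    depth <= depth_max
  } else {
    cs <- cumsum(c(0, depth))
    w <- min(smooth_bp, length(depth))
    half <- w %/% 2L
    n <- length(depth)
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    sm < drop_frac * med
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_len)
  if (!length(ok)) stop("no qualifying low-coverage run in the region")
  k <- ok[which.max(r$lengths[ok])]
  gs <- region$start + starts[k] - 1L
  ge <- region$start + ends[k] - 1L
  flank_med <- median(depth[-(starts[k]:ends[k])])
  structure(list(contig = region$contig, start = gs, end = ge,
                 global_start = local_to_global(refs, region$contig, gs),
                 global_end = local_to_global(refs, region$contig, ge),
                 length = ge - gs + 1L,
                 flank_median = flank_med,
                 gap_mean_depth = mean(depth[starts[k]:ends[k]]),
                 mode = mode),
            class = "tg_coverage_gap")
}

# mismatches between equal-length strings
str_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Resolve breakpoints at single-base resolution
#'
#' Collects soft-clipped reads at the coverage-gap edges, takes the
#' clip-position consensus per side (ties broken toward the position with
#' more reads, then leftmost), matches clipped sequences against the
#' transgene termini in both orientations, and computes the junction
#' microhomology as the maximal shared fragment between the transgene
#' terminus and the reference bases adjacent to the consensus clip.
#' Homology bases are attributed to the transgene: `left_bp` = left clip
#' consensus − `h_left` (the last retained chromosomal base) and `right_bp`
#' = right clip consensus + `h_right` (the first retained base) — the
#' convention under which the breakpoint coordinates and the deletion
#' length `right_bp - left_bp - 1` are mutually consistent.
#'
#' @param aln alignment data.frame.
#' @param gap a `tg_coverage_gap`.
#' @param refs the `tg_reference_set`.
#' @param min_support junction reads required per side for a confident call.
#' @param clip_min minimum soft-clip length considered junction evidence.
#' @param search_window clip positions this far (bp) from the gap edges are
#'   considered.
#' @param max_h maximum microhomology length searched.
#' @return list with global `left_bp`, `right_bp`, `h_left`, `h_right`,
#'   `orientation`, per-side `support`, `low_confidence` flag and the
#'   junction evidence table.
#' @export
resolve_breakpoints <- function(aln, gap, refs, min_support = 2L,
                                clip_min = 8L, search_window = 30L,
                                max_h = 30L) {
  contig <- gap$contig
  chrseq <- refs$seqs[[contig]]
  tg <- refs$seqs[[refs$transgene_name]]
  recs <- aln[aln$mapped & aln$contig == contig, , drop = FALSE]

  rs <- recs[recs$right_clip >= clip_min &
               abs((recs$pos + recs$m_len - 1L) - (gap$start - 1L)) <=
                 search_window, , drop = FALSE]
  ls <- recs[recs$left_clip >= clip_min &
               abs(recs$pos - (gap$end + 1L)) <= search_window, , drop = FALSE]
  if (nrow(rs) == 0 && nrow(ls) == 0)
    stop("no soft-clipped junction evidence at the gap edges")

  consensus <- function(p) {
    if (!length(p)) return(NA_integer_)
    tab <- table(p)
    hit <- as.integer(names(tab)[tab == max(tab)])
    min(hit)
  }
  c_L <- consensus(rs$pos + rs$m_len - 1L)
  c_R <- consensus(ls$pos)

  # left clips are transgene prefixes read forward; right clips are
  # transgene suffixes whose alignment-adjacent end is the clip's 3' end
  eval_left <- function(A) {
    if (is.na(c_L)) return(list(h = NA_integer_, n_ok = 0L, n_bad = 0L))
    h <- shared_prefix_len(A, chrseq, c_L, max_h)
    n_ok <- 0L; n_bad <- 0L
    if (!is.na(c_L) && nrow(rs)) for (i in seq_len(nrow(rs))) {
      r <- rs[i, ]
      if (r$pos + r$m_len - 1L != c_L) next
      clip <- substr(r$seq, r$left_clip + r$m_len + 1L, nchar(r$seq))
      expd <- substr(A, h + 1L, h + nchar(clip))
      cmp <- min(nchar(clip), nchar(expd))
      if (cmp > 0 && str_mismatches(substr(clip, 1, cmp),
                                    substr(expd, 1, cmp)) <= 1L)
        n_ok <- n_ok + 1L else n_bad <- n_bad + 1L
    }
    list(h = h, n_ok = n_ok, n_bad = n_bad)
  }
  eval_right <- function(A) {
    if (is.na(c_R)) return(list(h = NA_integer_, n_ok = 0L, n_bad = 0L))
    h <- shared_suffix_len(A, chrseq, c_R, max_h)
    Alen <- nchar(A)
    n_ok <- 0L; n_bad <- 0L
    if (!is.na(c_R) && nrow(ls)) for (i in seq_len(nrow(ls))) {
      r <- ls[i, ]
      if (r$pos != c_R) next
      clip <- substr(r$seq, 1L, r$left_clip)
      m <- nchar(clip)
      expd <- substr(A, Alen - h - m + 1L, Alen - h)
      cmp <- min(m, nchar(expd))
      if (cmp > 0 && str_mismatches(substr(clip, m - cmp + 1L, m),
                                    substr(expd, nchar(expd) - cmp + 1L,
                                           nchar(expd))) <= 1L)
        n_ok <- n_ok + 1L else n_bad <- n_bad + 1L
    }
    list(h = h, n_ok = n_ok, n_bad = n_bad)
  }

  scored <- lapply(c("+", "-"), function(ori) {
    A <- if (ori == "+") tg else revcomp(tg)
    l <- eval_left(A); r <- eval_right(A)
    list(ori = ori, l = l, r = r, total = l$n_ok + r$n_ok)
  })
  best <- scored[[which.max(vapply(scored, `[[`, 0L, "total"))]]
  if (best$l$n_bad + best$r$n_bad > 0)
    warning(sprintf("%d clipped sequence(s) matched neither transgene terminus; discarded",
                    best$l$n_bad + best$r$n_bad))
  h_left <- best$l$h; h_right <- best$r$h
  left_local <- if (is.na(c_L)) NA_integer_ else c_L - h_left
  right_local <- if (is.na(c_R)) NA_integer_ else c_R + h_right
  support <- c(left = best$l$n_ok, right = best$r$n_ok)
  list(contig = contig,
       left_bp = if (is.na(left_local)) NA_integer_
                 else local_to_global(refs, contig, left_local),
       right_bp = if (is.na(right_local)) NA_integer_
                  else local_to_global(refs, contig, right_local),
       h_left = h_left, h_right = h_right,
       orientation = best$ori, support = support,
       clip_consensus = c(left = c_L, right = c_R),
       low_confidence = any(support < min_support))
}

#' Call the transgene integration site
#'
#' Runs the full discovery chain — informative-pair extraction, candidate
#' region location, coverage-gap deletion detection, split-read breakpoint
#' resolution with microhomology — and the genome-wide secondary-site scan.
#' Zygosity is called homozygous when the in-gap depth is below
#' `hom_frac` of the flanking median. Wildtype-like input yields a clean
#' no-call.
#'
#' @param aln alignment data.frame (both mates).
#' @param refs the `tg_reference_set`.
#' @param config named list overriding defaults: `cluster_window`, `pad_to`,
#'   `min_pairs`, `depth_max`, `min_gap`, `gap_mode`
#'   (`"auto"`/`"homozygous"`/`"depth_drop"`), `drop_frac`, `min_support`,
#'   `clip_min`, `hom_frac`, `secondary_min_pairs`.
#' @return object of class `tg_integration_call`; `status` is `"call"` or
#'   `"no_call"`.
#' @export
call_integration <- function(aln, refs, config = list()) {
  cfg <- modifyList(list(cluster_window = 2000L, pad_to = 8000L,
                         min_pairs = 3L, depth_max = 0L, min_gap = 500L,
                         gap_mode = "auto", drop_frac = 0.75,
                         min_support = 2L, clip_min = 8L, hom_frac = 0.1,
                         secondary_min_pairs = 3L), config)
  pairs <- extract_informative_pairs(aln, refs)
  no_call <- function(reason) {
    structure(list(status = "no_call", reason = reason),
              class = "tg_integration_call")
  }
  if (nrow(pairs) == 0) return(no_call("no informative pairs"))
  arc <- refs$loci$arc_locus
  off <- pairs$mapped & pairs$contig != refs$transgene_name &
    !(pairs$contig == arc$contig & pairs$pos <= arc$end + 1000L &
        (pairs$pos + pairs$m_len - 1L) >= arc$start - 1000L)
  off[is.na(off)] <- FALSE
  regions <- cluster_regions(pairs[off, , drop = FALSE], refs,
                             cfg$cluster_window, cfg$pad_to, cfg$min_pairs)
  if (!length(regions))
    return(no_call("no off-locus counterpart cluster"))
  # a secondary insertion without a deletion can out-cluster the primary
  # site, so walk the ranked clusters until one yields a gap + breakpoints
  region <- NULL; gap <- NULL; bp <- NULL
  for (reg in regions[seq_len(min(3L, length(regions)))]) {
    g <- NULL
    if (cfg$gap_mode %in% c("auto", "homozygous")) {
      g <- tryCatch(
        detect_coverage_gap(aln, reg, refs, cfg$depth_max, cfg$min_gap,
                            "homozygous"),
        error = function(e) NULL)
    }
    if (is.null(g) && cfg$gap_mode %in% c("auto", "depth_drop")) {
      g <- tryCatch(
        detect_coverage_gap(aln, reg, refs, cfg$depth_max, cfg$min_gap,
                            "depth_drop", cfg$drop_frac),
        error = function(e) NULL)
    }
    if (is.null(g)) next
    search_window <- if (identical(g$mode, "depth_drop")) 800L else 30L
    b <- tryCatch(
      resolve_breakpoints(aln, g, refs, cfg$min_support, cfg$clip_min,
                          search_window = search_window),
      error = function(e) NULL)
    if (is.null(b) || is.na(b$left_bp) || is.na(b$right_bp)) next
    region <- reg; gap <- g; bp <- b
    break
  }
  if (is.null(region))
    return(no_call("no cluster with a coverage gap and junction evidence"))
  zyg <- if (gap$gap_mean_depth < cfg$hom_frac * max(gap$flank_median, 1))
    "homozygous" else "heterozygous"
  known <- list(list(contig = region$contig,
                     start = region$start, end = region$end))
  sec <- scan_secondary_integrations(aln, refs, known = known,
                                     min_pairs = cfg$secondary_min_pairs)
  structure(list(
    status = "call", chrom = region$contig,
    left_bp = bp$left_bp, right_bp = bp$right_bp,
    deletion_length = deletion_length(bp$left_bp, bp$right_bp),
    h_left = bp$h_left, h_right = bp$h_right,
    orientation = bp$orientation, support = bp$support,
    clip_consensus = bp$clip_consensus,
    zygosity = zyg, low_confidence = bp$low_confidence,
    secondary_sites = sec, region = region, gap = gap),
    class = "tg_integration_call")
}

#' @export
print.tg_integration_call <- function(x, ...) {
  if (!identical(x$status, "call")) {
    cat("Transgene integration: no call (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Transgene integration call\n")
  cat(sprintf("  %s:%s-%s  (deletion %s bp)\n", x$chrom,
              format(x$left_bp, big.mark = ","),
              format(x$right_bp, big.mark = ","),
              format(x$deletion_length, big.mark = ",")))
  cat(sprintf("  microhomology %d / %d bp, orientation '%s', %s%s\n",
              x$h_left, x$h_right, x$orientation, x$zygosity,
              if (x$low_confidence) " (LOW CONFIDENCE)" else ""))
  cat(sprintf("  junction support: left %d, right %d; secondary sites: %d\n",
              x$support["left"], x$support["right"],
              nrow(x$secondary_sites)))
  invisible(x)
}

#' Scan for secondary integration sites
#'
#' Clusters the non-transgene mates of transgene-anchored pairs outside the
#' known loci (primary candidate region, Arc locus); clusters supported by
#' at least `min_pairs` distinct pairs are reported.
#'
#' @param aln alignment data.frame.
#' @param refs the `tg_reference_set`.
#' @param known list of list(`contig`, `start`, `end`) local intervals to
#'   ignore (e.g. the primary site).
#' @param min_pairs minimum supporting pairs per reported site.
#' @param window maximum within-cluster gap (bp).
#' @return data.frame of sites (contig, local and global interval, n_pairs);
#'   zero rows when none are found.
#' @export
scan_secondary_integrations <- function(aln, refs, known = NULL,
                                        min_pairs = 3L, window = 2000L) {
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), global_start = integer(0),
                      global_end = integer(0), n_pairs = integer(0),
                      stringsAsFactors = FALSE)
  tg_q <- unique(aln$qname[aln$mapped & aln$contig == refs$transgene_name])
  if (!length(tg_q)) return(empty)
  mates <- aln[aln$qname %in% tg_q & aln$mapped &
                 aln$contig != refs$transgene_name, , drop = FALSE]
  if (!nrow(mates)) return(empty)
  arc <- refs$loci$arc_locus
  excl <- c(list(arc), if (is.null(known)) NULL else known)
  drop <- rep(FALSE, nrow(mates))
  for (iv in excl) {
    drop <- drop | (mates$contig == iv$contig & mates$pos <= iv$end &
                      (mates$pos + mates$m_len - 1L) >= iv$start)
  }
  mates <- mates[!drop, , drop = FALSE]
  if (!nrow(mates)) return(empty)
  out <- empty
  for (ct in unique(mates$contig)) {
    m <- mates[mates$contig == ct, , drop = FALSE]
    o <- order(m$pos)
    p <- m$pos[o]; q <- m$qname[o]
    grp <- cumsum(c(1L, as.integer(diff(p) > window)))
    for (g in unique(grp)) {
      i <- grp == g
      if (length(unique(q[i])) >= min_pairs) {
        s <- min(p[i]); e <- max(p[i] + m$m_len[o][i] - 1L)
        out <- rbind(out, data.frame(
          contig = ct, start = s, end = e,
          global_start = local_to_global(refs, ct, s),
          global_end = local_to_global(refs, ct, e),
          n_pairs = length(unique(q[i])), stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' In-silico PCR
#'
#' Exact primer matching on a template: products are reported wherever the
#' forward primer matches one strand and the reverse primer's
#' reverse-complement matches downstream within `max_len` (both template
#' orientations are scanned). The product length is the distance from the
#' forward primer's 5' end to the reverse primer's 3' end, inclusive.
#'
#' @param template template sequence (character scalar).
#' @param fwd,rev primer sequences, 5' to 3'.
#' @param max_len maximum product length reported.
#' @return sorted integer vector of product lengths (empty when no product).
#' @export
insilico_pcr <- function(template, fwd, rev, max_len = 5000L) {
  if (!nzchar(fwd) || !nzchar(rev)) stop("primers must be non-empty")
  find_all <- function(pat, subj) {
    m <- gregexpr(pat, subj, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  amplify <- function(p1, p2) {
    s1 <- find_all(p1, template)
    s2 <- find_all(revcomp(p2), template)
    if (!length(s1) || !length(s2)) return(integer(0))
    e2 <- s2 + nchar(p2) - 1L
    out <- integer(0)
    for (a in s1) {
      len <- e2 - a + 1L
      out <- c(out, len[len >= nchar(p1) + nchar(p2) & len <= max_len])
    }
    out
  }
  sort(unique(c(amplify(fwd, rev), amplify(rev, fwd))))
}
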