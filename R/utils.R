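#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of length n using the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Evaluate `expr` under a temporary seed, restoring the RNG state afterwards.
# seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a fan-out of per-stage seeds from one top-level seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# substring replacement keeping length
str_assign <- function(s, at, value) {
  stopifnot(at >= 1, at + nchar(value) - 1 <= nchar(s))
  paste0(substr(s, 1, at - 1), value, substr(s, at + nchar(value), nchar(s)))
}

# a base different from each of the given bases (first in ACGT order)
other_base <- function(...) {
  setdiff(c("A", "C", "G", "T"), c(...))[1]
}

# Parse simple CIGARs over {S, M} (single M run, optional flanking clips)
# into left clip, M length, right clip. Returns a data.frame.
parse_cigar <- function(cigar) {
  n <- length(cigar)
  left <- integer(n); mlen <- integer(n); right <- integer(n)
  ops <- gregexpr("(\\d+)([SMID])", cigar)
  for (i in seq_len(n)) {
    if (is.na(cigar[i])) { left[i] <- NA; mlen[i] <- NA; right[i] <- NA; next }
    m <- regmatches(cigar[i], ops[i])[[1]]
    lens <- as.integer(sub("[SMID]", "", m))
    kind <- sub("\\d+", "", m)
    mi <- which(kind == "M")
    mlen[i] <- sum(lens[mi])
    left[i] <- if (length(mi) && mi[1] > 1 && kind[1] == "S") lens[1] else 0L
    last <- length(kind)
    right[i] <- if (length(mi) && mi[length(mi)] < last && kind[last] == "S") lens[last] else 0L
  }
  data.frame(left_clip = left, m_len = mlen, right_clip = right)
}

#' Sum of fusion-protein component masses
#'
#' Adds component molecular weights, e.g. EGFP (32.7 kDa) + Arc (55 kDa)
#' = 87.7 kDa for the EGFP-Arc fusion protein.
#'
#' @param masses_kda numeric vector of component masses in kDa, all positive.
#' @return total mass in kDa.
#' @examples
#' fusion_protein_mass(c(32.7, 55))
#' @export
fusion_protein_mass <- function(masses_kda) {
  if (length(masses_kda) == 0) stop("no component masses given")
  if (any(!is.finite(masses_kda)) || any(masses_kda <= 0))
    stop("component masses must be positive")
  sum(masses_kda)
}
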