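# Small shared helpers: rounding, sequence arithmetic, interval algebra.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves carried away from zero, the
#' convention under which printed percentages such as 9.9 and 18.9 recompute
#' exactly from their integer totals (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-away-from-zero.
#' @examples
#' round_half_away(1.25, 1) # 1.3, not 1.2
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a total, rounded half away from zero
#' @param part,whole Numerators and denominator in bp.
#' @param digits Decimal places (default 1, matching the published tables).
#' @return Numeric percentage.
#' @export
pct_of <- function(part, whole, digits = 1) {
  round_half_away(100 * part / whole, digits)
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA sequences over A,C,G,T,N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence at a target GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2. Uses the current RNG
#' stream; callers control reproducibility with `set.seed()`.
#'
#' @param n Length in bp.
#' @param gc GC fraction (default 0.45, typical of plant mtDNA).
#' @return A single DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Mutate a DNA string by point substitutions at the given per-site rate
# (or an exact count if `count` is given). Returns the mutated string.
mutate_dna <- function(s, rate = 0, count = NULL) {
  n <- nchar(s)
  if (n == 0L) return(s)
  idx <- if (!is.null(count)) {
    if (count == 0L) integer(0) else sample.int(n, count)
  } else {
    which(stats::runif(n) < rate)
  }
  if (length(idx) == 0L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  ch[idx] <- vapply(ch[idx], function(b) sample(alt[[b]], 1L), character(1))
  paste(ch, collapse = "")
}

# length of a 1-based inclusive interval, allowing origin wrap on a circular
# genome of length L (start > end denotes wrap)
interval_length <- function(start, end, L) {
  ifelse(start <= end, end - start + 1L, L - start + 1L + end)
}

# union length in bp of a set of (linear) 1-based inclusive intervals
union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start, end))))
}

# merged (reduced) intervals as a tibble
reduce_intervals <- function(start, end) {
  if (length(start) == 0L) return(tibble(start = integer(0), end = integer(0)))
  r <- IRanges::reduce(IRanges::IRanges(start, end))
  tibble(start = IRanges::start(r), end = IRanges::end(r))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
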