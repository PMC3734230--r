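# Shared-sequence totals between mt genomes after masking chloroplast-derived
# segments and extra copies of large repeats.

#' Mask a genome for shared-sequence comparison
#'
#' Removes all merged chloroplast-derived intervals and, for every repeat
#' family whose alignment length reaches `large_cutoff`, every copy except
#' the first (lowest start coordinate). Removed intervals are replaced by N
#' in the masked sequence so downstream homology search never matches them;
#' the kept/removed partition is exact.
#'
#' @param ag An [annotated_genome()] (or [mt_genome()]).
#' @param homologs Homolog tibble from [scan_plastid_homologs()] (may be
#'   empty).
#' @param families Repeat-family tibble from [find_repeats()] (may be
#'   empty).
#' @param large_cutoff Families at or above this alignment length count as
#'   large repeats (default 1000 bp, the top published size class).
#' @return An object of class `masked_genome`: `species`, `length`,
#'   `masked_seq`, and tibbles `kept` and `removed` (with `reason` in
#'   {cp_derived, repeat_extra_copy}).
#' @export
mask_genome <- function(ag, homologs = empty_homologs(),
                        families = empty_repeat_families(),
                        large_cutoff = 1000) {
  g <- if (inherits(ag, "annotated_genome")) ag$genome else ag
  L <- g$length
  rem <- list()
  if (nrow(homologs)) {
    rem$cp <- tibble(start = homologs$mt_start, end = homologs$mt_end,
                     reason = "cp_derived")
  }
  if (nrow(families)) {
    extra <- families %>%
      filter(.data$rep_length >= large_cutoff) %>%
      mutate(copies = purrr::map(.data$copies, function(cp) {
        cp <- arrange(cp, .data$start)
        cp[-1, , drop = FALSE]  # keep the first copy
      })) %>%
      tidyr::unnest("copies")
    if (nrow(extra)) {
      lin_end <- ifelse(extra$end < extra$start, L, extra$end)
      lin_start2 <- ifelse(extra$end < extra$start, 1L, NA_integer_)
      rem$rep <- bind_rows(
        tibble(start = extra$start, end = lin_end, reason = "repeat_extra_copy"),
        tibble(start = lin_start2[!is.na(lin_start2)],
               end = extra$end[!is.na(lin_start2)],
               reason = "repeat_extra_copy"))
    }
  }
  removed_raw <- bind_rows(rem)
  if (nrow(removed_raw)) {
    red <- IRanges::reduce(IRanges::IRanges(removed_raw$start, removed_raw$end))
    removed <- tibble(start = IRanges::start(red), end = IRanges::end(red))
    # annotate merged intervals with the reasons they absorb
    rr <- IRanges::IRanges(removed_raw$start, removed_raw$end)
    ov <- IRanges::findOverlaps(red, rr)
    reason <- vapply(seq_len(length(red)), function(i) {
      paste(sort(unique(removed_raw$reason[S4Vectors::subjectHits(ov)[
        S4Vectors::queryHits(ov) == i]])), collapse = ",")
    }, character(1))
    removed$reason <- reason
    keptR <- IRanges::gaps(red, start = 1L, end = L)
    kept <- tibble(start = IRanges::start(keptR), end = IRanges::end(keptR))
  } else {
    removed <- tibble(start = integer(0), end = integer(0), reason = character(0))
    kept <- tibble(start = 1L, end = L)
  }
  ch <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(removed))) {
    ch[removed$start[i]:removed$end[i]] <- "N"
  }
  structure(list(species = if (inherits(ag, "annotated_genome")) ag$species else g$id,
                 length = L, masked_seq = paste(ch, collapse = ""),
                 kept = kept, removed = removed),
            class = "masked_genome")
}

#' @export
print.masked_genome <- function(x, ...) {
  cat(sprintf("<masked_genome> %s: %s bp, kept %s bp (%d removed intervals)\n",
              x$species, format(x$length, big.mark = ","),
              format(kept_length(x), big.mark = ","), nrow(x$removed)))
  invisible(x)
}

#' Kept (unmasked) length of a masked genome in bp
#' @param mg A `masked_genome`.
#' @return Integer bp.
#' @export
kept_length <- function(mg) {
  as.integer(sum(mg$kept$end - mg$kept$start + 1L))
}

#' Shared sequence length between two masked genomes
#'
#' Local homology search of the query's kept sequence against the subject's
#' kept sequence; matched query intervals are merged and their union length
#' returned. The total is query-based, so shared(q, s) and shared(s, q) can
#' differ slightly by merging direction.
#'
#' @param q,s `masked_genome` objects (query and subject).
#' @param min_identity Percent identity floor (default 70).
#' @param min_len Minimum hit length (default 50 bp).
#' @param word_size Seed size (default 11).
#' @return Shared length in bp (query coordinates).
#' @export
shared_length <- function(q, s, min_identity = 70, min_len = 50,
                          word_size = 11) {
  stopifnot(inherits(q, "masked_genome"), inherits(s, "masked_genome"))
  if (kept_length(q) == 0L || kept_length(s) == 0L) {
    warning("empty kept set; shared length is 0")
    return(0L)
  }
  hits <- find_local_matches(q$masked_seq, s$masked_seq, k = word_size,
                             min_len = min_len, min_identity = min_identity)
  if (nrow(hits) == 0L) return(0L)
  as.integer(union_length(hits$start1, hits$end1))
}

#' Pairwise shared-sequence matrix
#'
#' Full (both-direction) matrix of query-based shared totals; the diagonal
#' is each genome's kept length.
#'
#' @param genomes List of `masked_genome` objects.
#' @param ... Passed to [shared_length()].
#' @return A numeric matrix with species dimnames and a `parameters`
#'   attribute recording the search settings.
#' @export
shared_matrix <- function(genomes, ...) {
  stopifnot(length(genomes) >= 2L)
  sp <- vapply(genomes, function(g) g$species, character(1))
  n <- length(genomes)
  m <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- if (i == j) kept_length(genomes[[i]]) else
        shared_length(genomes[[i]], genomes[[j]], ...)
    }
  }
  attr(m, "parameters") <- list(...)
  m
}
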