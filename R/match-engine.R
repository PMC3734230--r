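# Seed-and-extend local matching engine shared by the repeat scanner, the
# MTPT scanner and the shared-sequence stage.
#
# Exact k-mer seeds on both strands are chained along diagonals, extended by
# ungapped X-drop alignment (substitution model; the synthetic generator's
# default divergence process) and polished outward to the full extent of a
# uniformly diverged region. Circular self-comparison scans the doubled
# sequence and folds coordinates back modulo the genome length.

# 2-bit k-mer codes for every window of `s`; windows containing N are NA.
kmer_codes <- function(s, k) {
  b <- utf8ToInt(s)
  map <- rep(NA_real_, 128)
  map[utf8ToInt("A")] <- 0; map[utf8ToInt("C")] <- 1
  map[utf8ToInt("G")] <- 2; map[utf8ToInt("T")] <- 3
  v <- map[b]
  n <- length(v)
  if (n < k) return(numeric(0))
  as.vector(stats::embed(v, k) %*% 4^(0:(k - 1)))
}

# seed pairs between s1 and oriented s2 as a data.table(p1, p2)
seed_pairs <- function(s1, s2, k, max_occ, self_forward = FALSE) {
  c1 <- kmer_codes(s1, k)
  d1 <- data.table::data.table(code = c1, p1 = seq_along(c1))[!is.na(code)]
  if (identical(s1, s2)) {
    d2 <- data.table::data.table(code = d1$code, p2 = d1$p1)
  } else {
    c2 <- kmer_codes(s2, k)
    d2 <- data.table::data.table(code = c2, p2 = seq_along(c2))[!is.na(code)]
  }
  # low-complexity guard: drop hyper-frequent words
  cnt1 <- d1[, .N, by = "code"]
  cnt2 <- d2[, .N, by = "code"]
  keep <- intersect(cnt1[cnt1$N <= max_occ]$code, cnt2[cnt2$N <= max_occ]$code)
  d1 <- d1[d1$code %in% keep]
  d2 <- d2[d2$code %in% keep]
  m <- merge(d1, d2, by = "code", allow.cartesian = TRUE)
  if (self_forward) m <- m[m$p1 < m$p2]
  m[, c("p1", "p2")]
}

# chain seeds sharing a diagonal into candidate cores
chain_seeds <- function(pairs, k, chain_gap) {
  if (nrow(pairs) == 0L) {
    return(tibble(a1 = integer(0), b1 = integer(0),
                  a2 = integer(0), b2 = integer(0)))
  }
  dt <- data.table::as.data.table(pairs)
  dt[, "diag" := dt$p2 - dt$p1]
  data.table::setorderv(dt, c("diag", "p1"))
  brk <- c(TRUE, diff(dt$p1) > chain_gap | diff(dt$diag) != 0L)
  dt[, "grp" := cumsum(brk)]
  ch <- dt[, list(a1 = min(p1), b1 = max(p1) + k - 1L,
                  a2 = min(p2), b2 = max(p2) + k - 1L), by = "grp"]
  as_tibble(ch[, -1])
}

#' Find local sequence matches between two sequences
#'
#' The package's homology-search engine: exact `k`-mer seeding on both
#' strands, diagonal chaining, ungapped X-drop extension, and an identity
#' polish that grows each hit to the furthest ends at which the whole hit
#' still meets `min_identity`. With `seq2 = NULL` the sequence is compared
#' against itself (trivial self-diagonal and mirror duplicates removed);
#' `circular = TRUE` additionally scans the doubled sequence so hits through
#' the origin are found, reported once with wrap coordinates.
#'
#' @param seq1 Query sequence (string over A,C,G,T,N).
#' @param seq2 Subject sequence, or NULL for self-comparison.
#' @param k Seed word size (exact match length).
#' @param min_len Minimum reported hit length in bp.
#' @param min_identity Minimum percent identity of a reported hit.
#' @param chain_gap Maximum seed-start gap chained along one diagonal.
#' @param max_occ Seeds occurring more often than this are skipped.
#' @param xdrop X-drop threshold for ungapped extension.
#' @param circular Treat `seq1` as circular (self-comparison only).
#' @return A tibble with one row per hit: `start1`, `end1`, `start2`,
#'   `end2`, `orientation` ("forward"/"reverse"), `length`, `matches`,
#'   `identity` (percent). For reverse hits `start2 < end2` still holds;
#'   the subject interval is given on the forward strand.
#' @export
find_local_matches <- function(seq1, seq2 = NULL, k = 15, min_len = 20,
                               min_identity = 80, chain_gap = 30,
                               max_occ = 64, xdrop = 12, circular = FALSE) {
  seq1 <- toupper(seq1)
  if (grepl("[^ACGTN]", seq1)) stop("non-ACGTN characters in seq1")
  self <- is.null(seq2)
  if (!self) {
    seq2 <- toupper(seq2)
    if (grepl("[^ACGTN]", seq2)) stop("non-ACGTN characters in seq2")
    if (nchar(seq2) < k) stop("seq2 shorter than the seed size")
  }
  if (min_len < k) stop("min_len must be >= the seed size k")
  L <- nchar(seq1)
  s1 <- if (self && circular) paste0(seq1, seq1) else seq1
  s2 <- if (self) s1 else seq2

  run_orientation <- function(orient) {
    if (orient == "forward") {
      pr <- seed_pairs(s1, s2, k, max_occ, self_forward = self)
      if (self) {
        # drop the doubled-sequence identity diagonal
        pr <- pr[pr$p2 - pr$p1 != L]
      }
      s2o <- s2
    } else {
      s2o <- revcomp(s2)
      pr <- seed_pairs(s1, s2o, k, max_occ, self_forward = FALSE)
    }
    cores <- chain_seeds(pr, k, chain_gap)
    if (nrow(cores) == 0L) return(NULL)
    ext <- as_tibble(extend_hits_cpp(s1, s2o, cores$a1, cores$b1, cores$a2,
                                     cores$b2, xdrop = xdrop, mispen = 2L,
                                     min_id = min_identity / 100))
    ext <- ext[ext$length >= min_len & ext$identity >= min_identity, ,
               drop = FALSE]
    if (nrow(ext) == 0L) return(NULL)
    if (orient == "reverse") {
      L2 <- nchar(s2o)
      new_s2 <- L2 - ext$end2 + 1L
      new_e2 <- L2 - ext$start2 + 1L
      ext$start2 <- new_s2
      ext$end2 <- new_e2
    }
    ext$orientation <- orient
    ext
  }

  hits <- bind_rows(run_orientation("forward"), run_orientation("reverse"))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(tibble(start1 = integer(0), end1 = integer(0), start2 = integer(0),
                  end2 = integer(0), orientation = character(0),
                  length = integer(0), matches = integer(0),
                  identity = numeric(0)))
  }
  hits <- merge_same_diagonal(hits, s1, s2, self)
  if (self) hits <- canonicalize_self_hits(hits, L, circular)
  hits %>%
    arrange(dplyr::desc(.data$length), .data$start1) %>%
    select("start1", "end1", "start2", "end2", "orientation", "length",
           "matches", "identity")
}

# merge overlapping hits that share a diagonal (same orientation), then drop
# hits contained in a longer hit on both coordinates
merge_same_diagonal <- function(hits, s1, s2, self) {
  s2f <- if (self) s1 else s2
  s2r <- revcomp(s2f)
  L2 <- nchar(s2f)
  out <- list()
  for (ori in unique(hits$orientation)) {
    h <- hits[hits$orientation == ori, , drop = FALSE]
    dg <- if (ori == "forward") h$start2 - h$start1 else h$start2 + h$end1
    for (d in unique(dg)) {
      hd <- h[dg == d, , drop = FALSE]
      r <- IRanges::reduce(IRanges::IRanges(hd$start1, hd$end1))
      ns <- IRanges::start(r); ne <- IRanges::end(r)
      if (ori == "forward") {
        a2 <- ns + d
        m <- count_matches_cpp(s1, s2f, ns, ne, a2)
        mg <- tibble(start1 = ns, end1 = ne, start2 = a2, end2 = ne + d,
                     orientation = ori, length = ne - ns + 1L, matches = m,
                     identity = 100 * m / (ne - ns + 1L))
      } else {
        # reverse diagonal: start2 + end1 constant = d
        e2 <- d - ns
        a2 <- d - ne
        # matches computed in reverse-complement space
        a2r <- L2 - e2 + 1L
        m <- count_matches_cpp(s1, s2r, ns, ne, a2r)
        mg <- tibble(start1 = ns, end1 = ne, start2 = a2, end2 = e2,
                     orientation = ori, length = ne - ns + 1L, matches = m,
                     identity = 100 * m / (ne - ns + 1L))
      }
      out[[length(out) + 1L]] <- mg
    }
  }
  res <- bind_rows(out)
  # drop hits fully contained in another hit on both intervals
  if (nrow(res) > 1L) {
    keep <- rep(TRUE, nrow(res))
    ord <- order(-res$length)
    for (i in seq_along(ord)) {
      ii <- ord[i]
      if (!keep[ii]) next
      within1 <- res$start1 >= res$start1[ii] & res$end1 <= res$end1[ii]
      within2 <- res$start2 >= res$start2[ii] & res$end2 <= res$end2[ii]
      cont <- within1 & within2 & res$orientation == res$orientation[ii] &
        seq_len(nrow(res)) != ii & res$length <= res$length[ii]
      keep[cont] <- FALSE
    }
    res <- res[keep, , drop = FALSE]
  }
  res
}

# fold doubled-sequence coordinates back to [1, L], drop mirror duplicates
# and self-matches
canonicalize_self_hits <- function(hits, L, circular) {
  fold <- function(x) ((x - 1L) %% L) + 1L
  if (circular) {
    ok <- hits$start1 <= L & (hits$end1 - hits$start1 + 1L) <= L &
      (hits$end2 - hits$start2 + 1L) <= L
    hits <- hits[ok, , drop = FALSE]
    hits$end1 <- fold(hits$end1); hits$start1 <- fold(hits$start1)
    hits$end2 <- fold(hits$end2); hits$start2 <- fold(hits$start2)
  }
  if (nrow(hits) == 0L) return(hits)
  key_a <- sprintf("%d-%d", hits$start1, hits$end1)
  key_b <- sprintf("%d-%d", hits$start2, hits$end2)
  canon <- ifelse(key_b < key_a, paste(key_b, key_a, hits$orientation),
                  paste(key_a, key_b, hits$orientation))
  keep <- key_a != key_b & !duplicated(canon)
  hits[keep, , drop = FALSE]
}
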