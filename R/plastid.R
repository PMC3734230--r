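# Chloroplast-derived (MTPT) sequence detection and classification.

PHOTOSYNTHESIS_PATTERNS <- "^(psa|psb|pet|rbcL|ndh)"

#' Scan a mitochondrial genome for chloroplast-derived segments
#'
#' Local homology search of the mt genome against the chloroplast genome on
#' both strands; hits below the identity or length floors are discarded and
#' overlapping mt intervals are merged, keeping the best-identity
#' chloroplast source for each merged segment.
#'
#' @param mt An [mt_genome()] or [annotated_genome()] (mitochondrial).
#' @param cp An [annotated_genome()] (chloroplast; annotation is used by
#'   [classify_homolog()]).
#' @param min_identity Minimum percent identity (default 80, the
#'   conventional MTPT reporting floor).
#' @param min_len Minimum segment length in bp (default 30).
#' @param word_size Exact seed size for the search (default 6; small enough
#'   that short diverged segments near the identity floor still seed).
#' @return A tibble of homologs: `mt_start`, `mt_end`, `cp_start`, `cp_end`,
#'   `strand`, `length`, `identity`, ordered by `mt_start`.
#' @export
scan_plastid_homologs <- function(mt, cp, min_identity = 80, min_len = 30,
                                  word_size = 6) {
  if (inherits(mt, "annotated_genome")) mt <- mt$genome
  stopifnot(inherits(mt, "mt_genome"), inherits(cp, "annotated_genome"))
  if (cp$genome$length == 0L) stop("empty chloroplast genome")
  hits <- find_local_matches(mt$seq, cp$genome$seq, k = word_size,
                             min_len = min_len, min_identity = min_identity)
  if (nrow(hits) == 0L) return(empty_homologs())
  # merge overlapping mt intervals (merge distance 0); the best-identity hit
  # within each merged segment donates the cp source coordinates
  r <- IRanges::reduce(IRanges::IRanges(hits$start1, hits$end1))
  grp <- S4Vectors::subjectHits(IRanges::findOverlaps(
    IRanges::IRanges(hits$start1, hits$end1), r, select = "all"))
  hits$grp <- grp
  merged <- hits %>%
    group_by(.data$grp) %>%
    summarise(
      mt_start = min(.data$start1), mt_end = max(.data$end1),
      best = which.max(.data$identity * .data$length),
      cp_start = .data$start2[best], cp_end = .data$end2[best],
      strand = ifelse(.data$orientation[best] == "forward", "+", "-"),
      identity = .data$identity[best],
      .groups = "drop") %>%
    mutate(length = .data$mt_end - .data$mt_start + 1L) %>%
    filter(.data$length >= min_len) %>%
    arrange(.data$mt_start) %>%
    select("mt_start", "mt_end", "cp_start", "cp_end", "strand", "length",
           "identity")
  merged
}

empty_homologs <- function() {
  tibble(mt_start = integer(0), mt_end = integer(0), cp_start = integer(0),
         cp_end = integer(0), strand = character(0), length = integer(0),
         identity = numeric(0))
}

#' Classify a plastid homolog by its chloroplast source annotation
#'
#' `tRNA` if the source interval overlaps a chloroplast tRNA gene (taking
#' precedence on double overlap), `photosynthesis` if it overlaps a
#' photosynthesis-related gene (psa*/psb*/pet*/rbcL/ndh*), `other`
#' otherwise.
#'
#' @param homologs A homolog tibble from [scan_plastid_homologs()].
#' @param cp The annotated chloroplast genome.
#' @return The homolog tibble with a `klass` column and, for tRNA-class
#'   homologs, the overlapped cp gene in `cp_gene`.
#' @export
classify_homolog <- function(homologs, cp) {
  stopifnot(inherits(cp, "annotated_genome"))
  fb <- feature_blocks(cp$features)
  klass <- rep("other", nrow(homologs))
  cp_gene <- rep(NA_character_, nrow(homologs))
  if (nrow(homologs) == 0L) {
    return(mutate(homologs, klass = character(0), cp_gene = character(0)))
  }
  hr <- IRanges::IRanges(homologs$cp_start, homologs$cp_end)
  overlap_gene <- function(rows) {
    if (nrow(rows) == 0L) return(rep(NA_character_, nrow(homologs)))
    fr <- IRanges::IRanges(rows$start, rows$end)
    ov <- IRanges::findOverlaps(hr, fr, select = "first")
    ifelse(is.na(ov), NA_character_, rows$locus[ov])
  }
  trna_hit <- overlap_gene(fb[fb$category == "tRNA", , drop = FALSE])
  photo <- fb[grepl(PHOTOSYNTHESIS_PATTERNS, fb$locus), , drop = FALSE]
  photo_hit <- overlap_gene(photo)
  klass[!is.na(photo_hit)] <- "photosynthesis"
  klass[!is.na(trna_hit)] <- "tRNA"   # tRNA wins on double overlap
  cp_gene[!is.na(photo_hit)] <- photo_hit[!is.na(photo_hit)]
  cp_gene[!is.na(trna_hit)] <- trna_hit[!is.na(trna_hit)]
  mutate(homologs, klass = klass, cp_gene = cp_gene)
}

#' Summarize MTPT capacity per species
#'
#' One row per mt/cp genome pair: merged homolog count, total length and
#' coverage percent of the mt genome (one decimal).
#'
#' @param pairs A list of `list(mt = , cp = )` pairs of annotated genomes,
#'   or a single such pair.
#' @param ... Passed to [scan_plastid_homologs()].
#' @return A tibble with `species`, `total_bp`, `n_homologs`,
#'   `coverage_pct`.
#' @export
summarize_mtpt <- function(pairs, ...) {
  if (!is.null(pairs$mt)) pairs <- list(pairs)
  purrr::map_dfr(pairs, function(p) {
    h <- scan_plastid_homologs(p$mt, p$cp, ...)
    mtpt_summary_row(h, species = p$mt$species %||% p$mt$id,
                     genome_length = if (inherits(p$mt, "annotated_genome"))
                       p$mt$genome$length else p$mt$length)
  })
}

#' Summary row from an existing homolog table
#' @param homologs Homolog tibble (merged mt intervals).
#' @param species Species label.
#' @param genome_length mt genome length in bp.
#' @return One-row tibble with `species`, `total_bp`, `n_homologs`,
#'   `coverage_pct`.
#' @export
mtpt_summary_row <- function(homologs, species, genome_length) {
  total <- union_length(homologs$mt_start, homologs$mt_end)
  tibble(species = species, total_bp = as.integer(total),
         n_homologs = nrow(homologs),
         coverage_pct = pct_of(total, genome_length))
}

#' Conserved linkage of plastid homologs with mitochondrial genes
#'
#' For every homolog the nearest annotated mt gene within `window` bp on
#' each side is recorded; records with an identical (homolog label, left
#' gene, right gene) arrangement are grouped across species and the species
#' set sharing each arrangement is reported.
#'
#' @param species_results Named list (by species) of
#'   `list(homologs = , mt = )` where `homologs` carries `klass`/`cp_gene`
#'   columns from [classify_homolog()] and `mt` is the annotated mt genome.
#' @param window Maximum flank distance in bp (default 2000).
#' @return A tibble with `homolog`, `left_gene`, `right_gene`, `species`
#'   (list-column), `n_species`.
#' @export
conserved_linkage <- function(species_results, window = 2000) {
  recs <- purrr::imap_dfr(species_results, function(res, sp) {
    h <- res$homologs
    if (nrow(h) == 0L) return(NULL)
    fb <- feature_blocks(res$mt$features) %>%
      filter(.data$category %in% c("protein", "rRNA"))
    left_gene <- right_gene <- rep(NA_character_, nrow(h))
    if (nrow(fb)) {
      for (i in seq_len(nrow(h))) {
        dl <- h$mt_start[i] - fb$end
        dr <- fb$start - h$mt_end[i]
        lcand <- which(dl >= 0 & dl <= window)
        rcand <- which(dr >= 0 & dr <= window)
        if (length(lcand)) left_gene[i] <- fb$locus[lcand[which.min(dl[lcand])]]
        if (length(rcand)) right_gene[i] <- fb$locus[rcand[which.min(dr[rcand])]]
      }
    }
    lab <- if ("cp_gene" %in% names(h)) {
      ifelse(is.na(h$cp_gene), sprintf("cp:%d-%d", h$cp_start, h$cp_end), h$cp_gene)
    } else {
      sprintf("cp:%d-%d", h$cp_start, h$cp_end)
    }
    tibble(species = sp, homolog = lab, left_gene = left_gene,
           right_gene = right_gene)
  })
  if (nrow(recs) == 0L) {
    return(tibble(homolog = character(0), left_gene = character(0),
                  right_gene = character(0), species = list(),
                  n_species = integer(0)))
  }
  recs %>%
    group_by(.data$homolog, .data$left_gene, .data$right_gene) %>%
    summarise(species = list(sort(unique(.data$species))), .groups = "drop") %>%
    mutate(n_species = lengths(.data$species)) %>%
    arrange(dplyr::desc(.data$n_species), .data$homolog)
}
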