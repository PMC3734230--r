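# Core data model: circular genomes and annotated genomes with 1-based
# inclusive exon intervals. Features live in a tidy tibble (one row per exon)
# so downstream verbs compose with dplyr.

FEATURE_CATEGORIES <- c("protein", "rRNA", "tRNA", "pseudogene", "remnant")

#' Construct a (circular) genome
#'
#' @param seq Nucleotide sequence over A,C,G,T,N (a single string).
#' @param id Text label.
#' @param circular Logical; plant mitochondrial master circles are circular.
#' @return An object of class `mt_genome` with fields `id`, `seq`, `length`,
#'   `circular`.
#' @export
mt_genome <- function(seq, id = "genome", circular = TRUE) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", seq)) stop("genome sequence contains non-ACGTN characters")
  structure(list(id = id, seq = seq, length = nchar(seq), circular = circular),
            class = "mt_genome")
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf("<mt_genome> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Build a feature table
#'
#' One row per exon; trans-spliced genes contribute one cis-contiguous block
#' of exons per `trans_block` label (e.g. the nad1 b-c block separate from
#' d-e). Duplicate gene copies share `locus` and are distinguished by
#' `copy_index`.
#'
#' @param locus Character; gene label (duplicates share it).
#' @param category One of protein, rRNA, tRNA, pseudogene, remnant.
#' @param strand "+" or "-" per exon; all exons of one feature share a strand.
#' @param start,end 1-based inclusive coordinates; `start > end` denotes an
#'   origin-spanning interval on a circular genome.
#' @param exon Exon index within the feature (default 1).
#' @param trans_block Optional label naming the cis block of a trans-spliced
#'   gene (NA for ordinary genes).
#' @param copy_index Copy number of a duplicated locus (default 1).
#' @return A tibble with the canonical feature columns.
#' @export
feature_table <- function(locus, category, strand, start, end,
                          exon = 1L, trans_block = NA_character_,
                          copy_index = 1L) {
  stopifnot(all(category %in% FEATURE_CATEGORIES), all(strand %in% c("+", "-")))
  tibble(locus = as.character(locus), category = as.character(category),
         strand = as.character(strand), start = as.integer(start),
         end = as.integer(end), exon = as.integer(exon),
         trans_block = as.character(trans_block),
         copy_index = as.integer(copy_index))
}

empty_features <- function() {
  feature_table(character(0), character(0), character(0), integer(0), integer(0),
                integer(0), character(0), integer(0))
}

#' Construct an annotated genome
#'
#' @param genome An [mt_genome()].
#' @param features A feature tibble as built by [feature_table()].
#' @param species Species name.
#' @param group Taxonomic group: "gymnosperm", "monocot" or "dicot".
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome, features = empty_features(),
                             species = genome$id, group = NA_character_) {
  stopifnot(inherits(genome, "mt_genome"))
  features <- as_tibble(features)
  need <- c("locus", "category", "strand", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  if (!"exon" %in% names(features)) features$exon <- 1L
  if (!"trans_block" %in% names(features)) features$trans_block <- NA_character_
  if (!"copy_index" %in% names(features)) features$copy_index <- 1L
  bad <- features$start < 1L | features$end < 1L |
    features$start > genome$length | features$end > genome$length
  if (any(bad)) {
    stop(sprintf("feature coordinates out of range [1, %d] for locus %s",
                 genome$length, features$locus[which(bad)[1]]))
  }
  if (any(features$start > features$end & !genome$circular)) {
    stop("wrap intervals (start > end) are only legal on a circular genome")
  }
  structure(list(genome = genome, features = features,
                 species = species, group = group),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s (%s): %s bp, %d features / %d loci\n",
              x$species, x$group %||% NA, format(x$genome$length, big.mark = ","),
              nrow(feature_blocks(x$features)), length(unique(x$features$locus))))
  invisible(x)
}

# Collapse the per-exon table to one row per feature (locus, trans_block,
# copy_index), keeping strand, the block span and summed exon length.
feature_blocks <- function(features) {
  if (nrow(features) == 0L) {
    return(tibble(locus = character(0), category = character(0),
                  strand = character(0), trans_block = character(0),
                  copy_index = integer(0), start = integer(0), end = integer(0),
                  exon_bp = integer(0), n_exons = integer(0)))
  }
  features %>%
    group_by(.data$locus, .data$category, .data$strand, .data$trans_block,
             .data$copy_index) %>%
    summarise(exon_bp = sum(.data$end - .data$start + 1L),
              n_exons = dplyr::n(),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    arrange(.data$start)
}

#' Extract a subsequence from a genome
#'
#' Returns the forward-strand slice for `strand = "+"`, or its reverse
#' complement for `strand = "-"`. On a circular genome `start > end` wraps
#' through the origin.
#'
#' @param g An [mt_genome()] (or `annotated_genome`, whose genome is used).
#' @param start,end 1-based inclusive coordinates.
#' @param strand "+" or "-".
#' @return A single DNA string.
#' @examples
#' g <- mt_genome("ACGTAC")
#' extract_subsequence(g, 2, 4)        # "CGT"
#' extract_subsequence(g, 2, 4, "-")   # "ACG"
#' extract_subsequence(g, 5, 2)        # "ACAC" (wrap)
#' @export
extract_subsequence <- function(g, start, end, strand = "+") {
  if (inherits(g, "annotated_genome")) g <- g$genome
  stopifnot(inherits(g, "mt_genome"))
  L <- g$length
  if (start < 1L || end < 1L || start > L || end > L) {
    stop(sprintf("interval [%d, %d] outside [1, %d]", start, end, L))
  }
  s <- if (start <= end) {
    substr(g$seq, start, end)
  } else {
    if (!g$circular) stop("wrap interval on a linear genome")
    paste0(substr(g$seq, start, L), substr(g$seq, 1L, end))
  }
  if (strand == "-") revcomp(s) else s
}

#' Intergenic gap between two neighboring genes
#'
#' The signed distance `start2 - end1 - 1` in the transcription direction of
#' the cluster, taken modulo the genome length when the pair spans the
#' origin. Zero means the genes touch; negative values denote an overlap of
#' the coding regions by that many bp.
#'
#' @param end1 End coordinate (1-based, inclusive) of the upstream gene.
#' @param start2 Start coordinate of the downstream gene.
#' @param genome_length Circular genome length in bp.
#' @return Signed integer gap in bp.
#' @examples
#' intergenic_gap(309502, 309687, 621884) # 184
#' intergenic_gap(129754, 129803, 621884) # 48
#' intergenic_gap(100, 101, 1000)         # 0 (touching)
#' @export
intergenic_gap <- function(end1, start2, genome_length) {
  if (end1 == start2) stop("identical coordinates do not form a gene pair")
  raw <- start2 - end1 - 1L
  # wrap through the origin: take the short way around when the linear gap
  # would be impossibly large and negative
  if (raw < -(genome_length %/% 2L)) raw <- raw + genome_length
  as.integer(raw)
}

#' Tabulate genic content of an annotated genome
#'
#' Per-category totals in bp and as a percentage of genome length (one
#' decimal, half away from zero). The protein total splits into exon and
#' intron bp; intron length of a cis exon block is its coordinate span minus
#' the summed exon lengths (trans-spliced "introns" between blocks are
#' undefined and not counted).
#'
#' @param ag An [annotated_genome()].
#' @return A tibble with columns `category`, `bp`, `pct`; protein appears as
#'   the rows `protein_exon`, `protein_intron` and `protein_total`.
#' @export
genic_content_table <- function(ag) {
  stopifnot(inherits(ag, "annotated_genome"))
  L <- ag$genome$length
  fb <- feature_blocks(ag$features)
  span <- function(b) interval_length(b$start, b$end, L)
  tot <- function(cat) {
    b <- fb[fb$category == cat, , drop = FALSE]
    exon <- sum(b$exon_bp)
    intron <- sum(span(b)) - exon
    c(exon = exon, intron = intron)
  }
  p <- tot("protein")
  out <- tibble(
    category = c("protein_exon", "protein_intron", "protein_total",
                 "tRNA", "rRNA"),
    bp = as.integer(c(p["exon"], p["intron"], sum(p),
                      tot("tRNA")["exon"], tot("rRNA")["exon"] +
                        tot("rRNA")["intron"]))
  )
  out$pct <- pct_of(out$bp, L)
  out
}

#' Count annotated genes per category
#'
#' Counts distinct loci per category the way published gene totals are
#' quoted: duplicate copies of a locus count once, pseudogenes and remnant
#' fragments are excluded from the headline total.
#'
#' @param ag An [annotated_genome()].
#' @return A tibble with `category`, `n_loci` and a `total` attribute-free
#'   grand-total row for protein + rRNA + tRNA.
#' @export
gene_counts <- function(ag) {
  fb <- feature_blocks(ag$features)
  core <- fb %>%
    filter(.data$category %in% c("protein", "rRNA", "tRNA")) %>%
    distinct(.data$locus, .data$category) %>%
    dplyr::count(.data$category, name = "n_loci")
  bind_rows(core, tibble(category = "total", n_loci = sum(core$n_loci)))
}
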