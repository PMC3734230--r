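# I/O for annotated genomes.
#
# Primary plain-text format: FASTA (via Biostrings) + a tab-separated feature
# table; a GenBank flat-file reader/writer covers records deposited with
# join()/complement() locations. GFF3 (1-based) and BED (0-based half-open)
# exports are provided for interoperability; conversions are exact.

#' Read an annotated genome
#'
#' @param path Path to a GenBank flat file, or to a FASTA file when
#'   `format = "fasta+features"` (the feature table is then read from
#'   `features_path`).
#' @param format `"genbank"` or `"fasta+features"`.
#' @param features_path Path to the tab-separated feature table (columns
#'   locus, category, strand, exons as `start..end` joined by commas,
#'   trans_block, copy_index). Defaults to `path` with a `.features.tsv`
#'   extension.
#' @param species,group Optional metadata overriding what the file carries.
#' @param circular Is the genome circular (default TRUE)?
#' @return An [annotated_genome()].
#' @export
read_annotated_genome <- function(path, format = c("genbank", "fasta+features"),
                                  features_path = NULL, species = NULL,
                                  group = NA_character_, circular = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "genbank") {
    ag <- read_genbank(path, circular = circular)
  } else {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 1L) stop("expected exactly one FASTA record in ", path)
    g <- mt_genome(as.character(ss[[1]]), id = sub("\\s.*$", "", names(ss)[1]),
                   circular = circular)
    if (is.null(features_path)) {
      features_path <- paste0(sub("\\.(fa|fasta|fna)$", "", path), ".features.tsv")
    }
    feats <- if (file.exists(features_path)) {
      read_feature_tsv(features_path)
    } else {
      empty_features()
    }
    ag <- annotated_genome(g, feats, species = g$id)
  }
  if (!is.null(species)) ag$species <- species
  if (!is.na(group)) ag$group <- group
  ag
}

#' Write an annotated genome as FASTA plus a feature table
#'
#' The inverse of [read_annotated_genome()] for the `fasta+features` format;
#' write-then-read is the identity on the data model.
#'
#' @param ag An [annotated_genome()].
#' @param path Output FASTA path; the feature table goes to `path` with a
#'   `.features.tsv` extension unless `features_path` is given.
#' @param features_path Optional explicit feature-table path.
#' @return Invisibly, the two paths written.
#' @export
write_annotated_genome <- function(ag, path, features_path = NULL) {
  stopifnot(inherits(ag, "annotated_genome"))
  if (is.null(features_path)) {
    features_path <- paste0(sub("\\.(fa|fasta|fna)$", "", path), ".features.tsv")
  }
  ss <- Biostrings::DNAStringSet(ag$genome$seq)
  names(ss) <- ag$genome$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  write_feature_tsv(ag$features, features_path)
  invisible(c(fasta = path, features = features_path))
}

read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("locus", "category", "strand", "exons", "trans_block", "copy_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  rows <- purrr::pmap(df, function(locus, category, strand, exons, trans_block,
                                   copy_index, ...) {
    iv <- parse_exon_list(exons)
    feature_table(locus, category, strand, iv$start, iv$end,
                  exon = seq_len(nrow(iv)),
                  trans_block = if (trans_block == "") NA_character_ else trans_block,
                  copy_index = as.integer(copy_index))
  })
  bind_rows(rows)
}

write_feature_tsv <- function(features, path) {
  df <- features %>%
    group_by(.data$locus, .data$category, .data$strand, .data$trans_block,
             .data$copy_index) %>%
    arrange(.data$exon, .by_group = TRUE) %>%
    summarise(exons = paste(sprintf("%d..%d", .data$start, .data$end),
                            collapse = ","), .groups = "drop") %>%
    arrange(.data$locus, .data$copy_index) %>%
    mutate(trans_block = ifelse(is.na(.data$trans_block), "", .data$trans_block)) %>%
    select("locus", "category", "strand", "exons", "trans_block", "copy_index")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_exon_list <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed exon interval: '", parts[which(bad)[1]], "'")
  tibble(start = as.integer(vapply(m, `[`, character(1), 2L)),
         end = as.integer(vapply(m, `[`, character(1), 3L)))
}

# ---- GenBank flat file -----------------------------------------------------

GB_CATEGORY <- c(CDS = "protein", tRNA = "tRNA", rRNA = "rRNA")

# Parse a GenBank location string into exon intervals + strand.
# Supports: N..M, complement(...), join(...), and the combination
# complement(join(...)); partial markers < and > are tolerated.
parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)(\\.\\.(\\d+))?$", parts))
  bad <- vapply(m, length, integer(1)) == 0L | vapply(m, `[`, character(1), 1L) == ""
  if (any(bad)) stop("malformed GenBank location: '", parts[which(bad)[1]], "'")
  start <- as.integer(vapply(m, `[`, character(1), 2L))
  end <- vapply(m, `[`, character(1), 4L)
  end <- ifelse(end == "", start, suppressWarnings(as.integer(end)))
  list(start = start, end = as.integer(end), strand = strand)
}

read_genbank <- function(path, circular = TRUE) {
  lines <- readLines(path)
  locus_line <- grep("^LOCUS", lines, value = TRUE)[1]
  id <- if (!is.na(locus_line)) strsplit(trimws(locus_line), "\\s+")[[1]][2] else "genome"
  ori <- grep("^ORIGIN", lines)[1]
  if (is.na(ori)) stop("no ORIGIN section in ", path)
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
  fstart <- grep("^FEATURES", lines)[1]
  feats <- empty_features()
  if (!is.na(fstart)) {
    block <- lines[(fstart + 1L):(ori - 1L)]
    key_idx <- grep("^ {5}\\S", block)
    rows <- list()
    counts <- new.env(parent = emptyenv())
    for (i in seq_along(key_idx)) {
      from <- key_idx[i]
      to <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(block)
      entry <- block[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", entry[1])
      if (!key %in% names(GB_CATEGORY)) next
      body <- paste(trimws(entry), collapse = " ")
      loc <- sub(paste0("^", key, "\\s+"), "", trimws(entry[1]))
      # location may continue over lines until the first qualifier
      extra <- entry[-1]
      qual_at <- grep("^\\s*/", extra)
      loc_cont <- if (length(qual_at)) extra[seq_len(min(qual_at) - 1L)] else extra
      loc <- paste0(loc, paste(trimws(loc_cont), collapse = ""))
      iv <- tryCatch(parse_gb_location(loc), error = function(e) {
        stop("in ", path, " feature starting at FEATURES line ", from, ": ",
             conditionMessage(e))
      })
      gene <- sub('.*?/gene="([^"]+)".*', "\\1", body)
      if (identical(gene, body)) {
        gene <- sub('.*?/locus_tag="([^"]+)".*', "\\1", body)
        if (identical(gene, body)) gene <- paste0(tolower(key), "_", i)
      }
      category <- if (grepl("/pseudo\\b", body)) "pseudogene" else GB_CATEGORY[[key]]
      trans_block <- sub('.*?/note="trans_block:([^"]+)".*', "\\1", body)
      if (identical(trans_block, body)) trans_block <- NA_character_
      key2 <- paste(gene, trans_block, sep = "\r")
      copy <- (get0(key2, envir = counts, ifnotfound = 0L)) + 1L
      assign(key2, copy, envir = counts)
      rows[[length(rows) + 1L]] <- feature_table(
        gene, category, iv$strand, iv$start, iv$end,
        exon = seq_along(iv$start), trans_block = trans_block, copy_index = copy)
    }
    if (length(rows)) feats <- bind_rows(rows)
  }
  g <- mt_genome(seq, id = id, circular = circular)
  annotated_genome(g, feats, species = id)
}

#' Write an annotated genome as a GenBank flat file
#'
#' A minimal but standards-shaped writer (LOCUS, FEATURES with
#' join()/complement() locations, ORIGIN) sufficient for round-tripping the
#' data model through [read_annotated_genome()].
#'
#' @param ag An [annotated_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(ag, path) {
  g <- ag$genome
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   PLN",
                     g$id, g$length, if (g$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", ag$species), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", g$length), con)
  fb <- ag$features %>%
    group_by(.data$locus, .data$category, .data$strand, .data$trans_block,
             .data$copy_index) %>%
    arrange(.data$exon, .by_group = TRUE) %>%
    summarise(loc = {
      iv <- sprintf("%d..%d", .data$start, .data$end)
      s <- if (length(iv) > 1L) sprintf("join(%s)", paste(iv, collapse = ",")) else iv
      if (.data$strand[1] == "-") sprintf("complement(%s)", s) else s
    }, .groups = "drop") %>%
    arrange(.data$locus, .data$copy_index)
  key_of <- c(protein = "CDS", rRNA = "rRNA", tRNA = "tRNA",
              pseudogene = "CDS", remnant = "misc_feature")
  for (i in seq_len(nrow(fb))) {
    key <- key_of[[fb$category[i]]]
    writeLines(sprintf("     %-15s %s", key, fb$loc[i]), con)
    writeLines(sprintf('                     /gene="%s"', fb$locus[i]), con)
    if (fb$category[i] == "pseudogene") {
      writeLines("                     /pseudo", con)
    }
    if (!is.na(fb$trans_block[i])) {
      writeLines(sprintf('                     /note="trans_block:%s"',
                         fb$trans_block[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(g$seq)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---- GFF3 / BED ------------------------------------------------------------

#' Export features as GFF3 (1-based, inclusive)
#' @param ag An [annotated_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(ag, path) {
  f <- ag$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", ag$genome$id, ag$genome$length))
  if (nrow(f)) {
    attr_str <- sprintf("ID=%s.%d.e%d;locus=%s;category=%s%s",
                        f$locus, f$copy_index, f$exon, f$locus, f$category,
                        ifelse(is.na(f$trans_block), "",
                               paste0(";trans_block=", f$trans_block)))
    lines <- c(lines, sprintf("%s\tmtcompare\texon\t%d\t%d\t.\t%s\t.\t%s",
                              ag$genome$id, f$start, f$end, f$strand, attr_str))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export features as BED (0-based, half-open)
#'
#' The conversion from the internal 1-based inclusive coordinates is exact:
#' BED start = start - 1, BED end = end.
#'
#' @param ag An [annotated_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(ag, path) {
  f <- ag$features
  lines <- if (nrow(f)) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", ag$genome$id, f$start - 1L, f$end,
            paste0(f$locus, ".", f$copy_index, ".e", f$exon), f$strand)
  } else {
    character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert coordinates between 1-based inclusive and 0-based half-open
#'
#' @param start,end Coordinate vectors.
#' @param from `"one_based"` or `"zero_based"`.
#' @return A tibble with converted `start`, `end`.
#' @export
convert_coordinates <- function(start, end, from = c("one_based", "zero_based")) {
  from <- match.arg(from)
  if (from == "one_based") {
    tibble(start = start - 1L, end = end)
  } else {
    tibble(start = start + 1L, end = end)
  }
}
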