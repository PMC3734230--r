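# Synthetic plant-mtDNA generator with full truth tables.
#
# Emulates the architecture the comparative analyses operate on: a circular
# master-circle genome at GC ~0.45 carrying clustered multi-exon and
# trans-spliced genes, planted repeat families across the published size
# classes in direct/inverted orientation, chloroplast-derived insertions at
# >= 80% identity, native and chloroplast-like tRNA genes, and scripted
# rearrangement and tRNA gain/loss histories down a species tree. Every
# planted element is recorded in a truth table so each analysis stage can be
# validated against ground truth at any divergence.

#' Simulation configuration
#'
#' @param length Mitochondrial genome length in bp (default 100000; the
#'   published genomes span roughly 50 kb to 650 kb and the default keeps
#'   every stage fast while leaving room for all planted elements).
#' @param gc Background GC fraction (default 0.45).
#' @param seed Mandatory RNG seed.
#' @param genes Gene roster tibble (see [default_gene_roster()]).
#' @param repeat_plan Repeat plan tibble (see [default_repeat_plan()]).
#' @param mtpt_plan MTPT plan (see [default_mtpt_plan()]).
#' @param trna_native,trna_cp_like tRNA rosters: native labels and
#'   chloroplast-like labels (the latter are copied from the cp genome).
#' @param cp_length Chloroplast genome length in bp (default 30000, a
#'   compact stand-in carrying the annotated gene classes the MTPT and tRNA
#'   stages need).
#' @param cp_like_divergence Maximum per-site divergence applied to
#'   chloroplast-like tRNA copies (default 0.05).
#' @param species,group Metadata for the emitted genome.
#' @return A `sim_config` list.
#' @export
sim_config <- function(length = 100000, gc = 0.45, seed,
                       genes = default_gene_roster(),
                       repeat_plan = default_repeat_plan(),
                       mtpt_plan = default_mtpt_plan(),
                       trna_native = c("trnA", "trnE", "trnG", "trnK", "trnQ",
                                       "trnY", "trnS(GCT)", "trnfM"),
                       trna_cp_like = c("trnH", "trnM", "trnN", "trnP",
                                        "trnW", "trnD"),
                       cp_length = 30000,
                       cp_like_divergence = 0.05,
                       species = "simulated", group = "dicot") {
  if (missing(seed)) stop("a seed is mandatory")
  structure(list(length = as.integer(length), gc = gc, seed = as.integer(seed),
                 genes = genes, repeat_plan = repeat_plan,
                 mtpt_plan = mtpt_plan, trna_native = trna_native,
                 trna_cp_like = trna_cp_like, cp_length = as.integer(cp_length),
                 cp_like_divergence = cp_like_divergence,
                 species = species, group = group),
            class = "sim_config")
}

#' Default gene roster
#'
#' A scaled-down higher-plant mitochondrial roster: ten co-transcribed gene
#' clusters (including the trans-spliced nad1 and nad5 blocks placed in
#' separated clusters), singleton respiratory and ribosomal-protein genes,
#' and three rRNAs.
#'
#' @return A tibble with `locus`, `category`, `length`, `n_exons`,
#'   `trans_block`, `cluster`.
#' @export
default_gene_roster <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~locus, ~category, ~length, ~n_exons, ~trans_block, ~cluster,
    "rpl16",  "protein",  435L, 1L, NA,       "c_rpl16_rps3",
    "rps3",   "protein", 1670L, 2L, NA,       "c_rpl16_rps3",
    "cob",    "protein", 1179L, 1L, NA,       "c_cob_rps14",
    "rps14",  "protein",  303L, 1L, NA,       "c_cob_rps14",
    "rpl2",   "protein", 1005L, 1L, NA,       "c_rpl2_rpl5_nad5c",
    "rpl5",   "protein",  582L, 1L, NA,       "c_rpl2_rpl5_nad5c",
    "nad5",   "protein",   66L, 1L, "nad5c",  "c_rpl2_rpl5_nad5c",
    "nad2",   "protein", 1200L, 3L, "nad2abc", "c_nad2_sdh3",
    "sdh3",   "protein",  435L, 1L, NA,       "c_nad2_sdh3",
    "mttB",   "protein",  801L, 1L, NA,       "c_mttB_nad9",
    "nad9",   "protein",  573L, 1L, NA,       "c_mttB_nad9",
    "sdh4",   "protein",  399L, 1L, NA,       "c_sdh4_cox3",
    "cox3",   "protein",  798L, 1L, NA,       "c_sdh4_cox3",
    "cox1",   "protein", 1593L, 1L, NA,       "c_cox1_rps10",
    "rps10",  "protein",  450L, 2L, NA,       "c_cox1_rps10",
    "atp9",   "protein",  312L, 1L, NA,       "c_atp9_nad5ab",
    "nad5",   "protein", 1500L, 2L, "nad5ab", "c_atp9_nad5ab",
    "nad3",   "protein",  372L, 1L, NA,       "c_nad3_rps12",
    "rps12",  "protein",  357L, 1L, NA,       "c_nad3_rps12",
    "nad1",   "protein",  259L, 1L, "nad1e",  "c_nad1e_matR_nad1d",
    "matR",   "protein", 1968L, 1L, NA,       "c_nad1e_matR_nad1d",
    "nad1",   "protein",   58L, 1L, "nad1d",  "c_nad1e_matR_nad1d",
    "nad1",   "protein",  600L, 2L, "nad1bc", NA,
    "nad2",   "protein",  700L, 2L, "nad2de", NA,
    "atp1",   "protein", 1530L, 1L, NA,       NA,
    "atp4",   "protein",  597L, 1L, NA,       NA,
    "atp6",   "protein",  720L, 1L, NA,       NA,
    "atp8",   "protein",  480L, 1L, NA,       NA,
    "ccmB",   "protein",  621L, 1L, NA,       NA,
    "ccmC",   "protein",  753L, 1L, NA,       NA,
    "ccmFC",  "protein", 1200L, 2L, NA,       NA,
    "ccmFN",  "protein", 1743L, 1L, NA,       NA,
    "nad4",   "protein", 1488L, 3L, NA,       NA,
    "nad4L",  "protein",  303L, 1L, NA,       NA,
    "nad6",   "protein",  720L, 1L, NA,       NA,
    "nad7",   "protein", 1185L, 3L, NA,       NA,
    "cox2",   "protein",  780L, 2L, NA,       NA,
    "rps4",   "protein", 1080L, 1L, NA,       NA,
    "rrn5",   "rRNA",     118L, 1L, NA,       "c_rrn5_rrn18",
    "rrn18",  "rRNA",    1900L, 1L, NA,       "c_rrn5_rrn18",
    "rrn26",  "rRNA",    3400L, 1L, NA,       NA
  )
}

#' Default repeat plan
#'
#' One row per planted family: a size draw within each published size class,
#' mostly two-copy families with a mix of direct and inverted orientation
#' and one three-copy mixed (IR/DR) family. Divergence 0 by default; tests
#' and callers set it per run.
#'
#' @param divergence Per-site substitution divergence between copies
#'   (default 0).
#' @return A tibble with `len_min`, `len_max`, `n_copies`, `type`,
#'   `divergence`.
#' @export
default_repeat_plan <- function(divergence = 0) {
  tibble(
    len_min = c(rep(20L, 4), rep(40L, 3), rep(60L, 2), rep(80L, 2),
                120L, 300L, 1200L, 2000L),
    len_max = c(rep(39L, 4), rep(59L, 3), rep(79L, 2), rep(99L, 2),
                600L, 990L, 1800L, 2500L),
    n_copies = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 3L, 2L, 2L, 2L),
    type = c("DR", "IR", "DR", "IR", "DR", "IR", "DR", "IR", "DR", "IR",
             "DR", "IR/DR", "IR", "DR", "IR"),
    divergence = divergence
  )
}

#' Default MTPT plan
#'
#' Ten chloroplast-derived insertions: four overlapping cp tRNA genes, two
#' inside photosynthesis genes, four from intergenic cp sequence with sizes
#' log-uniform over the published 36-2185 bp range. Identity per insert is
#' uniform on \[`min_identity`, 1\], the reporting floor of MTPT surveys.
#'
#' @param n_trna,n_photo,n_other Insert counts per source class.
#' @param min_identity Lower bound of per-insert identity (default 0.8).
#' @return A list-plan consumed by [generate_mt_genome()].
#' @export
default_mtpt_plan <- function(n_trna = 4, n_photo = 2, n_other = 4,
                              min_identity = 0.8) {
  list(n_trna = n_trna, n_photo = n_photo, n_other = n_other,
       min_identity = min_identity, size_range = c(36L, 2185L))
}

# --- chloroplast genome -----------------------------------------------------

# Build the synthetic chloroplast partner: tRNAs, photosynthesis genes and
# other genes laid head-to-tail with random spacers.
build_cp_genome <- function(cfg) {
  roster <- tibble(
    locus = c("trnH", "trnM", "trnN", "trnP", "trnW", "trnC", "trnD", "trnF",
              "psbA", "psaA", "rbcL", "petA", "ndhB", "rpoB", "clpP"),
    category = c(rep("tRNA", 8), rep("protein", 7)),
    length = c(rep(75L, 8), 1062L, 1500L, 1428L, 963L, 1500L, 2000L, 591L)
  )
  seq <- random_dna(cfg$cp_length, gc = 0.37)
  pos <- 200L
  feats <- list()
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(roster))) {
    gap <- sample(150:600, 1)
    start <- pos + gap
    end <- start + roster$length[i] - 1L
    if (end > cfg$cp_length - 200L) stop("cp roster does not fit cp_length")
    strand <- sample(c("+", "-"), 1)
    feats[[i]] <- feature_table(roster$locus[i], roster$category[i], strand,
                                start, end)
    pos <- end
  }
  annotated_genome(mt_genome(paste(ch, collapse = ""), id = "cp_sim"),
                   bind_rows(feats), species = paste0(cfg$species, "_cp"))
}

# --- placement machinery ----------------------------------------------------

new_occupancy <- function(L) {
  env <- new.env(parent = emptyenv())
  env$iv <- IRanges::IRanges()
  env$L <- L
  env
}

occupy <- function(occ, start, end) {
  occ$iv <- IRanges::reduce(c(occ$iv, IRanges::IRanges(start, end)))
  invisible(occ)
}

# uniform draw over all feasible placements of a `len`-bp slot with
# `margin` clearance; errors only when the packing is truly infeasible
find_slot <- function(occ, len, margin = 40L) {
  L <- occ$L
  need <- len + margin
  gaps <- if (length(occ$iv) == 0L) IRanges::IRanges(1L, L) else
    IRanges::gaps(occ$iv, start = 1L, end = L)
  gaps <- gaps[IRanges::width(gaps) >= need]
  if (length(gaps) == 0L) {
    stop(sprintf("infeasible packing: no free gap can hold %d bp", len))
  }
  slack <- IRanges::width(gaps) - need + 1L
  gi <- sample.int(length(gaps), 1, prob = slack)
  start <- IRanges::start(gaps)[gi] + margin %/% 2L +
    sample.int(slack[gi], 1) - 1L
  occupy(occ, start - margin %/% 2L, start + len - 1L + margin %/% 2L)
  start
}

splice_into <- function(chars, start, s) {
  chars[start:(start + nchar(s) - 1L)] <- strsplit(s, "", fixed = TRUE)[[1]]
  chars
}

# --- main generator ---------------------------------------------------------

#' Generate a synthetic annotated plant mt genome with truth tables
#'
#' Deterministic for a fixed seed. Background sequence is i.i.d. at the
#' target GC; genes (clustered, multi-exon, trans-spliced), repeat-family
#' copies and chloroplast-derived insertions are placed without unplanned
#' overlap; the chloroplast partner genome is emitted with tRNA and
#' photosynthesis annotations so MTPT and tRNA-origin classification are
#' testable end to end.
#'
#' @param cfg A [sim_config()].
#' @return A list: `mt` (annotated mt genome), `cp` (annotated cp genome),
#'   `truth` (list of tibbles: `repeats` one row per copy, `mtpt` one row
#'   per planted cp-derived segment, `trna` origin per tRNA, `clusters`
#'   named list of ordered cluster label vectors).
#' @export
generate_mt_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$length
  cp <- build_cp_genome(cfg)
  chars <- strsplit(random_dna(L, cfg$gc), "", fixed = TRUE)[[1]]
  occ <- new_occupancy(L)
  feats <- list()
  truth_rep <- list()
  truth_mtpt <- list()
  truth_trna <- list()

  # -- genes, cluster blocks first
  roster <- cfg$genes
  add_gene <- function(row, start, strand) {
    len <- row$length
    n_ex <- row$n_exons
    if (n_ex == 1L) {
      ex_st <- start; ex_en <- start + len - 1L
    } else {
      exl <- diff(round(seq(0, len, length.out = n_ex + 1L)))
      intr <- sample(120:600, n_ex - 1L, replace = TRUE)
      ex_st <- integer(n_ex); ex_en <- integer(n_ex)
      p <- start
      for (e in seq_len(n_ex)) {
        ex_st[e] <- p; ex_en[e] <- p + exl[e] - 1L
        p <- ex_en[e] + 1L + if (e < n_ex) intr[e] else 0L
      }
    }
    span_end <- max(ex_en)
    feats[[length(feats) + 1L]] <<- feature_table(
      row$locus, row$category, strand, ex_st, ex_en,
      exon = seq_along(ex_st), trans_block = row$trans_block,
      copy_index = 1L)
    span_end
  }
  gene_span <- function(row) {
    # coordinate span including introns (drawn later; reserve generously)
    row$length + (row$n_exons - 1L) * 650L
  }
  clusters <- split(roster[!is.na(roster$cluster), ],
                    roster$cluster[!is.na(roster$cluster)])
  truth_clusters <- list()
  for (cl in names(clusters)) {
    block <- clusters[[cl]]
    gaps <- sample(30:500, nrow(block), replace = TRUE)
    span <- sum(vapply(seq_len(nrow(block)), function(i) gene_span(block[i, ]),
                       numeric(1))) + sum(gaps)
    start <- find_slot(occ, span, margin = 60L)
    strand <- sample(c("+", "-"), 1)
    p <- start
    labels <- character(0)
    for (i in seq_len(nrow(block))) {
      row <- block[i, ]
      en <- add_gene(row, p, strand)
      labels <- c(labels, if (!is.na(row$trans_block)) row$trans_block else row$locus)
      p <- en + 1L + gaps[i]
    }
    if (strand == "-") labels <- rev(labels)
    truth_clusters[[cl]] <- labels
  }
  # -- all remaining elements are drawn first, then placed largest-first so
  # packing succeeds whenever the plans fit the genome at all
  cp_fb <- feature_blocks(cp$features)
  plan <- cfg$mtpt_plan
  cp_len <- cp$genome$length
  jobs <- list()
  add_job <- function(size, margin, run) {
    jobs[[length(jobs) + 1L]] <<- list(size = size, margin = margin, run = run)
  }

  # repeat family copies
  rp <- cfg$repeat_plan
  for (i in seq_len(nrow(rp))) {
    len <- sample(rp$len_min[i]:rp$len_max[i], 1)
    proto <- random_dna(len, cfg$gc)
    n_cp <- rp$n_copies[i]
    ori <- switch(rp$type[i],
                  DR = rep("forward", n_cp),
                  IR = c("forward", "reverse"),
                  `IR/DR` = c("forward", "forward", "reverse"))
    if (length(ori) != n_cp) ori <- rep_len(ori, n_cp)
    for (ci in seq_len(n_cp)) {
      s <- if (ci == 1L) proto else
        mutate_dna(proto, count = floor(rp$divergence[i] * len))
      if (ori[ci] == "reverse") s <- revcomp(s)
      local({
        fam <- i; cc <- ci; ss <- s; ll <- len; oo <- ori[ci]
        dv <- rp$divergence[i]; ty <- rp$type[i]
        add_job(ll, 40L, function(start) {
          chars <<- splice_into(chars, start, ss)
          truth_rep[[length(truth_rep) + 1L]] <<- tibble(
            family = fam, rep_length = ll, copy = cc,
            start = start, end = start + ll - 1L, orientation = oo,
            divergence = dv, type = ty)
        })
      })
    }
  }

  pick_source <- function(klass) {
    if (klass == "tRNA") {
      g <- cp_fb[cp_fb$category == "tRNA", ]
      g <- g[sample.int(nrow(g), 1), ]
      pad <- sample(0:20, 2, replace = TRUE)
      c(max(1L, g$start - pad[1]), min(cp_len, g$end + pad[2]))
    } else if (klass == "photosynthesis") {
      g <- cp_fb[grepl(PHOTOSYNTHESIS_PATTERNS, cp_fb$locus), ]
      g <- g[sample.int(nrow(g), 1), ]
      len <- sample(200:min(1500L, g$end - g$start + 1L), 1)
      st <- g$start + sample.int(g$end - g$start - len + 2L, 1) - 1L
      c(st, st + len - 1L)
    } else {
      # intergenic source
      occ_cp <- IRanges::reduce(IRanges::IRanges(cp_fb$start, cp_fb$end))
      gaps <- IRanges::gaps(occ_cp, start = 1L, end = cp_len)
      gaps <- gaps[IRanges::width(gaps) >= 50]
      r <- exp(stats::runif(1, log(plan$size_range[1]),
                            log(min(plan$size_range[2], max(IRanges::width(gaps))))))
      len <- max(plan$size_range[1], min(round(r), plan$size_range[2]))
      gi <- which(IRanges::width(gaps) >= len)
      g <- gaps[gi[sample.int(length(gi), 1)]]
      st <- IRanges::start(g) + sample.int(IRanges::width(g) - len + 1L, 1) - 1L
      c(st, st + len - 1L)
    }
  }
  klasses <- c(rep("tRNA", plan$n_trna), rep("photosynthesis", plan$n_photo),
               rep("other", plan$n_other))
  for (kl in klasses) {
    src <- pick_source(kl)
    s <- substr(cp$genome$seq, src[1], src[2])
    u <- stats::runif(1, plan$min_identity, 1)
    s2 <- mutate_dna(s, count = floor((1 - u) * nchar(s)))
    strand <- sample(c("+", "-"), 1)
    local({
      kl2 <- kl; src2 <- src; seq2 <- s2; str2 <- strand
      idy <- 1 - floor((1 - u) * nchar(s)) / nchar(s)
      add_job(nchar(seq2), 40L, function(start) {
        chars <<- splice_into(chars, start,
                              if (str2 == "+") seq2 else revcomp(seq2))
        truth_mtpt[[length(truth_mtpt) + 1L]] <<- tibble(
          mt_start = start, mt_end = start + nchar(seq2) - 1L,
          cp_start = src2[1], cp_end = src2[2], klass = kl2,
          identity = idy, source = "insert")
      })
    })
  }

  # singleton genes
  singles <- roster[is.na(roster$cluster), ]
  for (i in seq_len(nrow(singles))) {
    local({
      row <- singles[i, ]
      strand <- sample(c("+", "-"), 1)
      add_job(gene_span(row), 60L, function(start) {
        add_gene(row, start, strand)
      })
    })
  }

  # tRNAs: native (background-derived sequence) and cp-like (copied)
  for (lab in cfg$trna_native) {
    local({
      lab2 <- lab
      len <- sample(70:85, 1)
      strand <- sample(c("+", "-"), 1)
      add_job(len, 30L, function(start) {
        feats[[length(feats) + 1L]] <<- feature_table(lab2, "tRNA", strand,
                                                      start, start + len - 1L)
        truth_trna[[length(truth_trna) + 1L]] <<- tibble(locus = lab2,
                                                         origin = "native")
      })
    })
  }
  for (lab in cfg$trna_cp_like) {
    src <- cp_fb[cp_fb$locus == lab & cp_fb$category == "tRNA", ]
    if (nrow(src) == 0L) stop("cp roster lacks tRNA ", lab)
    s <- extract_subsequence(cp$genome, src$start[1], src$end[1], src$strand[1])
    d <- stats::runif(1, 0, cfg$cp_like_divergence)
    s2 <- mutate_dna(s, count = floor(d * nchar(s)))
    strand <- sample(c("+", "-"), 1)
    local({
      lab2 <- lab; seq2 <- s2; str2 <- strand; d2 <- d
      cps <- src$start[1]; cpe <- src$end[1]
      add_job(nchar(seq2), 30L, function(start) {
        chars <<- splice_into(chars, start,
                              if (str2 == "+") seq2 else revcomp(seq2))
        feats[[length(feats) + 1L]] <<- feature_table(
          lab2, "tRNA", str2, start, start + nchar(seq2) - 1L)
        truth_trna[[length(truth_trna) + 1L]] <<- tibble(locus = lab2,
                                                         origin = "cp_like")
        truth_mtpt[[length(truth_mtpt) + 1L]] <<- tibble(
          mt_start = start, mt_end = start + nchar(seq2) - 1L,
          cp_start = cps, cp_end = cpe, klass = "tRNA",
          identity = 1 - d2, source = "trna_gene")
      })
    })
  }

  # place all drawn elements, largest first
  if (length(jobs)) {
    for (j in jobs[order(-vapply(jobs, `[[`, numeric(1), "size"))]) {
      j$run(find_slot(occ, j$size, margin = j$margin))
    }
  }

  mt <- annotated_genome(mt_genome(paste(chars, collapse = ""),
                                   id = cfg$species),
                         if (length(feats)) bind_rows(feats) else empty_features(),
                         species = cfg$species, group = cfg$group)
  list(mt = mt, cp = cp,
       truth = list(repeats = bind_rows(truth_rep),
                    mtpt = bind_rows(truth_mtpt),
                    trna = bind_rows(truth_trna),
                    clusters = truth_clusters))
}

# --- rearrangement operators ------------------------------------------------

# feature-safe sequence span around the gene-order entries [i, i+k-1]
# (protein/rRNA entries, the units of the circular gene order); cut points
# fall in free sequence between features, so no feature of any category is
# split, and interior tRNAs simply travel with the block
block_span <- function(ag, i, k) {
  fb <- feature_blocks(ag$features) %>% arrange(.data$start)
  qi <- which(fb$category %in% c("protein", "rRNA"))
  n <- length(qi)
  if (i < 1L || i + k - 1L > n) stop("block outside the gene order")
  fi <- qi[i]; li <- qi[i + k - 1L]
  first <- fb[fi, ]; last <- fb[li, ]
  prev_end <- if (fi == 1L) 0L else max(fb$end[seq_len(fi - 1L)])
  next_start <- if (li == nrow(fb)) ag$genome$length + 1L else
    min(fb$start[(li + 1L):nrow(fb)])
  if (prev_end >= first$start || last$end >= next_start) {
    stop("cannot cut without splitting a feature")
  }
  a <- prev_end + ((first$start - prev_end) %/% 2L)
  b <- last$end + ((next_start - last$end) %/% 2L)
  c(max(1L, a), min(ag$genome$length, b))
}

# invert the sequence span [a, b] and remap features
apply_inversion_span <- function(ag, a, b) {
  g <- ag$genome
  s <- paste0(substr(g$seq, 1, a - 1L),
              revcomp(substr(g$seq, a, b)),
              substr(g$seq, b + 1L, g$length))
  f <- ag$features
  inside <- f$start >= a & f$end <= b
  if (any((f$start <= b & f$end >= a) & !inside)) {
    stop("inversion span splits a feature")
  }
  ns <- a + b - f$end[inside]
  ne <- a + b - f$start[inside]
  f$start[inside] <- ns
  f$end[inside] <- ne
  f$strand[inside] <- ifelse(f$strand[inside] == "+", "-", "+")
  annotated_genome(mt_genome(s, id = g$id, circular = g$circular), f,
                   species = ag$species, group = ag$group)
}

# move the sequence span [a, b] to position `dest` (a coordinate outside
# [a, b] in the original genome, falling in free sequence)
apply_transposition_span <- function(ag, a, b, dest) {
  g <- ag$genome
  block <- substr(g$seq, a, b)
  rest <- paste0(substr(g$seq, 1, a - 1L), substr(g$seq, b + 1L, g$length))
  w <- b - a + 1L
  dest2 <- if (dest > b) dest - w else dest
  s <- paste0(substr(rest, 1, dest2), block,
              substr(rest, dest2 + 1L, nchar(rest)))
  f <- ag$features
  inside <- f$start >= a & f$end <= b
  if (any((f$start <= b & f$end >= a) & !inside)) {
    stop("transposition span splits a feature")
  }
  shift_out <- function(x) {
    # coordinate in `rest`, then final
    y <- ifelse(x > b, x - w, x)
    ifelse(y > dest2, y + w, y)
  }
  f$start[!inside] <- shift_out(f$start[!inside])
  f$end[!inside] <- shift_out(f$end[!inside])
  f$start[inside] <- f$start[inside] - a + dest2 + 1L
  f$end[inside] <- f$end[inside] - a + dest2 + 1L
  annotated_genome(mt_genome(s, id = g$id, circular = g$circular), f,
                   species = ag$species, group = ag$group)
}

#' Generate a rearranged genome pair with adjacency truth
#'
#' Genome B is derived from genome A by `n_inversions` internal-block
#' inversions and `n_transpositions` block transpositions acting on
#' gene-order blocks (never inside genes). The truth table records the
#' surviving shared-adjacency count computed on the abstract orders by
#' direct enumeration.
#'
#' @param cfg A [sim_config()].
#' @param n_inversions,n_transpositions Numbers of scripted operations.
#' @param block_range Inclusive range of block sizes (in gene-order
#'   entries).
#' @return A list: `a`, `b` (annotated genomes), `truth` with
#'   `shared_adjacency_count` and the per-operation script.
#' @export
generate_related_pair <- function(cfg, n_inversions = 1, n_transpositions = 0,
                                  block_range = c(2, 4)) {
  base <- generate_mt_genome(cfg)
  a <- base$mt
  b <- a
  b$species <- paste0(a$species, "_derived")
  ops <- list()
  n_ops <- n_inversions + n_transpositions
  kinds <- c(rep("inversion", n_inversions), rep("transposition", n_transpositions))
  if (n_ops > 0) kinds <- sample(kinds)
  for (op in kinds) {
    fb <- feature_blocks(b$features) %>% arrange(.data$start)
    n <- sum(fb$category %in% c("protein", "rRNA"))
    if (n < 4L) stop("operations exceed what the gene count allows")
    k <- sample(block_range[1]:min(block_range[2], n - 2L), 1)
    i <- sample(2:(n - k), 1)
    sp <- block_span(b, i, k)
    if (op == "inversion") {
      b <- apply_inversion_span(b, sp[1], sp[2])
    } else {
      # destination in free sequence away from the block
      fb2 <- feature_blocks(b$features) %>% arrange(.data$start)
      cand_gap <- which(fb2$start[-1] - fb2$end[-nrow(fb2)] > 80L)
      cand_gap <- cand_gap[fb2$end[cand_gap] < sp[1] - 100L |
                             fb2$start[cand_gap + 1L] > sp[2] + 100L]
      if (!length(cand_gap)) stop("no destination gap for transposition")
      gi <- sample(rep(cand_gap, 2L), 1)
      dest <- fb2$end[gi] + (fb2$start[gi + 1L] - fb2$end[gi]) %/% 2L
      b <- apply_transposition_span(b, sp[1], sp[2], dest)
    }
    ops[[length(ops) + 1L]] <- tibble(op = op, block_start = i, block_k = k)
  }
  truth_count <- brute_shared_adjacency_count(order_labels(a), order_labels(b))
  list(a = a, b = b,
       truth = list(shared_adjacency_count = truth_count,
                    script = bind_rows(ops),
                    base_truth = base$truth))
}

# abstract (label, strand) circular order of protein+rRNA entries
order_labels <- function(ag) {
  fb <- feature_blocks(ag$features) %>%
    filter(.data$category %in% c("protein", "rRNA")) %>%
    arrange(.data$start) %>%
    mutate(label = ifelse(is.na(.data$trans_block), .data$locus,
                          .data$trans_block))
  tibble(label = fb$label, strand = fb$strand)
}

# independent truth computation: direct enumeration of matching unordered
# neighbor pairs with agreeing relative orientation
brute_shared_adjacency_count <- function(o1, o2) {
  pairs_of <- function(o) {
    n <- nrow(o)
    if (n < 2L) return(character(0))
    nxt <- c(2:n, 1L)
    a <- o$label; b <- o$label[nxt]
    rel <- ifelse(o$strand == o$strand[nxt], "same", "opposite")
    unique(paste(pmin(a, b), pmax(a, b), rel))
  }
  length(intersect(pairs_of(o1), pairs_of(o2)))
}

#' Generate a species panel by evolution down a tree with scripted events
#'
#' The root genome from `cfg` is evolved down `tree`: each branch applies
#' point substitutions at a rate equal to its branch length and any events
#' scripted for its child node (chloroplast-like tRNA gains, tRNA losses,
#' block inversions). Tips become annotated genomes sharing the same
#' chloroplast partner.
#'
#' @param tree A rooted `phylo` with branch lengths in substitutions/site.
#' @param cfg A [sim_config()].
#' @param script Optional event tibble with columns `node` (child node
#'   number of the branch), `event` ("gain_cp", "loss", "invert"), `trna`
#'   (label; NA for invert).
#' @param groups Optional named character vector tip label -> group.
#' @return A list: `genomes` (named list of annotated genomes), `cp`,
#'   `truth` (the script, per-tip expected tRNA states, pairwise tree
#'   distances).
#' @export
generate_species_set <- function(tree, cfg, script = NULL, groups = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(script) && nrow(script) &&
      any(!script$node %in% tree$edge[, 2])) {
    stop("script references a node that is not a branch child in the tree")
  }
  base <- generate_mt_genome(cfg)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  genomes <- list()
  evolve <- function(ag, node) {
    # apply events scripted for this node, then recurse
    if (!is.null(script) && nrow(script)) {
      for (r in which(script$node == node)) {
        ev <- script[r, ]
        if (ev$event == "gain_cp") {
          ag <- add_cp_trna(ag, base$cp, ev$trna, cfg)
        } else if (ev$event == "loss") {
          ag <- drop_trna(ag, ev$trna, cfg)
        } else if (ev$event == "invert") {
          fb <- feature_blocks(ag$features)
          n <- sum(fb$category %in% c("protein", "rRNA"))
          k <- sample(2:3, 1)
          i <- sample(2:(n - k), 1)
          sp <- block_span(ag, i, k)
          ag <- apply_inversion_span(ag, sp[1], sp[2])
        }
      }
    }
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) {
      genomes[[tree$tip.label[node]]] <<- ag
      return(invisible())
    }
    for (kid in kids) {
      rate <- tree$edge.length[which(tree$edge[, 1] == node &
                                       tree$edge[, 2] == kid)]
      g2 <- ag
      g2$genome <- mt_genome(mutate_dna(ag$genome$seq, rate = rate),
                             id = ag$genome$id, circular = ag$genome$circular)
      g2 <- annotated_genome(g2$genome, ag$features, species = ag$species,
                             group = ag$group)
      evolve(g2, kid)
    }
    invisible()
  }
  evolve(base$mt, root)
  for (tip in names(genomes)) {
    genomes[[tip]]$species <- tip
    genomes[[tip]]$genome$id <- tip
    if (!is.null(groups) && tip %in% names(groups)) {
      genomes[[tip]]$group <- groups[[tip]]
    }
  }
  genomes <- genomes[tree$tip.label]
  list(genomes = genomes, cp = base$cp,
       truth = list(script = script, base_truth = base$truth,
                    tree_distance = stats::cophenetic(tree)))
}

# insert a fresh cp-like tRNA copy into the genome
add_cp_trna <- function(ag, cp, lab, cfg) {
  cp_fb <- feature_blocks(cp$features)
  src <- cp_fb[cp_fb$locus == lab & cp_fb$category == "tRNA", ]
  if (nrow(src) == 0L) stop("cp genome lacks tRNA ", lab)
  s <- extract_subsequence(cp$genome, src$start[1], src$end[1], src$strand[1])
  fb <- feature_blocks(ag$features)
  occ <- new_occupancy(ag$genome$length)
  if (nrow(fb)) occupy(occ, fb$start, fb$end)
  start <- find_slot(occ, nchar(s), margin = 30L)
  chars <- strsplit(ag$genome$seq, "", fixed = TRUE)[[1]]
  chars <- splice_into(chars, start, s)
  copy <- sum(ag$features$locus == lab & ag$features$exon == 1L) + 1L
  f <- bind_rows(ag$features,
                 feature_table(lab, "tRNA", "+", start, start + nchar(s) - 1L,
                               copy_index = copy))
  annotated_genome(mt_genome(paste(chars, collapse = ""), id = ag$genome$id),
                   f, species = ag$species, group = ag$group)
}

# remove a tRNA annotation and randomize the underlying sequence
drop_trna <- function(ag, lab, cfg) {
  hit <- ag$features$locus == lab & ag$features$category == "tRNA"
  if (!any(hit)) return(ag)
  chars <- strsplit(ag$genome$seq, "", fixed = TRUE)[[1]]
  for (i in which(hit)) {
    w <- ag$features$end[i] - ag$features$start[i] + 1L
    chars <- splice_into(chars, ag$features$start[i], random_dna(w, cfg$gc))
  }
  annotated_genome(mt_genome(paste(chars, collapse = ""), id = ag$genome$id),
                   ag$features[!hit, ], species = ag$species, group = ag$group)
}
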