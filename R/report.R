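# Table renderers mirroring the published layouts, the run manifest, and a
# one-call pipeline over a simulated data set.

tsv <- function(df) {
  paste(c(paste(names(df), collapse = "\t"),
          do.call(paste, c(lapply(df, as.character), sep = "\t"))),
        collapse = "\n")
}

#' Render a gene-cluster table (location-and-interval layout)
#'
#' One row per cluster: member loci joined by dashes and the
#' coordinate/interval string `start..end-(gap bp)-start..end`.
#'
#' @param ag An [annotated_genome()].
#' @param clusters Named list of ordered member label vectors.
#' @return TSV text.
#' @export
render_cluster_table <- function(ag, clusters) {
  L <- ag$genome$length
  fb <- feature_blocks(ag$features) %>%
    mutate(label = ifelse(is.na(.data$trans_block), .data$locus, .data$trans_block))
  rows <- purrr::imap_dfr(clusters, function(members, name) {
    mfb <- fb[match(members, fb$label), ]
    if (any(is.na(mfb$start))) {
      return(tibble(cluster = name, location = "member missing"))
    }
    parts <- sprintf("%d..%d", mfb$start, mfb$end)
    gaps <- if (nrow(mfb) > 1L) {
      vapply(seq_len(nrow(mfb) - 1L), function(i) {
        intergenic_gap(mfb$end[i], mfb$start[i + 1L], L)
      }, integer(1))
    } else {
      integer(0)
    }
    loc <- parts[1]
    for (i in seq_along(gaps)) {
      loc <- sprintf("%s-(%dbp)-%s", loc, gaps[i], parts[i + 1L])
    }
    tibble(cluster = paste(members, collapse = "-"), location = loc)
  })
  tsv(rows)
}

#' Render a repeat table (size/identity/copies/type layout)
#' @param families Family tibble from [find_repeats()].
#' @return TSV text with one row per family and copy coordinate columns.
#' @export
render_repeat_table <- function(families) {
  max_cp <- if (nrow(families)) max(families$n_copies) else 2L
  rows <- purrr::pmap_dfr(families, function(family_id, rep_length, identity,
                                             type, n_copies, copies) {
    r <- tibble(no = family_id, size_bp = rep_length,
                identity_pct = round_half_away(identity, 2), type = type)
    for (i in seq_len(max_cp)) {
      r[[sprintf("copy%d_start", i)]] <- if (i <= nrow(copies)) copies$start[i] else NA_integer_
      r[[sprintf("copy%d_end", i)]] <- if (i <= nrow(copies)) copies$end[i] else NA_integer_
    }
    r
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(no = character(0), size_bp = integer(0),
                   identity_pct = numeric(0), type = character(0))
  }
  tsv(rows)
}

#' Render the repeat landscape (size-class frequency layout)
#' @param landscape Output of [tabulate_landscape()].
#' @return TSV text in the published row layout (size classes as columns).
#' @export
render_landscape_table <- function(landscape) {
  df <- tibble(row = c("number", "total_length_bp", "coverage_pct"))
  for (i in seq_len(nrow(landscape))) {
    df[[landscape$size_class[i]]] <- c(landscape$n_families[i],
                                       landscape$total_bp[i],
                                       landscape$coverage_pct[i])
  }
  tsv(df)
}

#' Render the MTPT summary (per-species capacity layout)
#' @param summaries Output of [summarize_mtpt()] / [mtpt_summary_row()].
#' @return TSV text.
#' @export
render_mtpt_table <- function(summaries) {
  tsv(summaries %>%
        select(species = "species", total_length_bp = "total_bp",
               n_homologs = "n_homologs", coverage_pct = "coverage_pct"))
}

#' Render the synteny matrix (lower-triangular layout)
#' @param m Matrix from [synteny_matrix()].
#' @return TSV text; upper triangle left blank.
#' @export
render_synteny_matrix <- function(m) {
  n <- nrow(m)
  df <- tibble(species = rownames(m))
  for (j in seq_len(n)) {
    col <- as.character(m[, j])
    col[seq_len(min(j, n))] <- ""
    df[[colnames(m)[j]]] <- col
  }
  tsv(df)
}

#' Render a cluster presence/absence grid with +/-/# symbols
#' @param grid Output of [cluster_presence_grid()].
#' @return TSV text.
#' @export
render_presence_table <- function(grid) {
  tsv(grid)
}

#' Render the shared-sequence matrix
#' @param m Matrix from [shared_matrix()].
#' @return TSV text with the parameters used on a comment line.
#' @export
render_shared_matrix <- function(m) {
  p <- attr(m, "parameters")
  header <- if (length(p)) {
    sprintf("# parameters: %s",
            paste(sprintf("%s=%s", names(p), unlist(p)), collapse = " "))
  } else {
    "# parameters: defaults"
  }
  df <- as_tibble(m, rownames = "species")
  paste(header, tsv(df), sep = "\n")
}

#' Write a machine-readable run manifest
#'
#' Records the package version, seed, parameters and md5 checksums of every
#' written output so each table regenerates from the manifest alone. No
#' timestamps, so reruns are byte-identical.
#'
#' @param dir Run directory.
#' @param seed Seed used.
#' @param params Named list of parameters.
#' @param files Character vector of output files (paths relative to `dir`).
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(dir, seed, params, files) {
  checks <- tools::md5sum(file.path(dir, files))
  manifest <- list(package = "mtcompare",
                   version = as.character(utils::packageVersion("mtcompare")),
                   seed = seed, parameters = params,
                   outputs = as.list(setNames(unname(checks), files)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full simulated pipeline into a directory
#'
#' Simulates a genome, a rearranged pair and a small species panel from one
#' seed, runs every analysis stage (repeats, landscape, MTPT, tRNA census,
#' synteny, masking/shared matrix, concatenated NJ tree) and writes all
#' tables under fixed filenames plus a manifest. Outputs are deterministic:
#' two runs with the same seed are byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param genome_length Simulated mt genome length in bp.
#' @param genes Gene roster for the simulated genomes.
#' @return Invisibly, a named list of the main in-memory results.
#' @export
run_pipeline <- function(dir, seed, genome_length = 100000,
                         genes = default_gene_roster()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(length = genome_length, seed = seed, genes = genes)
  sim <- generate_mt_genome(cfg)
  mt <- sim$mt; cp <- sim$cp

  fams <- find_repeats(mt)
  land <- tabulate_landscape(fams, mt$genome$length)
  hom <- classify_homolog(scan_plastid_homologs(mt, cp), cp)
  mtpt <- mtpt_summary_row(hom, mt$species, mt$genome$length)
  trna <- classify_trna_origin(mt, cp)

  pair <- generate_related_pair(sim_config(length = genome_length,
                                           seed = seed + 1L, genes = genes),
                                n_inversions = 1, n_transpositions = 1)
  sm <- synteny_matrix(list(pair$a, pair$b))
  grid <- cluster_presence_grid(pair$truth$base_truth$clusters,
                                list(pair$a, pair$b))

  tree <- ape::read.tree(text = "((A:0.01,B:0.01):0.005,(C:0.012,D:0.008):0.006);")
  panel <- generate_species_set(tree, sim_config(length = genome_length,
                                                 seed = seed + 2L,
                                                 genes = genes))
  masked <- purrr::map(panel$genomes, function(g) {
    mask_genome(g, scan_plastid_homologs(g, panel$cp), find_repeats(g))
  })
  shm <- shared_matrix(masked)

  loci <- panel_locus_alignments(panel$genomes)
  ca <- concatenate_loci(loci, intersect(conserved_gene_set("all21"),
                                         unique(loci$locus)))
  nj <- nj_tree(p_distance_matrix(ca))

  writeLines(render_repeat_table(fams), file.path(dir, "repeats.tsv"))
  writeLines(render_landscape_table(land), file.path(dir, "landscape.tsv"))
  writeLines(render_mtpt_table(mtpt), file.path(dir, "mtpt.tsv"))
  writeLines(tsv(trna), file.path(dir, "trna_origin.tsv"))
  writeLines(render_synteny_matrix(sm), file.path(dir, "synteny_matrix.tsv"))
  writeLines(render_presence_table(grid), file.path(dir, "presence.tsv"))
  writeLines(render_shared_matrix(shm), file.path(dir, "shared_matrix.tsv"))
  writeLines(nj$newick, file.path(dir, "nj.nwk"))
  files <- c("repeats.tsv", "landscape.tsv", "mtpt.tsv", "trna_origin.tsv",
             "synteny_matrix.tsv", "presence.tsv", "shared_matrix.tsv",
             "nj.nwk")
  write_run_manifest(dir, seed, list(genome_length = genome_length), files)
  invisible(list(families = fams, landscape = land, homologs = hom,
                 mtpt = mtpt, trna = trna, synteny = sm, presence = grid,
                 shared = shm, nj = nj))
}

# per-locus "alignments" for a panel evolved without indels: the gene
# sequences line up positionally, so extraction doubles as alignment
panel_locus_alignments <- function(genomes) {
  purrr::imap_dfr(genomes, function(g, sp) {
    fb <- feature_blocks(g$features) %>%
      filter(.data$category == "protein", is.na(.data$trans_block),
             .data$copy_index == 1L)
    purrr::map_dfr(seq_len(nrow(fb)), function(i) {
      tibble(locus = fb$locus[i], species = sp,
             seq = extract_subsequence(g$genome, fb$start[i], fb$end[i],
                                       fb$strand[i]))
    })
  })
}
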