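# Circular gene orders, shared adjacencies and syntenic gene clusters.

#' Extract the circular gene order of an annotated genome
#'
#' Protein and rRNA features only; tRNAs, pseudogenes and remnants are
#' excluded. Trans-spliced genes appear once per cis block under their
#' `trans_block` label; duplicate copies each contribute one entry under the
#' shared locus label. Entries are sorted by circular start coordinate.
#'
#' @param ag An [annotated_genome()].
#' @return A tibble with `label`, `strand`, `start` ordered along the
#'   circle, carrying the species as attribute `species`.
#' @export
extract_gene_order <- function(ag) {
  stopifnot(inherits(ag, "annotated_genome"))
  fb <- feature_blocks(ag$features) %>%
    filter(.data$category %in% c("protein", "rRNA"))
  if (nrow(fb) == 0L) {
    warning("no protein or rRNA features; empty gene order")
    out <- tibble(label = character(0), strand = character(0), start = integer(0))
  } else {
    out <- fb %>%
      mutate(label = ifelse(is.na(.data$trans_block), .data$locus,
                            .data$trans_block)) %>%
      arrange(.data$start) %>%
      select("label", "strand", "start")
  }
  attr(out, "species") <- ag$species
  out
}

# unordered circular adjacency set of an order tibble: one row per
# neighboring pair with relative orientation
order_adjacencies <- function(ord) {
  n <- nrow(ord)
  if (n < 2L) {
    return(tibble(a = character(0), b = character(0),
                  rel = character(0)))
  }
  nxt <- c(seq_len(n)[-1], 1L)
  a <- ord$label; b <- ord$label[nxt]
  sa <- ord$strand; sb <- ord$strand[nxt]
  rel <- ifelse(sa == sb, "same", "opposite")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  tibble(a = lo, b = hi, rel = rel) %>% distinct()
}

#' Shared adjacencies between two circular gene orders
#'
#' An adjacency matches when the unordered label pair and the relative
#' orientation of its members agree in both genomes; each distinct label
#' pair counts at most once regardless of copy multiplicity. Set
#' `orientation_aware = FALSE` to match on the label pair alone.
#'
#' @param o1,o2 Gene-order tibbles from [extract_gene_order()].
#' @param orientation_aware Require matching relative orientation
#'   (default TRUE).
#' @return A tibble of shared adjacencies (`a`, `b`, `rel`).
#' @export
shared_adjacencies <- function(o1, o2, orientation_aware = TRUE) {
  a1 <- order_adjacencies(o1)
  a2 <- order_adjacencies(o2)
  key <- if (orientation_aware) c("a", "b", "rel") else c("a", "b")
  dplyr::semi_join(a1, a2, by = key) %>% distinct(.data$a, .data$b, .keep_all = TRUE)
}

#' Count syntenic gene clusters between two genomes
#'
#' In `"pair"` mode (the default, matching the convention that any two
#' linked genes count as one cluster) the count is the number of shared
#' adjacencies. In `"run"` mode it is the number of maximal chains of two or
#' more order entries whose consecutive adjacencies are all shared.
#'
#' @param o1,o2 Gene-order tibbles from [extract_gene_order()].
#' @param mode `"pair"` or `"run"`.
#' @param orientation_aware Passed to [shared_adjacencies()].
#' @return Integer cluster count.
#' @export
count_synteny_clusters <- function(o1, o2, mode = c("pair", "run"),
                                   orientation_aware = TRUE) {
  mode <- match.arg(mode)
  sh <- shared_adjacencies(o1, o2, orientation_aware)
  if (mode == "pair") return(nrow(sh))
  # run mode: walk o1's circle and count maximal stretches of shared links
  n <- nrow(o1)
  if (n < 2L || nrow(sh) == 0L) return(0L)
  nxt <- c(seq_len(n)[-1], 1L)
  a <- o1$label; b <- o1$label[nxt]
  rel <- ifelse(o1$strand == o1$strand[nxt], "same", "opposite")
  key <- function(x, y, r) {
    swap <- y < x
    paste(ifelse(swap, y, x), ifelse(swap, x, y),
          if (orientation_aware) r else "", sep = "\r")
  }
  shared_edge <- key(a, b, rel) %in% key(sh$a, sh$b, sh$rel)
  if (all(shared_edge)) return(1L)  # one circular run
  # count maximal blocks of TRUE in the circular edge vector
  rot <- which(!shared_edge)[1]
  v <- shared_edge[c(rot:n, seq_len(rot - 1L))]
  r <- rle(v)
  sum(r$values)
}

#' Pairwise synteny matrix for a set of genomes
#'
#' @param genomes List of [annotated_genome()] objects.
#' @param mode,orientation_aware Passed to [count_synteny_clusters()].
#' @return A symmetric integer matrix (species x species); the diagonal is
#'   the self-comparison count.
#' @export
synteny_matrix <- function(genomes, mode = "pair", orientation_aware = TRUE) {
  orders <- purrr::map(genomes, extract_gene_order)
  sp <- vapply(genomes, function(g) g$species, character(1))
  n <- length(orders)
  m <- matrix(0L, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      m[i, j] <- m[j, i] <- count_synteny_clusters(orders[[i]], orders[[j]],
                                                   mode = mode,
                                                   orientation_aware = orientation_aware)
    }
  }
  m
}

#' Status of a named gene cluster in a genome
#'
#' `member_missing` ("#") when any cluster member has no feature in the
#' genome (this takes precedence), `present` ("+") when all members occur
#' consecutively in the circular order (in either direction) with conserved
#' relative orientations, `broken` ("-") otherwise.
#'
#' @param cluster Ordered character vector of at least two entry labels
#'   (locus or trans-block labels as used by [extract_gene_order()]).
#' @param ag An [annotated_genome()].
#' @return One of `"present"`, `"broken"`, `"member_missing"`.
#' @export
cluster_status <- function(cluster, ag) {
  if (length(cluster) < 2L) stop("a gene cluster needs at least two members")
  ord <- extract_gene_order(ag)
  if (!all(cluster %in% ord$label)) return("member_missing")
  n <- nrow(ord)
  k <- length(cluster)
  if (n < k) return("broken")
  lab2 <- c(ord$label, ord$label)
  str2 <- c(ord$strand, ord$strand)
  for (i in seq_len(n)) {
    win_lab <- lab2[i:(i + k - 1L)]
    win_str <- str2[i:(i + k - 1L)]
    hit <- identical(win_lab, cluster) || identical(win_lab, rev(cluster))
    # conserved relative orientation: the members of a co-transcribed
    # cluster sit on one strand, whichever way the block now points
    if (hit && length(unique(win_str)) == 1L) return("present")
  }
  "broken"
}

#' Conserved clusters across a genome panel
#'
#' Enumerates all adjacencies, reporting those shared by every genome
#' (universal) and those present in every member of one taxonomic group and
#' in no member of any other (group-specific). Genomes in which a member
#' gene is absent are ignored for the presence requirement when
#' `ignore_missing = TRUE` (the "#" policy).
#'
#' @param genomes List of [annotated_genome()] objects with `group` labels.
#' @param ignore_missing Treat member-missing genomes as uninformative
#'   rather than as absence (default TRUE).
#' @return A tibble with `a`, `b`, `rel`, `scope` ("universal" or the group
#'   name) for each conserved adjacency.
#' @export
conserved_clusters <- function(genomes, ignore_missing = TRUE) {
  orders <- purrr::map(genomes, extract_gene_order)
  groups <- vapply(genomes, function(g) as.character(g$group %||% NA), character(1))
  if (length(unique(stats::na.omit(groups))) < 2L) {
    warning("single taxonomic group: universal and group-specific sets coincide")
  }
  adjs <- purrr::map(orders, order_adjacencies)
  all_pairs <- bind_rows(adjs) %>% distinct(.data$a, .data$b, .data$rel)
  status <- purrr::map(seq_along(orders), function(i) {
    present <- paste(all_pairs$a, all_pairs$b, all_pairs$rel) %in%
      paste(adjs[[i]]$a, adjs[[i]]$b, adjs[[i]]$rel)
    missing <- !(all_pairs$a %in% orders[[i]]$label) |
      !(all_pairs$b %in% orders[[i]]$label)
    ifelse(present, "present", ifelse(missing, "member_missing", "broken"))
  })
  stat <- do.call(cbind, status)
  informative <- if (ignore_missing) stat != "member_missing" else
    matrix(TRUE, nrow(stat), ncol(stat))
  res <- list()
  universal <- vapply(seq_len(nrow(stat)), function(r) {
    inf <- informative[r, ]
    any(inf) && all(stat[r, inf] == "present")
  }, logical(1))
  if (any(universal)) {
    res$universal <- mutate(all_pairs[universal, ], scope = "universal")
  }
  for (grp in unique(stats::na.omit(groups))) {
    ing <- which(groups == grp)
    outg <- which(groups != grp)
    spec <- vapply(seq_len(nrow(stat)), function(r) {
      inf_in <- informative[r, ing]
      if (!any(inf_in) || !all(stat[r, ing][inf_in] == "present")) return(FALSE)
      all(stat[r, outg] != "present")
    }, logical(1))
    spec <- spec & !universal
    if (any(spec)) {
      res[[grp]] <- mutate(all_pairs[spec, ], scope = grp)
    }
  }
  if (!length(res)) {
    return(tibble(a = character(0), b = character(0), rel = character(0),
                  scope = character(0)))
  }
  bind_rows(res)
}

#' Cluster presence/absence grid across genomes
#'
#' @param clusters Named list of ordered label vectors.
#' @param genomes List of [annotated_genome()] objects.
#' @return A tibble species x cluster with values "+", "-", "#"
#'   (present / broken / member missing).
#' @export
cluster_presence_grid <- function(clusters, genomes) {
  sym <- c(present = "+", broken = "-", member_missing = "#")
  rows <- purrr::map_dfr(genomes, function(g) {
    st <- vapply(clusters, cluster_status, character(1), ag = g)
    tibble(species = g$species, cluster = names(clusters),
           status = unname(sym[st]))
  })
  tidyr::pivot_wider(rows, names_from = "cluster", values_from = "status")
}
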